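#' @rdname pmi
#' @export
new_assoc_matrix <- function(values, kind, threshold = NA_real_, stratum = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            kind %in% c("pmi", "ppmi", "apc", "ppmi_apc"))
  diag(values) <- NA_real_
  structure(values, class = c("assoc_matrix", "matrix"),
            kind = kind, threshold = threshold, stratum = stratum)
}

.assert_kind <- function(mat, kind) {
  if (!inherits(mat, "assoc_matrix") || !identical(attr(mat, "kind"), kind))
    stop("expected an assoc_matrix of kind '", kind, "'")
}

#' @export
print.assoc_matrix <- function(x, digits = 4, ...) {
  cat("<assoc_matrix> kind = ", attr(x, "kind"), ", ", nrow(x), " animals\n", sep = "")
  m <- unclass(x); attributes(m)[c("kind", "threshold", "stratum")] <- NULL
  print(round(m, digits))
  invisible(x)
}

#' Contact probabilities
#'
#' Converts dyadic contact counts to the joint and marginal probabilities
#' underlying pointwise mutual information: `p(a,b) = f(a,b) / n` and
#' `p(a) = f(a) / (2n)`, where `n` is the total number of contacts. Defined
#' this way, the joint probabilities sum to 1 over dyads and the marginals
#' sum to 1 over animals.
#'
#' @param counts a `contact_counts` object from [count_contacts()].
#' @return An object of class `prob_table`: list with `p_ab` (symmetric
#'   matrix, `NA` diagonal), `p_a` (named vector), `n`.
#' @export
probabilities <- function(counts) {
  stopifnot(inherits(counts, "contact_counts"))
  if (counts$n <= 0) stop("no contacts: probabilities are undefined for n = 0")
  p_ab <- counts$f / counts$n
  diag(p_ab) <- NA_real_
  structure(list(p_ab = p_ab, p_a = counts$f_a / (2 * counts$n), n = counts$n),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat("<prob_table> n = ", x$n, " contacts, ", length(x$p_a), " animals\n", sep = "")
  invisible(x)
}

#' Pointwise mutual information of dyadic contacts
#'
#' For each dyad, `PMI(a,b) = log2( p(a,b) / (p(a) p(b)) )`: how much more
#' (or less) often two animals are in contact than expected if their contact
#' participation were independent. Dyads that never co-occur have
#' `p(a,b) = 0` and get `-Inf`, which the PPMI clamp maps to 0.
#'
#' @param counts a `contact_counts` object.
#' @return An `assoc_matrix` of kind `"pmi"`.
#' @export
pmi <- function(counts) {
  pr <- probabilities(counts)
  vals <- log2(pr$p_ab / outer(pr$p_a, pr$p_a))
  # f(a,b) = 0 gets the -Inf sentinel, also when a marginal is 0 (0/0)
  vals[counts$f == 0] <- -Inf
  new_assoc_matrix(vals, "pmi")
}

#' Positive pointwise mutual information
#'
#' Clamps PMI at zero from below: values strictly greater than 0 pass
#' through, everything else (including the `-Inf` of never-co-occurring
#' dyads) becomes 0. The subsequent background correction assumes
#' nonnegative scores.
#'
#' @param mat an `assoc_matrix` of kind `"pmi"` (see [pmi()]).
#' @return An `assoc_matrix` of kind `"ppmi"`.
#' @export
ppmi <- function(mat) {
  .assert_kind(mat, "pmi")
  new_assoc_matrix(pmax(unclass(mat), 0), "ppmi",
                   threshold = attr(mat, "threshold"), stratum = attr(mat, "stratum"))
}

#' Average product correction (APC) background estimate
#'
#' Estimates, for each dyad, the association expected from the two animals'
#' overall gregariousness rather than a specific preference: the product of
#' the animals' average PPMI with all other animals, divided by the overall
#' average PPMI. Computed in the cancelled form `APC(a,b) = S_a * S_b / S`
#' with `S_a = sum over x != a of PPMI(a,x)` and
#' `S = sum over ordered pairs x != y of PPMI(x,y)`; any consistent
#' averaging denominator cancels algebraically, so this equals the
#' mean-based definition for every choice of that denominator. If all PPMI
#' values are zero, APC is identically zero.
#'
#' @param mat an `assoc_matrix` of kind `"ppmi"`.
#' @return An `assoc_matrix` of kind `"apc"`.
#' @export
apc <- function(mat) {
  .assert_kind(mat, "ppmi")
  if (nrow(mat) < 3)
    stop("APC needs at least 3 animals (averages over 'other' animals)")
  m <- unclass(mat)
  s_a <- rowSums(m, na.rm = TRUE)
  s <- sum(s_a)
  vals <- if (s == 0) matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
          else outer(s_a, s_a) / s
  new_assoc_matrix(vals, "apc",
                   threshold = attr(mat, "threshold"), stratum = attr(mat, "stratum"))
}

#' APC-corrected PPMI
#'
#' Subtracts the APC background estimate from the PPMI scores:
#' `PPMI_APC(a,b) = PPMI(a,b) - APC(a,b)`. Values can be negative; a dyad is
#' considered socially associated when its corrected score is strictly
#' positive.
#'
#' @param mat an `assoc_matrix` of kind `"ppmi"`.
#' @return An `assoc_matrix` of kind `"ppmi_apc"`.
#' @export
ppmi_apc <- function(mat) {
  .assert_kind(mat, "ppmi")
  vals <- unclass(mat) - unclass(apc(mat))
  new_assoc_matrix(vals, "ppmi_apc",
                   threshold = attr(mat, "threshold"), stratum = attr(mat, "stratum"))
}

#' Social network from corrected association scores
#'
#' Animals become nodes; an undirected edge joins a dyad if and only if its
#' APC-corrected PPMI is strictly positive, weighted by that value. Animals
#' with no positive association remain as isolated nodes.
#'
#' @param mat an `assoc_matrix` of kind `"ppmi_apc"` (see [ppmi_apc()]).
#' @return An undirected weighted [igraph::igraph] graph.
#' @export
build_network <- function(mat) {
  .assert_kind(mat, "ppmi_apc")
  animals <- rownames(mat)
  m <- unclass(mat)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  edges <- data.frame(from = animals[idx[, 1]], to = animals[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = animals))
}

#' Node degree summary
#'
#' @param net an undirected weighted igraph graph (see [build_network()]).
#' @return data.frame with `animal`, `degree` (incident edge count) and
#'   `weighted_degree` (sum of incident edge weights).
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "igraph"))
  w <- if (igraph::ecount(net) > 0 && "weight" %in% igraph::edge_attr_names(net))
    igraph::strength(net) else igraph::degree(net) * 0
  data.frame(animal = igraph::V(net)$name,
             degree = as.integer(igraph::degree(net)),
             weighted_degree = as.numeric(w),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export an association matrix as CSV
#'
#' @param mat an `assoc_matrix`.
#' @param path output path.
#' @param shape `"square"` (animals x animals matrix with a leading id
#'   column) or `"long"` (one row per dyad: `animal_a,animal_b,value`).
#' @return `path`, invisibly.
#' @export
write_assoc_csv <- function(mat, path, shape = c("square", "long")) {
  stopifnot(inherits(mat, "assoc_matrix"))
  shape <- match.arg(shape)
  m <- unclass(mat)
  if (shape == "square") {
    df <- data.frame(animal_id = rownames(m), m, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(animal_a = rownames(m)[idx[, 1]],
                     animal_b = colnames(m)[idx[, 2]],
                     value = m[idx])
    df <- df[order(df$animal_a, df$animal_b), , drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
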