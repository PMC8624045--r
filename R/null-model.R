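#' Shuffle the distance column of a dyad-minute table
#'
#' One global permutation of the distance values over all rows, keeping the
#' (dyad, minute) keys in place — the randomization behind the pre-network
#' permutation null model. The multiset of distances is exactly preserved,
#' so the total number of contacts at any threshold is conserved.
#'
#' @param dtable distance table from [pairwise_distances()].
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return A distance table of the same shape with permuted `distance`.
#' @export
shuffle_distances <- function(dtable, seed = NULL) {
  if (nrow(dtable) == 0) stop("empty distance table")
  .with_seed(seed, {
    dtable$distance <- dtable$distance[sample.int(nrow(dtable))]
  })
  dtable
}

# statistic over a vector of per-dyad contact counts; `ai`/`bi` index the
# two animals of each dyad, `inc` is the animals x dyads incidence matrix
.null_stat_fun <- function(statistic, inc, ai, bi) {
  if (statistic == "contact_count") return(function(cnt) cnt)
  function(cnt) {
    n <- sum(cnt)
    f_a <- as.numeric(inc %*% cnt)
    p_a <- f_a / (2 * n)
    s <- log2((cnt / n) / (p_a[ai] * p_a[bi]))
    s[cnt == 0] <- -Inf
    s
  }
}

#' Pre-network permutation null model
#'
#' Shuffles the distance column of the dyad-minute table `n_perm` times;
#' after each shuffle, contacts are re-thresholded and the per-dyad
#' statistic (contact count or PMI) recomputed. The one-sided upper-tail
#' p-value of each dyad is `(1 + r) / (1 + n_perm)` where `r` is the number
#' of replicates whose statistic is at least the observed one (add-one
#' convention, so p is never 0). Because the distance multiset is preserved,
#' every replicate has exactly the observed total number of contacts.
#'
#' @param dtable distance table from [pairwise_distances()].
#' @param threshold contact threshold in meters.
#' @param statistic `"contact_count"` or `"pmi"`.
#' @param n_perm number of permutation replicates (default 1000).
#' @param seed optional integer seed (global RNG state restored).
#' @return An object of class `permutation_result`: list with `table`
#'   (data.frame `animal_a`, `animal_b`, `observed`, `p`), `statistic`,
#'   `threshold`, `n_perm`, `seed`, `total_contacts`, `replicate_totals`,
#'   `animals`.
#' @export
permutation_test <- function(dtable, threshold,
                             statistic = c("contact_count", "pmi"),
                             n_perm = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(dtable) == 0) stop("empty distance table")
  key <- .dyad_key(dtable$animal_a, dtable$animal_b)
  dy <- factor(key)
  di <- as.integer(dy)
  K <- nlevels(dy)
  parts <- strsplit(levels(dy), "--", fixed = TRUE)
  a_lab <- vapply(parts, `[`, "", 1)
  b_lab <- vapply(parts, `[`, "", 2)
  animals <- sort(unique(c(a_lab, b_lab)))
  ai <- match(a_lab, animals); bi <- match(b_lab, animals)
  inc <- matrix(0, length(animals), K)
  inc[cbind(ai, seq_len(K))] <- 1
  inc[cbind(bi, seq_len(K))] <- inc[cbind(bi, seq_len(K))] + 1
  d <- dtable$distance
  obs_cnt <- tabulate(di[d <= threshold], K)
  if (sum(obs_cnt) == 0) stop("zero observed contacts at threshold ", threshold)
  stat_fun <- .null_stat_fun(statistic, inc, ai, bi)
  obs_stat <- stat_fun(obs_cnt)
  m <- length(d)
  ge <- integer(K)
  totals <- integer(n_perm)
  .with_seed(seed, {
    for (r in seq_len(n_perm)) {
      cnt <- tabulate(di[d[sample.int(m)] <= threshold], K)
      totals[r] <- sum(cnt)
      ge <- ge + (stat_fun(cnt) >= obs_stat)
    }
  })
  structure(list(
    table = data.frame(animal_a = a_lab, animal_b = b_lab,
                       observed = obs_stat, p = (1 + ge) / (1 + n_perm),
                       stringsAsFactors = FALSE),
    statistic = statistic, threshold = threshold, n_perm = n_perm,
    seed = seed, total_contacts = sum(obs_cnt), replicate_totals = totals,
    animals = animals
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> statistic = ", x$statistic,
      ", threshold = ", x$threshold, " m, n_perm = ", x$n_perm, "\n", sep = "")
  cat("  dyads with p < 0.05: ", sum(x$table$p < 0.05), " of ", nrow(x$table), "\n", sep = "")
  invisible(x)
}

#' Network of significant dyads
#'
#' Builds an unweighted network whose edges are the dyads significant under
#' the permutation null model: an edge is present iff `p < alpha` (after the
#' optional multiple-testing adjustment), with all edge weights set to 1.
#'
#' @param result a `permutation_result`.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"`.
#' @return An undirected igraph graph over the animals of `result`.
#' @export
significant_network <- function(result, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(result, "permutation_result"))
  p <- stats::p.adjust(result$table$p, method = adjust)
  sel <- p < alpha
  edges <- data.frame(from = result$table$animal_a[sel],
                      to = result$table$animal_b[sel], weight = rep(1, sum(sel)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = result$animals))
}

#' Export permutation results
#'
#' Writes the per-dyad table as CSV and, alongside it, a small JSON metadata
#' file (statistic, threshold, n_perm, seed, total contacts).
#'
#' @param result a `permutation_result`.
#' @param path CSV output path; metadata goes to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_permutation_csv <- function(result, path) {
  stopifnot(inherits(result, "permutation_result"))
  write.csv(result$table, path, row.names = FALSE)
  meta <- result[c("statistic", "threshold", "n_perm", "seed", "total_contacts")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
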