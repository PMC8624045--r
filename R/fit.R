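#' Fit a social network from GPS tracks
#'
#' Runs the full association pipeline: pairwise dyad-minute distances,
#' threshold-based contact detection, dyadic contact counts, pointwise
#' mutual information (PMI), its positive part (PPMI), the average product
#' correction (APC) background estimate, the corrected scores
#' (PPMI - APC), and finally the network whose edges are the dyads with
#' strictly positive corrected association.
#'
#' @param tracks a [track_set()].
#' @param threshold contact distance threshold in meters (default 1).
#' @param activity optional activity data.frame; required when
#'   `stratum != "all"`.
#' @param stratum `"all"` (default), or `"lying"` / `"standing"` to restrict
#'   the analysis to minutes where the animal spent the whole minute in that
#'   state (both animals of a dyad must then be in the state for a contact).
#' @param dtable optional precomputed distance table (from
#'   [pairwise_distances()]); when supplied, `tracks` is only used for the
#'   animal roster and `stratum` must be `"all"`.
#' @return An object of class `apc_network`: list with elements `animals`,
#'   `threshold`, `stratum`, `counts` (`contact_counts`), `prob`, `pmi`,
#'   `ppmi`, `apc`, `ppmi_apc` (association matrices), `network` (igraph)
#'   and `call`. Methods: `print`, `summary`, `coef` (corrected score
#'   matrix), `plot`.
#' @examples
#' sim <- simulate_herd(sim_config(duration_days = 1, seed = 42))
#' fit <- apc_network(sim$tracks, threshold = 2.5)
#' fit
#' coef(fit)["A", "B"]
#' @export
apc_network <- function(tracks, threshold = 1, activity = NULL,
                        stratum = c("all", "lying", "standing"),
                        dtable = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  stratum <- match.arg(stratum)
  if (stratum != "all") {
    if (is.null(activity))
      stop("activity records are required for stratum = '", stratum, "'")
    if (!is.null(dtable))
      stop("supply either a precomputed dtable or a stratum, not both")
    tracks <- filter_by_activity(tracks, activity, stratum)
  }
  if (is.null(dtable)) dtable <- pairwise_distances(tracks)
  ctable <- detect_contacts(dtable, threshold)
  counts <- count_contacts(ctable, animals = tracks$animals)
  pr <- probabilities(counts)
  m_pmi <- pmi(counts)
  attr(m_pmi, "threshold") <- threshold
  attr(m_pmi, "stratum") <- stratum
  m_ppmi <- ppmi(m_pmi)
  m_apc <- apc(m_ppmi)
  m_corr <- ppmi_apc(m_ppmi)
  structure(list(
    animals = tracks$animals, threshold = threshold, stratum = stratum,
    counts = counts, prob = pr,
    pmi = m_pmi, ppmi = m_ppmi, apc = m_apc, ppmi_apc = m_corr,
    network = build_network(m_corr), call = match.call()
  ), class = "apc_network")
}

#' @export
print.apc_network <- function(x, ...) {
  cat("Social network fit (PPMI with average product correction)\n")
  cat("  animals   : ", length(x$animals), " (", paste(x$animals, collapse = ", "), ")\n", sep = "")
  cat("  threshold : ", x$threshold, " m, stratum: ", x$stratum, "\n", sep = "")
  cat("  contacts  : n = ", x$counts$n, "\n", sep = "")
  cat("  edges     : ", igraph::ecount(x$network), " of ",
      choose(length(x$animals), 2), " possible dyads\n", sep = "")
  invisible(x)
}

#' @describeIn apc_network matrix of APC-corrected PPMI scores (the edge
#'   weights before the positivity cut).
#' @param object,x an `apc_network` fit.
#' @param ... ignored.
#' @export
coef.apc_network <- function(object, ...) {
  object$ppmi_apc
}

#' @export
summary.apc_network <- function(object, ...) {
  m <- unclass(object$ppmi_apc)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  a <- rownames(m)[idx[, 1]]; b <- colnames(m)[idx[, 2]]
  dyads <- data.frame(
    animal_a = a, animal_b = b,
    f = object$counts$f[idx],
    pmi = unclass(object$pmi)[idx],
    ppmi = unclass(object$ppmi)[idx],
    apc = unclass(object$apc)[idx],
    ppmi_apc = m[idx],
    edge = m[idx] > 0,
    stringsAsFactors = FALSE)
  dyads <- dyads[order(-dyads$ppmi_apc), , drop = FALSE]
  rownames(dyads) <- NULL
  structure(list(fit = object, dyads = dyads,
                 degrees = degree_summary(object$network)),
            class = "summary.apc_network")
}

#' @export
print.summary.apc_network <- function(x, ...) {
  print(x$fit)
  cat("\nDyad scores (sorted by corrected association):\n")
  df <- x$dyads
  df[c("pmi", "ppmi", "apc", "ppmi_apc")] <- round(df[c("pmi", "ppmi", "apc", "ppmi_apc")], 4)
  print(df, row.names = FALSE)
  cat("\nNode degrees:\n")
  print(x$degrees, row.names = FALSE)
  invisible(x)
}

#' @describeIn apc_network plot the inferred network; edge width scales with
#'   the corrected association score.
#' @export
plot.apc_network <- function(x, ...) {
  g <- x$network
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  igraph::plot.igraph(
    g, edge.width = if (length(w)) 1 + 4 * w / max(w) else 1,
    vertex.color = "lightsteelblue", vertex.size = 24, ...)
  invisible(x)
}
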