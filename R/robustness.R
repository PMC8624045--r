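#' Randomly thin a track set
#'
#' Deletes GPS records uniformly at random (without replacement) across all
#' animals and minutes, keeping `round(keep_fraction * n)` records. The
#' animal roster is preserved even if an animal loses every record. With
#' `per_animal = TRUE`, the same fraction is removed within each animal
#' instead of globally.
#'
#' @param tracks a [track_set()].
#' @param keep_fraction fraction of records to keep, in (0, 1].
#' @param seed optional integer seed (global RNG state restored).
#' @param per_animal stratify the deletion by animal (default `FALSE`).
#' @return A [track_set()] with the same roster.
#' @export
subsample_tracks <- function(tracks, keep_fraction, seed = NULL, per_animal = FALSE) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  rec <- tracks$records
  if (keep_fraction == 1) return(tracks)
  idx <- .with_seed(seed, {
    if (per_animal) {
      unlist(lapply(split(seq_len(nrow(rec)), rec$animal_id), function(rows) {
        sort(sample(rows, round(keep_fraction * length(rows))))
      }), use.names = FALSE)
    } else {
      sort(sample.int(nrow(rec), round(keep_fraction * nrow(rec))))
    }
  })
  track_set(rec[idx, , drop = FALSE], animals = tracks$animals)
}

#' Missing-data robustness experiment
#'
#' Measures how stable the inferred network is under random loss of GPS
#' records: for each kept fraction and replicate, records are deleted
#' uniformly at random, the full association pipeline is re-run, and the
#' resulting network is compared to the full-data network by the graph
#' Hamming distance. Replicate seeds are derived deterministically from
#' `base_seed`, so any single replicate can be reproduced in isolation.
#'
#' @param tracks a [track_set()].
#' @param threshold contact threshold in meters (default 1).
#' @param fractions kept fractions of the data
#'   (default `c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)`).
#' @param n_rep replicates per fraction (default 10).
#' @param base_seed integer seed from which replicate seeds are derived.
#' @return An object of class `robustness_result`: data.frame with columns
#'   `fraction_kept`, `replicate`, `seed`, `hamming`, `n_edges`,
#'   `n_edge_diff`; the full-data network is attached as attribute
#'   `full_network`. A replicate whose thinned data yield zero contacts is
#'   recorded as `NA` with a warning.
#' @export
robustness_experiment <- function(tracks, threshold = 1,
                                  fractions = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                                  n_rep = 10, base_seed = 1) {
  stopifnot(inherits(tracks, "track_set"))
  full <- apc_network(tracks, threshold = threshold)
  rows <- vector("list", length(fractions) * n_rep)
  k <- 0L
  for (fi in seq_along(fractions)) {
    for (r in seq_len(n_rep)) {
      seed <- (base_seed + 7919L * fi + 104729L * r) %% .Machine$integer.max
      sub <- subsample_tracks(tracks, fractions[fi], seed = seed)
      fit <- tryCatch(apc_network(sub, threshold = threshold), error = function(e) NULL)
      k <- k + 1L
      if (is.null(fit)) {
        warning("replicate with zero contacts at fraction ", fractions[fi],
                " (replicate ", r, "); recorded as NA")
        rows[[k]] <- data.frame(fraction_kept = fractions[fi], replicate = r,
                                seed = seed, hamming = NA_real_,
                                n_edges = NA_integer_, n_edge_diff = NA_integer_)
      } else {
        rows[[k]] <- data.frame(
          fraction_kept = fractions[fi], replicate = r, seed = seed,
          hamming = hamming(full$network, fit$network),
          n_edges = igraph::ecount(fit$network),
          n_edge_diff = edge_symmetric_difference(full$network, fit$network))
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("robustness_result", "data.frame")
  attr(res, "full_network") <- full$network
  attr(res, "threshold") <- threshold
  res
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("<robustness_result> threshold = ", attr(x, "threshold"), " m, ",
      igraph::ecount(attr(x, "full_network")), " edges in the full network\n", sep = "")
  agg <- aggregate(cbind(hamming, n_edge_diff) ~ fraction_kept, data = x, FUN = median)
  agg <- agg[order(-agg$fraction_kept), ]
  names(agg) <- c("fraction_kept", "median_hamming", "median_edge_diff")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Export a robustness experiment as CSV
#' @param result a `robustness_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom stats aggregate
#' @export
write_robustness_csv <- function(result, path) {
  write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
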