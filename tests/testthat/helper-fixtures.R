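# in-code fixtures and independent oracles used across the test files

utc <- function(x) as.POSIXct(x, tz = "UTC")

# minimal track set: one row per element of the argument vectors
mk_tracks <- function(animal, minute, lon, lat, animals = NULL) {
  track_set(data.frame(
    animal_id = animal,
    timestamp = utc("2019-09-24 00:00:00") + 60 * minute,
    longitude = lon, latitude = lat, stringsAsFactors = FALSE), animals = animals)
}

mk_activity <- function(animal, minute, fraction) {
  data.frame(animal_id = animal,
             timestamp = utc("2019-09-24 00:00:00") + 60 * minute,
             fraction_lying = fraction, stringsAsFactors = FALSE)
}

# contact counts of the 4-animal worked example, built through the real
# counting path (one contact-table row per contact)
worked_counts <- function() {
  f <- c("A--B" = 10, "A--C" = 2, "B--C" = 2, "C--D" = 4, "A--D" = 1, "B--D" = 1)
  ab <- do.call(rbind, strsplit(names(f), "--", fixed = TRUE))
  ctable <- data.frame(
    animal_a = rep(ab[, 1], f), animal_b = rep(ab[, 2], f),
    timestamp = utc("2019-09-24 00:00:00") + 60 * seq_len(sum(f)),
    distance = 0.5, mid_lon = 0, mid_lat = 0, stringsAsFactors = FALSE)
  count_contacts(ctable, animals = c("A", "B", "C", "D"))
}

# random contact counts over N animals; guarantees n > 0
random_counts <- function(N, max_count = 50, zero_prob = 0.2) {
  animals <- LETTERS[seq_len(N)]
  f <- matrix(0, N, N, dimnames = list(animals, animals))
  for (i in seq_len(N - 1)) for (j in seq((i + 1), N)) {
    v <- if (runif(1) < zero_prob) 0 else sample.int(max_count, 1)
    f[i, j] <- v; f[j, i] <- v
  }
  if (sum(f) == 0) f[1, 2] <- f[2, 1] <- 1
  structure(list(animals = animals, f = f, f_a = rowSums(f), n = sum(f) / 2),
            class = "contact_counts")
}

# ---- independent brute-force oracle for the association math --------------
# Explicit double loops, no sharing with the package internals. `norm_n` is
# the averaging denominator used in both the per-animal and the overall
# average (any consistent choice must give the same APC).
oracle_scores <- function(counts, norm_n = length(counts$animals)) {
  an <- counts$animals
  N <- length(an)
  f <- counts$f
  n <- 0
  for (i in seq_len(N - 1)) for (j in seq((i + 1), N)) n <- n + f[i, j]
  p_ab <- f / n
  p_a <- numeric(N); names(p_a) <- an
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) if (j != i) s <- s + f[i, j]
    p_a[i] <- s / (2 * n)
  }
  PMI <- matrix(NA_real_, N, N, dimnames = list(an, an))
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    # never-co-occurring dyads carry the -Inf sentinel (clamped to 0 below)
    PMI[i, j] <- if (f[i, j] == 0) -Inf else log2(p_ab[i, j] / (p_a[i] * p_a[j]))
  }
  PPMI <- PMI
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    PPMI[i, j] <- if (is.finite(PMI[i, j]) && PMI[i, j] > 0) PMI[i, j] else 0
  avg_a <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) if (j != i) s <- s + PPMI[i, j]
    avg_a[i] <- s / norm_n
  }
  overall <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) overall <- overall + PPMI[i, j]
  overall <- overall / norm_n^2
  APC <- matrix(NA_real_, N, N, dimnames = list(an, an))
  CORR <- APC
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    APC[i, j] <- if (overall == 0) 0 else avg_a[i] * avg_a[j] / overall
    CORR[i, j] <- PPMI[i, j] - APC[i, j]
  }
  list(pmi = PMI, ppmi = PPMI, apc = APC, ppmi_apc = CORR,
       p_ab = p_ab, p_a = p_a, n = n)
}

# undirected random graph on 8 named nodes with a given number of edges
random_graph8 <- function(n_edges, nodes = LETTERS[1:8]) {
  all_pairs <- t(combn(nodes, 2))
  pick <- sample.int(nrow(all_pairs), n_edges)
  igraph::graph_from_data_frame(
    data.frame(from = all_pairs[pick, 1], to = all_pairs[pick, 2]),
    directed = FALSE, vertices = data.frame(name = nodes))
}

# exchange k edges of g: delete k existing, add k absent (nodes fixed)
exchange_edges <- function(g, k) {
  nodes <- igraph::V(g)$name
  all_pairs <- t(combn(nodes, 2))
  keys <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                pmax(all_pairs[, 1], all_pairs[, 2]), sep = "--")
  el <- igraph::as_edgelist(g)
  present <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--")
  absent <- setdiff(keys, present)
  stopifnot(length(present) >= k, length(absent) >= k)
  new_keys <- c(setdiff(present, sample(present, k)), sample(absent, k))
  ab <- do.call(rbind, strsplit(new_keys, "--", fixed = TRUE))
  igraph::graph_from_data_frame(
    data.frame(from = ab[, 1], to = ab[, 2]),
    directed = FALSE, vertices = data.frame(name = nodes))
}

# iid-distance dyad-minute table: the fully exchangeable null
exchangeable_dtable <- function(n_minutes = 400, n_animals = 8, max_dist = 10) {
  an <- LETTERS[seq_len(n_animals)]
  pairs <- t(combn(an, 2))
  K <- nrow(pairs)
  data.frame(animal_a = rep(pairs[, 1], n_minutes),
             animal_b = rep(pairs[, 2], n_minutes),
             timestamp = utc("2019-09-24 00:00:00") + rep(60 * seq_len(n_minutes), each = K),
             distance = runif(K * n_minutes, 0, max_dist),
             lon_a = 0, lat_a = 0, lon_b = 0, lat_b = 0,
             stringsAsFactors = FALSE)
}

# small, strongly structured herd for pipeline-level tests
small_sim <- function(seed = 42, days = 2, ...) {
  simulate_herd(sim_config(duration_days = days, seed = seed, ...))
}
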