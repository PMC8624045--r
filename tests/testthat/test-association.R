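# Expected values for the 4-animal worked example were computed with the
# explicit-loop oracle in helper-fixtures.R and frozen here to 4 decimals.

test_that("contact probabilities match direct arithmetic and normalize exactly", {
  pr <- probabilities(worked_counts())
  expect_equal(pr$n, 20)
  expect_equal(pr$p_ab["A", "B"], 0.5)
  expect_equal(unname(pr$p_a[c("A", "B", "C", "D")]), c(0.325, 0.325, 0.2, 0.15))

  single <- count_contacts(data.frame(
    animal_a = rep("A", 5), animal_b = rep("B", 5),
    timestamp = utc("2019-09-24 00:00:00") + 60 * (1:5),
    distance = 0.5, mid_lon = 0, mid_lat = 0))
  pr1 <- probabilities(single)
  expect_equal(pr1$p_ab["A", "B"], 1)
  expect_equal(unname(pr1$p_a), c(0.5, 0.5))

  set.seed(2)
  for (k in 1:25) {
    pr_k <- probabilities(random_counts(sample(3:10, 1)))
    expect_equal(sum(pr_k$p_ab[upper.tri(pr_k$p_ab)]), 1, tolerance = 1e-12)
    expect_equal(sum(pr_k$p_a), 1, tolerance = 1e-12)
  }

  empty <- count_contacts(data.frame(animal_a = character(), animal_b = character(),
                                     timestamp = utc(character()), distance = numeric(),
                                     mid_lon = numeric(), mid_lat = numeric()),
                          animals = c("A", "B"))
  expect_error(probabilities(empty), "no contacts")
})

test_that("PMI reproduces the worked example and the uniform closed form", {
  m <- pmi(worked_counts())
  expect_equal(m["A", "B"], 2.2430, tolerance = 1e-4)
  expect_equal(m["A", "D"], 0.0365, tolerance = 1e-3)
  expect_equal(m["C", "D"], 2.7370, tolerance = 1e-4)
  expect_true(is.na(m["A", "A"]))

  # equal counts on all dyads of N animals: PMI = log2(2N/(N-1)) everywhere
  for (N in c(4, 6, 9)) {
    cc <- random_counts(N)
    cc$f[upper.tri(cc$f)] <- 7; cc$f[lower.tri(cc$f)] <- 7
    cc$f_a <- rowSums(cc$f); cc$n <- sum(cc$f) / 2
    mu <- pmi(cc)
    off <- mu[upper.tri(mu)]
    expect_equal(off, rep(log2(2 * N / (N - 1)), length(off)), tolerance = 1e-12)
  }
  expect_equal(log2(8 / 3), 1.415, tolerance = 1e-3)

  # a never-co-occurring dyad gets -Inf, which PPMI clamps to 0
  cc0 <- worked_counts()
  cc0$f["A", "D"] <- cc0$f["D", "A"] <- 0
  cc0$f_a <- rowSums(cc0$f); cc0$n <- sum(cc0$f) / 2
  m0 <- pmi(cc0)
  expect_identical(m0["A", "D"], -Inf)
  expect_equal(ppmi(m0)["A", "D"], 0)
})

test_that("PPMI clamps strictly at zero", {
  vals <- matrix(c(NA, 2.243, -0.3, 0,
                   2.243, NA, 1, 1,
                   -0.3, 1, NA, 1,
                   0, 1, 1, NA), 4, 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  p <- ppmi(new_assoc_matrix(vals, "pmi"))
  expect_equal(p["A", "B"], 2.243)   # positive passes through
  expect_equal(p["A", "C"], 0)       # negative clamped
  expect_equal(p["A", "D"], 0)       # exactly zero is not "positive"
  expect_error(ppmi(p), "kind 'pmi'")
})

test_that("APC matches the worked example and its closed forms", {
  p <- ppmi(pmi(worked_counts()))
  a <- apc(p)
  expect_equal(a["A", "B"], 0.6683, tolerance = 1e-3)
  expect_equal(a["A", "C"], 0.9169, tolerance = 1e-3)

  # uniform PPMI = v over N animals -> APC = (N-1) v / N everywhere
  for (N in c(4, 7)) {
    v <- 1.3
    u <- matrix(v, N, N, dimnames = list(LETTERS[1:N], LETTERS[1:N]))
    au <- apc(new_assoc_matrix(u, "ppmi"))
    expect_equal(au[upper.tri(au)], rep((N - 1) * v / N, N * (N - 1) / 2),
                 tolerance = 1e-12)
    corr <- ppmi_apc(new_assoc_matrix(u, "ppmi"))
    expect_equal(corr[upper.tri(corr)], rep(v / N, N * (N - 1) / 2), tolerance = 1e-12)
    expect_equal(igraph::ecount(build_network(corr)), N * (N - 1) / 2)  # complete
  }

  zero <- new_assoc_matrix(matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])), "ppmi")
  expect_true(all(apc(zero)[upper.tri(apc(zero))] == 0))
  expect_true(all(ppmi_apc(zero)[upper.tri(ppmi_apc(zero))] == 0))

  two <- new_assoc_matrix(matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))), "ppmi")
  expect_error(apc(two), "at least 3")
})

test_that("corrected scores and the network rule reproduce the worked example", {
  cc <- worked_counts()
  corr <- ppmi_apc(ppmi(pmi(cc)))
  expect_equal(corr["A", "B"], 1.5746, tolerance = 1e-3)
  expect_equal(corr["A", "C"], -0.2954, tolerance = 1e-3)
  expect_equal(corr["C", "D"], 1.8488, tolerance = 1e-3)
  expect_equal(corr["A", "D"], -0.6109, tolerance = 1e-3)

  net <- build_network(corr)
  keys <- apply(igraph::as_edgelist(net), 1, function(e) paste(sort(e), collapse = "--"))
  expect_setequal(keys, c("A--B", "C--D"))
  expect_equal(igraph::vcount(net), 4)  # all animals stay as nodes

  deg <- degree_summary(net)
  expect_equal(deg$degree[deg$animal == "A"], 1)
  expect_equal(deg$weighted_degree[deg$animal == "A"], 1.5746, tolerance = 1e-3)

  # an exactly-zero corrected score yields no edge
  vals <- matrix(c(NA, 0, 0, NA), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  g0 <- build_network(new_assoc_matrix(vals, "ppmi_apc"))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(degree_summary(g0)$degree, c(0L, 0L))
  expect_equal(degree_summary(g0)$weighted_degree, c(0, 0))
})

test_that("vectorized pipeline equals the explicit-loop oracle on random counts", {
  set.seed(31)
  for (k in 1:30) {
    cc <- random_counts(sample(3:10, 1))
    o <- oracle_scores(cc)
    expect_equal(unclass(pmi(cc)), o$pmi, tolerance = 1e-10, ignore_attr = TRUE)
    p <- ppmi(pmi(cc))
    expect_equal(unclass(p), o$ppmi, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(apc(p)), o$apc, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(ppmi_apc(p)), o$ppmi_apc, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("APC is invariant to the averaging denominator and scales linearly", {
  set.seed(17)
  for (k in 1:10) {
    N <- sample(3:9, 1)
    cc <- random_counts(N)
    o_N <- oracle_scores(cc, norm_n = N)
    o_N1 <- oracle_scores(cc, norm_n = N - 1)
    expect_equal(o_N$apc, o_N1$apc, tolerance = 1e-12)
    expect_equal(unclass(apc(ppmi(pmi(cc)))), o_N$apc, tolerance = 1e-10,
                 ignore_attr = TRUE)

    # scale equivariance: k * PPMI -> k * APC and k * corrected; same edges
    p <- ppmi(pmi(cc))
    k_ <- runif(1, 0.5, 4)
    ps <- new_assoc_matrix(unclass(p) * k_, "ppmi")
    expect_equal(unclass(apc(ps)), unclass(apc(p)) * k_, tolerance = 1e-10)
    expect_equal(unclass(ppmi_apc(ps)), unclass(ppmi_apc(p)) * k_, tolerance = 1e-10)
    e1 <- igraph::as_edgelist(build_network(ppmi_apc(p)))
    e2 <- igraph::as_edgelist(build_network(ppmi_apc(ps)))
    expect_equal(e1, e2)
  }
})

test_that("symmetry is preserved through every pipeline stage", {
  set.seed(23)
  cc <- random_counts(7)
  for (m in list(pmi(cc), ppmi(pmi(cc)), apc(ppmi(pmi(cc))), ppmi_apc(ppmi(pmi(cc))))) {
    mm <- unclass(m); diag(mm) <- 0
    expect_equal(mm, t(mm))
  }
})

test_that("association matrices export as square and long CSV", {
  corr <- ppmi_apc(ppmi(pmi(worked_counts())))
  sq <- withr::local_tempfile(fileext = ".csv")
  write_assoc_csv(corr, sq, "square")
  dsq <- read.csv(sq, check.names = FALSE)
  expect_equal(dsq$animal_id, c("A", "B", "C", "D"))
  expect_equal(dsq$B[1], corr["A", "B"])
  lg <- withr::local_tempfile(fileext = ".csv")
  write_assoc_csv(corr, lg, "long")
  dlg <- read.csv(lg)
  expect_equal(nrow(dlg), 6)
  expect_equal(dlg$value[dlg$animal_a == "A" & dlg$animal_b == "B"], corr["A", "B"])
})
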