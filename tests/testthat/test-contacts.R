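test_that("pairwise distances cover exactly the dyad-minutes where both animals have records", {
  # 2 animals, both present at 3 minutes -> 3 rows
  tr <- mk_tracks(rep(c("A", "B"), each = 3), rep(0:2, 2),
                  lon = 9.5 + c(0, 0, 0, 1e-5, 1e-5, 1e-5), lat = rep(52.5, 6))
  d <- pairwise_distances(tr)
  expect_equal(nrow(d), 3)
  expect_true(all(d$animal_a == "A" & d$animal_b == "B"))

  # 3 animals at a single shared minute -> 3 dyads
  tr3 <- mk_tracks(c("A", "B", "C"), c(0, 0, 0), 9.5 + c(0, 1, 2) * 1e-5, rep(52.5, 3))
  expect_equal(nrow(pairwise_distances(tr3)), 3)

  # B missing at minute 1: no dyad containing B at that minute
  tr_gap <- mk_tracks(c("A", "A", "B", "C", "C"), c(0, 1, 0, 0, 1),
                      rep(9.5, 5), rep(52.5, 5))
  dg <- pairwise_distances(tr_gap)
  expect_equal(nrow(dg[dg$timestamp == utc("2019-09-24 00:01:00"), ]), 1)  # only A-C
  expect_false(any(dg$animal_b == "B" & dg$timestamp == utc("2019-09-24 00:01:00")))

  expect_warning(empty <- pairwise_distances(mk_tracks("A", 0, 9.5, 52.5)),
                 "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("distance table size matches the per-minute pair-count oracle", {
  set.seed(21)
  animals <- LETTERS[1:5]
  rows <- expand.grid(animal = animals, minute = 0:49, stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.7, ]
  tr <- mk_tracks(rows$animal, rows$minute,
                  9.5 + runif(nrow(rows)) * 1e-4, 52.5 + runif(nrow(rows)) * 1e-4,
                  animals = animals)
  d <- pairwise_distances(tr)
  present <- table(tr$records$timestamp)
  expect_equal(nrow(d), sum(choose(as.numeric(present), 2)))
})

test_that("contact detection is inclusive at the boundary and monotone in the threshold", {
  tr <- mk_tracks(rep(c("A", "B"), each = 3), rep(0:2, 2),
                  lon = rep(9.5, 6), lat = 52.5 + c(0, 0, 0, 0.5, 1.0, 1.2) / (6378137 * pi / 180))
  d <- pairwise_distances(tr)
  expect_equal(sort(round(d$distance, 6)), c(0.5, 1.0, 1.2))
  ct1 <- detect_contacts(d, 1)
  expect_equal(nrow(ct1), 2)  # 1.0 m is a contact at threshold 1 m
  ct5 <- detect_contacts(d, 5)
  key <- function(x) paste(x$animal_a, x$animal_b, x$timestamp)
  expect_true(all(key(ct1) %in% key(ct5)))
  expect_equal(nrow(detect_contacts(d[0, ], 1)), 0)
  expect_error(detect_contacts(d, 0), "positive")
  expect_error(detect_contacts(d, -1), "positive")
})

test_that("per-dyad counts at a stricter threshold never exceed the looser ones", {
  sim <- small_sim(seed = 8, days = 1)
  d <- pairwise_distances(sim$tracks)
  c1 <- count_contacts(detect_contacts(d, 1), animals = sim$tracks$animals)
  c5 <- count_contacts(detect_contacts(d, 5), animals = sim$tracks$animals)
  expect_true(all(c1$f <= c5$f))
  expect_lte(c1$n, c5$n)
})

test_that("contact counting follows pair-event semantics", {
  ct <- data.frame(
    animal_a = c(rep("A", 6), rep("C", 4)), animal_b = c(rep("B", 6), rep("D", 4)),
    timestamp = utc("2019-09-24 00:00:00") + 60 * (1:10),
    distance = 0.5, mid_lon = 0, mid_lat = 0)
  cc <- count_contacts(ct)
  expect_equal(cc$f["A", "B"], 6)
  expect_equal(cc$f["C", "D"], 4)
  expect_equal(cc$n, 10)
  expect_equal(unname(cc$f_a["A"]), 6)
  expect_equal(unname(cc$f_a["C"]), 4)

  # one minute where A contacts both B and C counts once per dyad, twice for A
  ct2 <- data.frame(animal_a = c("A", "A"), animal_b = c("B", "C"),
                    timestamp = rep(utc("2019-09-24 00:00:00"), 2),
                    distance = 0.5, mid_lon = 0, mid_lat = 0)
  cc2 <- count_contacts(ct2)
  expect_equal(cc2$f["A", "B"], 1)
  expect_equal(cc2$f["A", "C"], 1)
  expect_equal(unname(cc2$f_a["A"]), 2)

  expect_equal(count_contacts(ct[0, ], animals = c("A", "B"))$n, 0)
})

test_that("every animal's involvement sums to twice the total contacts", {
  set.seed(4)
  for (k in 1:20) {
    cc <- random_counts(sample(3:8, 1))
    expect_equal(sum(cc$f_a), 2 * cc$n)
  }
})

test_that("activity stratification keeps only whole-minute states of both animals", {
  # A lying at minutes 0-1; B standing at 0, lying at 1; C partial at 0
  tr <- mk_tracks(c("A", "A", "B", "B", "C"), c(0, 1, 0, 1, 0),
                  rep(9.5, 5), rep(52.5, 5))
  act <- mk_activity(c("A", "A", "B", "B", "C"), c(0, 1, 0, 1, 0),
                     c(1.0, 1.0, 0.0, 1.0, 0.4))
  lying <- filter_by_activity(tr, act, "lying")
  standing <- filter_by_activity(tr, act, "standing")
  # a partially lying minute belongs to neither stratum
  expect_false("C" %in% lying$records$animal_id)
  expect_false("C" %in% standing$records$animal_id)
  expect_equal(lying$animals, tr$animals)  # roster kept
  # A lying + B standing at minute 0: no dyad-minute in either stratum there
  expect_equal(nrow(pairwise_distances(lying)[
    pairwise_distances(lying)$timestamp == utc("2019-09-24 00:00:00"), ]), 0)
  d_stand <- pairwise_distances(standing)
  expect_equal(nrow(d_stand), 0)  # B alone standing
  # both lying at minute 1 -> exactly that dyad-minute survives
  d_lie <- pairwise_distances(lying)
  expect_equal(nrow(d_lie), 1)
  expect_equal(d_lie$timestamp, utc("2019-09-24 00:01:00"))

  # records with no activity match are dropped
  tr_extra <- mk_tracks(c("A", "A"), c(0, 5), rep(9.5, 2), rep(52.5, 2))
  act_one <- mk_activity("A", 0, 1.0)
  expect_equal(nrow(filter_by_activity(tr_extra, act_one, "lying")$records), 1)
})

test_that("contact grids conserve the number of contacts", {
  ky <- 6378137 * pi / 180
  ct <- data.frame(animal_a = "A", animal_b = "B",
                   timestamp = utc("2019-09-24 00:00:00") + 60 * (1:10),
                   distance = 0.5, mid_lon = 9.5, mid_lat = 52.5)
  g <- contact_grid(ct, cell_m = 5)
  expect_equal(sum(g$counts), 10)
  expect_equal(sum(g$counts > 0), 1)  # all contacts at one point -> one cell

  # two groups 100 m apart -> two distinct nonzero cells
  ct2 <- ct
  ct2$mid_lat <- 52.5 + c(rep(0, 5), rep(100 / ky, 5))
  g2 <- contact_grid(ct2, cell_m = 5)
  expect_equal(sum(g2$counts), 10)
  expect_equal(sum(g2$counts > 0), 2)

  # random scatter: cell sums always equal the row count
  set.seed(11)
  ct3 <- ct[rep(1, 200), ]
  ct3$mid_lon <- 9.5 + runif(200, 0, 1e-3)
  ct3$mid_lat <- 52.5 + runif(200, 0, 1e-3)
  expect_equal(sum(contact_grid(ct3, cell_m = 7)$counts), 200)

  expect_equal(contact_grid(ct[0, ])$n, 0)
  expect_error(contact_grid(ct, cell_m = 0), "positive")
})

test_that("contact grid exports to CSV and GeoJSON", {
  set.seed(3)
  ct <- data.frame(animal_a = "A", animal_b = "B",
                   timestamp = utc("2019-09-24 00:00:00") + 60 * (1:50),
                   distance = 0.5,
                   mid_lon = 9.5 + runif(50, 0, 1e-3),
                   mid_lat = 52.5 + runif(50, 0, 1e-3))
  g <- contact_grid(ct, cell_m = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_contact_grid(g, csv, "csv")
  df <- read.csv(csv)
  expect_equal(sum(df$count), 50)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_contact_grid(g, gj, "geojson")
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_equal(sum(vapply(parsed$features, function(f) f$properties$count, 1)), 50)
})
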