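#' Configuration for the synthetic herd simulator
#'
#' Defines the study conditions the simulator emulates: a small herd tracked
#' at one-minute resolution for about a month on a bounded pasture, with a
#' pair of planted partner dyads whose members actively stay close together,
#' two-state (lying/standing) activity, meter-scale GPS noise and optional
#' random missingness.
#'
#' Movement model: the herd center performs a boundary-reflected random walk
#' inside the pasture rectangle; each animal adds a mean-reverting
#' (discrete-time Ornstein-Uhlenbeck) offset around that center, so the herd
#' stays cohesive while individuals wander. Members of a planted dyad are
#' pulled toward each other's offset by `strength` per minute whenever both
#' are standing, and share their activity chain, so their lying bouts happen
#' together and — through the attraction — next to each other. A lying
#' animal keeps its position for the whole bout, which is what makes lying
#' bouts usable for stationary GPS quality estimation.
#'
#' @param n_animals number of animals (default 8, labelled `A`, `B`, ...).
#' @param duration_days days simulated (default 29).
#' @param resolution_minutes sampling interval (default 1).
#' @param start_time first timestamp (POSIXct UTC).
#' @param pasture_width_m,pasture_height_m pasture rectangle in meters
#'   (default 250 x 200 m = 5 ha).
#' @param anchor_lon,anchor_lat WGS84 anchor of the pasture's southwest
#'   corner.
#' @param planted_dyads data.frame `animal_a`, `animal_b`, `strength`;
#'   default two partner dyads A-B and C-D with strength 0.3 (fraction of
#'   the offset gap closed per minute).
#' @param herd_step_sd per-axis step SD of the herd center, m/min.
#' @param individual_spread stationary per-axis SD of an animal's offset
#'   from the herd center, meters.
#' @param offset_reversion mean-reversion rate of the offset per minute,
#'   in (0, 1).
#' @param gps_noise_sd per-axis GPS noise SD in meters,
#'   `c(lat = 1.04, lon = 0.8)`.
#' @param p_lie_down,p_stand_up per-minute transition probabilities of the
#'   two-state activity chain; the stationary lying fraction is
#'   `p_lie_down / (p_lie_down + p_stand_up)`.
#' @param missing_fraction fraction of GPS records dropped uniformly at
#'   random, in \[0, 1).
#' @param seed integer seed; the whole simulation is deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 8, duration_days = 29, resolution_minutes = 1,
                       start_time = as.POSIXct("2019-09-24 00:00:00", tz = "UTC"),
                       pasture_width_m = 250, pasture_height_m = 200,
                       anchor_lon = 9.5, anchor_lat = 52.5,
                       planted_dyads = NULL,
                       herd_step_sd = 5, individual_spread = 15,
                       offset_reversion = 0.1,
                       gps_noise_sd = c(lat = 1.04, lon = 0.8),
                       p_lie_down = 0.01, p_stand_up = 0.012,
                       missing_fraction = 0, seed = 1) {
  animals <- make.unique(rep(LETTERS, length.out = n_animals))
  if (is.null(planted_dyads)) {
    planted_dyads <- if (n_animals >= 4)
      data.frame(animal_a = animals[c(1, 3)], animal_b = animals[c(2, 4)],
                 strength = 0.3, stringsAsFactors = FALSE)
    else
      data.frame(animal_a = character(), animal_b = character(), strength = numeric())
  }
  cfg <- list(n_animals = n_animals, animals = animals,
              duration_days = duration_days, resolution_minutes = resolution_minutes,
              start_time = start_time,
              pasture_width_m = pasture_width_m, pasture_height_m = pasture_height_m,
              anchor_lon = anchor_lon, anchor_lat = anchor_lat,
              planted_dyads = planted_dyads,
              herd_step_sd = herd_step_sd, individual_spread = individual_spread,
              offset_reversion = offset_reversion, gps_noise_sd = gps_noise_sd,
              p_lie_down = p_lie_down, p_stand_up = p_stand_up,
              missing_fraction = missing_fraction, seed = seed)
  if (n_animals < 1 || duration_days <= 0 || resolution_minutes < 1)
    stop("invalid scale parameters")
  if (any(c(herd_step_sd, individual_spread, gps_noise_sd) < 0))
    stop("standard deviations must be nonnegative")
  if (offset_reversion <= 0 || offset_reversion >= 1)
    stop("offset_reversion must lie in (0, 1)")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  if (nrow(planted_dyads) > 0) {
    ok <- planted_dyads$animal_a %in% animals & planted_dyads$animal_b %in% animals &
      planted_dyads$animal_a != planted_dyads$animal_b
    if (!all(ok)) stop("planted_dyads must be pairs of distinct simulated animals")
    if (any(planted_dyads$strength < 0 | planted_dyads$strength >= 0.5))
      stop("attraction strength must lie in [0, 0.5)")
  }
  # animals must plausibly fit the pasture: +-3 SD of the offset either side
  if (6 * individual_spread > min(pasture_width_m, pasture_height_m))
    stop("individual_spread too large for the pasture")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_animals, " animals, ", x$duration_days, " day(s) at ",
      x$resolution_minutes, "-min resolution, seed ", x$seed, "\n", sep = "")
  if (nrow(x$planted_dyads) > 0) {
    cat("  planted dyads: ",
        paste(paste0(x$planted_dyads$animal_a, "-", x$planted_dyads$animal_b,
                     " (s=", x$planted_dyads$strength, ")"), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# reflect x into [lo, hi]
.reflect <- function(x, lo, hi) {
  w <- hi - lo
  r <- (x - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

#' Simulate a herd with planted social structure
#'
#' Generates GPS tracks, activity records and the ground truth for a
#' synthetic herd according to a [sim_config()]. See that help page for the
#' movement and activity model.
#'
#' @param config a [sim_config()].
#' @return An object of class `herd_sim`: list with `tracks` (a
#'   [track_set()]), `activity` (data.frame readable/writable by the
#'   activity CSV functions), `truth` (list: `planted` dyads, `true_x`,
#'   `true_y` noise-free local-meter positions (minutes x animals), `lying`
#'   logical matrix, `timestamps`) and `config`.
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_animals
  T_ <- as.integer(round(config$duration_days * 24 * 60 / config$resolution_minutes))
  animals <- config$animals
  W <- config$pasture_width_m; H <- config$pasture_height_m
  kappa <- config$offset_reversion
  sigma_step <- config$individual_spread * sqrt(1 - (1 - kappa)^2)

  # planted partners share one activity chain: map each animal to a group
  group <- seq_len(N)
  names(group) <- animals
  if (nrow(config$planted_dyads) > 0) {
    for (i in seq_len(nrow(config$planted_dyads)))
      group[config$planted_dyads$animal_b[i]] <- group[config$planted_dyads$animal_a[i]]
  }
  groups <- unique(group)
  pl_i <- match(config$planted_dyads$animal_a, animals)
  pl_j <- match(config$planted_dyads$animal_b, animals)
  pl_s <- config$planted_dyads$strength

  .with_seed(config$seed, {
    # activity chains, one per group
    p_on <- config$p_lie_down; p_off <- config$p_stand_up
    lying_g <- matrix(FALSE, T_, length(groups))
    for (gi in seq_along(groups)) {
      u <- runif(T_)
      s <- logical(T_)
      s[1] <- u[1] < p_on / (p_on + p_off)  # stationary start
      for (t in 2:T_) s[t] <- if (s[t - 1]) u[t] >= p_off else u[t] < p_on
      lying_g[, gi] <- s
    }
    lying <- lying_g[, match(group, groups), drop = FALSE]
    colnames(lying) <- animals

    # movement
    ncx <- rnorm(T_, 0, config$herd_step_sd)
    ncy <- rnorm(T_, 0, config$herd_step_sd)
    true_x <- matrix(NA_real_, T_, N, dimnames = list(NULL, animals))
    true_y <- true_x
    cx <- W / 2; cy <- H / 2
    ox <- rnorm(N, 0, config$individual_spread)
    oy <- rnorm(N, 0, config$individual_spread)
    px <- .reflect(cx + ox, 0, W); py <- .reflect(cy + oy, 0, H)
    ox <- px - cx; oy <- py - cy
    for (t in seq_len(T_)) {
      cx <- .reflect(cx + ncx[t], 0, W)
      cy <- .reflect(cy + ncy[t], 0, H)
      stand <- !lying[t, ]
      if (any(stand)) {
        ox[stand] <- (1 - kappa) * ox[stand] + rnorm(sum(stand), 0, sigma_step)
        oy[stand] <- (1 - kappa) * oy[stand] + rnorm(sum(stand), 0, sigma_step)
        if (length(pl_s) > 0) {
          for (d in seq_along(pl_s)) {
            i <- pl_i[d]; j <- pl_j[d]
            if (stand[i] && stand[j]) {
              dx <- ox[j] - ox[i]; dy <- oy[j] - oy[i]
              ox[i] <- ox[i] + pl_s[d] * dx; ox[j] <- ox[j] - pl_s[d] * dx
              oy[i] <- oy[i] + pl_s[d] * dy; oy[j] <- oy[j] - pl_s[d] * dy
            }
          }
        }
        px[stand] <- .reflect(cx + ox[stand], 0, W)
        py[stand] <- .reflect(cy + oy[stand], 0, H)
      }
      # lying animals keep their position; re-express offsets about the center
      ox <- px - cx; oy <- py - cy
      true_x[t, ] <- px; true_y[t, ] <- py
    }

    timestamps <- config$start_time + (seq_len(T_) - 1) * 60 * config$resolution_minutes
    noise_x <- rnorm(T_ * N, 0, config$gps_noise_sd[["lon"]])
    noise_y <- rnorm(T_ * N, 0, config$gps_noise_sd[["lat"]])
    ll <- .lonlat_from_xy(as.vector(true_x) + noise_x, as.vector(true_y) + noise_y,
                          config$anchor_lon, config$anchor_lat)
    records <- data.frame(
      animal_id = rep(animals, each = T_),
      timestamp = rep(timestamps, N),
      longitude = ll$longitude, latitude = ll$latitude,
      stringsAsFactors = FALSE)
    if (config$missing_fraction > 0)
      records <- records[runif(nrow(records)) >= config$missing_fraction, , drop = FALSE]
    activity <- data.frame(
      animal_id = rep(animals, each = T_),
      timestamp = rep(timestamps, N),
      fraction_lying = as.numeric(as.vector(lying)),
      stringsAsFactors = FALSE)

    structure(list(
      tracks = track_set(records, animals = animals),
      activity = activity,
      truth = list(planted = config$planted_dyads, true_x = true_x, true_y = true_y,
                   lying = lying, timestamps = timestamps),
      config = config
    ), class = "herd_sim")
  })
}

#' @export
print.herd_sim <- function(x, ...) {
  cat("<herd_sim> ", x$config$n_animals, " animals, ",
      nrow(x$tracks$records), " GPS records\n", sep = "")
  invisible(x)
}

#' Planted-dyad recovery report
#'
#' Scores an inferred network against the simulator's planted partner
#' dyads: precision and recall of the planted dyads among the network
#' edges, and the rank of each planted dyad when all dyads are ordered by
#' decreasing corrected association score.
#'
#' @param sim a `herd_sim` (or its `$truth` element).
#' @param fit an [apc_network()] fit on the simulated tracks.
#' @return list with `planted` (dyad keys), `n_edges`, `precision` (`NA`
#'   for an empty network), `recall`, `ranks` (named integer vector,
#'   position of each planted dyad in the score ordering) and
#'   `all_in_top_k` (`TRUE` iff every planted dyad ranks within the first
#'   `length(planted)` dyads).
#' @export
recovery_report <- function(sim, fit) {
  truth <- if (inherits(sim, "herd_sim")) sim$truth else sim
  stopifnot(inherits(fit, "apc_network"))
  planted <- .dyad_key(truth$planted$animal_a, truth$planted$animal_b)
  edges <- .edge_keys(fit$network)
  m <- unclass(coef(fit))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  keys <- .dyad_key(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
  ord <- order(-m[idx])
  ranks <- match(planted, keys[ord])
  names(ranks) <- planted
  list(planted = planted,
       n_edges = length(edges),
       precision = if (length(edges) == 0) NA_real_
                   else length(intersect(planted, edges)) / length(edges),
       recall = if (length(planted) == 0) NA_real_
                else length(intersect(planted, edges)) / length(planted),
       ranks = ranks,
       all_in_top_k = length(planted) > 0 && all(ranks <= length(planted)))
}
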