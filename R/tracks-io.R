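#' Construct a track set
#'
#' A `track_set` holds minute-gridded GPS records for a collection of
#' animals: one row per (animal, minute), timestamps in UTC, coordinates in
#' WGS84 degrees. Timestamps are floored to the minute and duplicate
#' (animal, minute) rows are collapsed to the first occurrence.
#'
#' @param records data.frame with columns `animal_id`, `timestamp`
#'   (`POSIXct`, UTC), `longitude`, `latitude` and optionally `height`,
#'   `n_satellites`, `dop`.
#' @param animals optional character vector of the full animal roster; must
#'   contain every id present in `records`. Defaults to the ids observed.
#'   Keeping the roster explicit lets downsampled or stratified track sets
#'   remember animals that lost all their records.
#' @return An object of class `track_set`: a list with elements `records`
#'   (the normalized data.frame, ordered by animal then time) and `animals`.
#' @export
track_set <- function(records, animals = NULL) {
  req <- c("animal_id", "timestamp", "longitude", "latitude")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("records is missing required column(s): ", paste(miss, collapse = ", "))
  records$animal_id <- as.character(records$animal_id)
  if (!inherits(records$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct (UTC)")
  attr(records$timestamp, "tzone") <- "UTC"
  bad_lon <- records$longitude < -180 | records$longitude > 180
  bad_lat <- records$latitude < -90 | records$latitude > 90
  if (any(bad_lon | bad_lat, na.rm = TRUE) || anyNA(records$longitude) || anyNA(records$latitude))
    stop("coordinates out of range: longitude must lie in [-180, 180], latitude in [-90, 90]")
  # floor to the minute (never round: deterministic and order-stable)
  records$timestamp <- .floor_minute(records$timestamp)
  key <- paste(records$animal_id, as.numeric(records$timestamp))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (animal, minute) record(s) dropped; first occurrence kept")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  records <- records[order(records$animal_id, records$timestamp), , drop = FALSE]
  rownames(records) <- NULL
  obs <- sort(unique(records$animal_id))
  if (is.null(animals)) {
    animals <- obs
  } else {
    animals <- sort(unique(as.character(animals)))
    if (!all(obs %in% animals))
      stop("records contain animal ids absent from the supplied roster")
  }
  structure(list(records = records, animals = animals), class = "track_set")
}

.floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set> ", length(x$animals), " animal(s), ",
      nrow(x$records), " records\n", sep = "")
  if (nrow(x$records) > 0)
    cat("  time span: ", format(min(x$records$timestamp), "%Y-%m-%d %H:%M"),
        " .. ", format(max(x$records$timestamp), "%Y-%m-%d %H:%M"), " UTC\n", sep = "")
  cat("  animals: ", paste(x$animals, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.parse_utc <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%MZ", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    ok <- !is.na(p)
    out[which(todo)[ok]] <- p[ok]
    todo[todo] <- !ok
  }
  out
}

#' Read GPS records from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `animal_id,timestamp,longitude,latitude` and optionally `height`,
#' `n_satellites`, `dop`. Timestamps are ISO-8601 UTC and are floored to the
#' minute on read.
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE`, a row with an unparseable timestamp or an
#'   out-of-range coordinate aborts the read; otherwise such rows are
#'   skipped with a warning.
#' @return A [track_set()].
#' @export
read_gps_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "timestamp", "longitude", "latitude")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("GPS CSV is missing required column(s): ", paste(miss, collapse = ", "))
  df$timestamp <- .parse_utc(df$timestamp)
  df$longitude <- suppressWarnings(as.numeric(df$longitude))
  df$latitude <- suppressWarnings(as.numeric(df$latitude))
  bad <- is.na(df$timestamp) | is.na(df$longitude) | is.na(df$latitude) |
    df$longitude < -180 | df$longitude > 180 | df$latitude < -90 | df$latitude > 90
  if (any(bad)) {
    if (strict)
      stop(sum(bad), " invalid row(s) in ", path,
           " (unparseable timestamp or out-of-range coordinate)")
    warning(sum(bad), " invalid row(s) skipped while reading ", path)
    df <- df[!bad, , drop = FALSE]
  }
  opt <- intersect(c("height", "n_satellites", "dop"), names(df))
  track_set(df[, c(req, opt), drop = FALSE])
}

#' Write GPS records to CSV
#'
#' Inverse of [read_gps_csv()]: emits the documented CSV dialect so that a
#' written track set reads back identically.
#'
#' @param tracks a [track_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$records
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-minute activity records from CSV
#'
#' Expects header `animal_id,timestamp,fraction_lying` where
#' `fraction_lying` is the proportion of the minute the animal spent lying,
#' in \[0, 1\]. Same minute-flooring and first-occurrence deduplication
#' contract as [read_gps_csv()].
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `animal_id`, `timestamp` (POSIXct UTC),
#'   `fraction_lying`, ordered by animal then time.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "timestamp", "fraction_lying")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("activity CSV is missing required column(s): ", paste(miss, collapse = ", "))
  df$animal_id <- as.character(df$animal_id)
  df$timestamp <- .parse_utc(df$timestamp)
  df$fraction_lying <- suppressWarnings(as.numeric(df$fraction_lying))
  if (anyNA(df$timestamp)) stop("unparseable timestamp in ", path)
  if (anyNA(df$fraction_lying) || any(df$fraction_lying < 0 | df$fraction_lying > 1))
    stop("fraction_lying must lie in [0, 1]")
  df$timestamp <- .floor_minute(df$timestamp)
  key <- paste(df$animal_id, as.numeric(df$timestamp))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate activity record(s) dropped; first occurrence kept")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$animal_id, df$timestamp), req, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write activity records to CSV
#' @param activity data.frame as returned by [read_activity_csv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  df <- activity
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Great-circle (haversine) distance in meters
#'
#' Spherical haversine distance between WGS84 coordinate pairs. All
#' pairwise animal distances in the package go through this function.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectorized.
#' @param radius Earth radius in meters (default 6378137).
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2, radius = .EARTH_RADIUS_M) {
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius))
}

# maximal runs of consecutive minutes with fraction_lying == 1, per animal;
# returns data.frame(animal_id, start, end, n_minutes)
.lying_bouts <- function(activity, min_bout_minutes = 60) {
  out <- list()
  for (a in unique(activity$animal_id)) {
    sub <- activity[activity$animal_id == a, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    lying <- sub$fraction_lying == 1.0
    if (!any(lying)) next
    tnum <- as.numeric(sub$timestamp)
    # break a run when the state changes or the minute grid has a gap
    grp <- cumsum(c(TRUE, diff(tnum) != 60 | diff(lying) != 0))
    for (g in split(seq_along(grp), grp)) {
      if (!lying[g[1]]) next
      if (length(g) <= min_bout_minutes) next  # strictly longer than threshold
      out[[length(out) + 1]] <- data.frame(
        animal_id = a, start = sub$timestamp[g[1]], end = sub$timestamp[g[length(g)]],
        n_minutes = length(g), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(animal_id = character(), start = .floor_minute(Sys.time())[0],
                      end = .floor_minute(Sys.time())[0], n_minutes = integer()))
  do.call(rbind, out)
}

#' Stationary GPS quality from lying bouts
#'
#' Uses lying bouts — maximal runs of consecutive minutes an animal spent
#' entirely lying, lasting strictly more than `min_bout_minutes` — as
#' quasi-stationary episodes. Within each bout, position fixes are compared
#' to the bout's geographic mean; deviations are converted to meters by
#' local equirectangular scaling at the bout's mean latitude, pooled across
#' bouts and animals, and summarized as per-axis standard deviations plus
#' the circular error probable, CEP = 0.59 (sd_lat + sd_lon) (50% radius),
#' and 2DRMS = 2 sqrt(sd_lat^2 + sd_lon^2) (approximately the 95% radius).
#'
#' @param tracks a [track_set()].
#' @param activity activity data.frame (see [read_activity_csv()]).
#' @param min_bout_minutes minimum bout duration; bouts must be strictly
#'   longer than this (default 60 minutes).
#' @return An object of class `gps_quality`: list with `bouts` (data.frame),
#'   `n_fixes`, `sd_latitude_m`, `sd_longitude_m`, `cep_m`, `two_drms_m`.
#'   With no qualifying bout, the metrics are `NA` and `bouts` has no rows.
#' @export
gps_quality <- function(tracks, activity, min_bout_minutes = 60) {
  stopifnot(inherits(tracks, "track_set"))
  bouts <- .lying_bouts(activity, min_bout_minutes)
  dev_lat <- numeric(0); dev_lon <- numeric(0)
  n_fixes <- integer(nrow(bouts))
  if (nrow(bouts) > 0) {
    rec <- tracks$records
    for (i in seq_len(nrow(bouts))) {
      sel <- rec$animal_id == bouts$animal_id[i] &
        rec$timestamp >= bouts$start[i] & rec$timestamp <= bouts$end[i]
      pts <- rec[sel, c("longitude", "latitude"), drop = FALSE]
      n_fixes[i] <- nrow(pts)
      if (nrow(pts) < 2) next
      ctr <- geosphere::geomean(as.matrix(pts))
      ky <- .EARTH_RADIUS_M * pi / 180
      kx <- .EARTH_RADIUS_M * cos(ctr[2] * pi / 180) * pi / 180
      dev_lat <- c(dev_lat, (pts$latitude - ctr[2]) * ky)
      dev_lon <- c(dev_lon, (pts$longitude - ctr[1]) * kx)
    }
  }
  bouts$n_fixes <- n_fixes
  if (length(dev_lat) < 2) {
    res <- list(bouts = bouts, n_fixes = length(dev_lat),
                sd_latitude_m = NA_real_, sd_longitude_m = NA_real_,
                cep_m = NA_real_, two_drms_m = NA_real_)
    return(structure(res, class = "gps_quality"))
  }
  sd_lat <- sd(dev_lat); sd_lon <- sd(dev_lon)
  structure(list(
    bouts = bouts, n_fixes = length(dev_lat),
    sd_latitude_m = sd_lat, sd_longitude_m = sd_lon,
    cep_m = 0.59 * (sd_lat + sd_lon),
    two_drms_m = 2 * sqrt(sd_lat^2 + sd_lon^2)
  ), class = "gps_quality")
}

#' @export
print.gps_quality <- function(x, ...) {
  cat("<gps_quality> ", nrow(x$bouts), " lying bout(s), ", x$n_fixes, " fixes\n", sep = "")
  cat(sprintf("  sd latitude : %.2f m\n  sd longitude: %.2f m\n", x$sd_latitude_m, x$sd_longitude_m))
  cat(sprintf("  CEP (50%%)   : %.2f m\n  2DRMS (95%%) : %.2f m\n", x$cep_m, x$two_drms_m))
  invisible(x)
}

#' Export a GPS quality report as JSON
#' @param quality a `gps_quality` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quality_json <- function(quality, path) {
  stopifnot(inherits(quality, "gps_quality"))
  out <- unclass(quality)
  out$bouts$start <- format(out$bouts$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$bouts$end <- format(out$bouts$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
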