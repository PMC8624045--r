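#' Dyad-minute pairwise distance table
#'
#' For every unordered animal pair (dyad) and every minute at which both
#' animals have a GPS record, computes the haversine distance between them.
#' Minutes at which either animal is missing are simply absent; no
#' interpolation is performed. Each dyad is stored with the
#' lexicographically smaller id first.
#'
#' @param tracks a [track_set()].
#' @return data.frame with columns `animal_a`, `animal_b`, `timestamp`,
#'   `distance` (m) plus the two animals' coordinates (`lon_a`, `lat_a`,
#'   `lon_b`, `lat_b`), ordered by dyad then time.
#' @export
pairwise_distances <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  animals <- tracks$animals
  empty <- data.frame(animal_a = character(), animal_b = character(),
                      timestamp = .floor_minute(Sys.time())[0], distance = numeric(),
                      lon_a = numeric(), lat_a = numeric(),
                      lon_b = numeric(), lat_b = numeric())
  if (length(animals) < 2) {
    warning("fewer than 2 animals: empty distance table")
    return(empty)
  }
  rec <- tracks$records
  per <- split(rec, rec$animal_id)
  out <- vector("list", choose(length(animals), 2))
  k <- 0L
  for (i in seq_len(length(animals) - 1L)) {
    for (j in seq((i + 1L), length(animals))) {
      a <- animals[i]; b <- animals[j]
      ra <- per[[a]]; rb <- per[[b]]
      if (is.null(ra) || is.null(rb)) next
      ia <- match(as.numeric(rb$timestamp), as.numeric(ra$timestamp))
      keep <- !is.na(ia)
      if (!any(keep)) next
      ra2 <- ra[ia[keep], , drop = FALSE]
      rb2 <- rb[keep, , drop = FALSE]
      k <- k + 1L
      out[[k]] <- data.frame(
        animal_a = a, animal_b = b, timestamp = rb2$timestamp,
        distance = haversine_m(ra2$longitude, ra2$latitude, rb2$longitude, rb2$latitude),
        lon_a = ra2$longitude, lat_a = ra2$latitude,
        lon_b = rb2$longitude, lat_b = rb2$latitude,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Threshold-based contact detection
#'
#' A contact is a dyad-minute whose pairwise distance does not exceed the
#' threshold (inclusive boundary). Each contact is located at the midpoint
#' between the two animals' positions.
#'
#' @param dtable distance table from [pairwise_distances()].
#' @param threshold contact distance threshold in meters (> 0). The study
#'   design this package supports uses 1, 1.5, 2.5 and 5 m.
#' @return data.frame with columns `animal_a`, `animal_b`, `timestamp`,
#'   `distance`, `mid_lon`, `mid_lat`.
#' @export
detect_contacts <- function(dtable, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number (meters)")
  keep <- dtable$distance <= threshold
  sub <- dtable[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(animal_a = character(), animal_b = character(),
                      timestamp = .floor_minute(Sys.time())[0], distance = numeric(),
                      mid_lon = numeric(), mid_lat = numeric()))
  }
  mid <- geosphere::midPoint(cbind(sub$lon_a, sub$lat_a), cbind(sub$lon_b, sub$lat_b))
  res <- data.frame(animal_a = sub$animal_a, animal_b = sub$animal_b,
                    timestamp = sub$timestamp, distance = sub$distance,
                    mid_lon = mid[, 1], mid_lat = mid[, 2],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Dyadic contact counts
#'
#' Tallies contacts per dyad: `f(a,b)` is the number of minutes animals `a`
#' and `b` were in contact. Derived quantities follow: the total number of
#' contacts `n = sum over dyads of f(a,b)` and the per-animal involvement
#' `f(a) = sum over b of f(a,b)`, which satisfy `sum(f(a)) = 2n` since each
#' contact involves two animals.
#'
#' @param ctable contact table from [detect_contacts()].
#' @param animals optional full roster; dyads never in contact get count 0.
#'   Defaults to the animals appearing in `ctable`.
#' @return An object of class `contact_counts`: list with `animals`, `f`
#'   (symmetric count matrix, zero diagonal), `f_a` (named vector), `n`.
#' @export
count_contacts <- function(ctable, animals = NULL) {
  if (is.null(animals))
    animals <- sort(unique(c(ctable$animal_a, ctable$animal_b)))
  animals <- sort(unique(as.character(animals)))
  f <- matrix(0, length(animals), length(animals), dimnames = list(animals, animals))
  if (nrow(ctable) > 0) {
    tab <- table(factor(ctable$animal_a, levels = animals),
                 factor(ctable$animal_b, levels = animals))
    f <- f + as.matrix(tab)
    f <- f + t(f)  # symmetric; input dyads are stored a < b only
  }
  structure(list(animals = animals, f = f, f_a = rowSums(f), n = sum(f) / 2),
            class = "contact_counts")
}

#' @export
print.contact_counts <- function(x, ...) {
  cat("<contact_counts> ", length(x$animals), " animals, n = ", x$n,
      " total contacts\n", sep = "")
  invisible(x)
}

#' Restrict tracks to minutes of a single activity state
#'
#' Keeps GPS records whose matching activity minute shows the animal
#' entirely in the requested state: `fraction_lying == 1` for `"lying"`,
#' `fraction_lying == 0` for `"standing"`. Records without an activity match
#' are dropped. Downstream contact detection then automatically requires
#' both animals of a dyad to be in the state at the same minute.
#'
#' @param tracks a [track_set()].
#' @param activity activity data.frame (see [read_activity_csv()]).
#' @param state `"lying"` or `"standing"`.
#' @return A [track_set()] over the same animal roster.
#' @export
filter_by_activity <- function(tracks, activity, state = c("lying", "standing")) {
  stopifnot(inherits(tracks, "track_set"))
  state <- match.arg(state)
  target <- if (state == "lying") 1.0 else 0.0
  act <- activity[activity$fraction_lying == target, , drop = FALSE]
  akey <- paste(act$animal_id, as.numeric(act$timestamp))
  rec <- tracks$records
  rkey <- paste(rec$animal_id, as.numeric(rec$timestamp))
  track_set(rec[rkey %in% akey, , drop = FALSE], animals = tracks$animals)
}

#' Spatial grid of contact locations
#'
#' Bins contact midpoints into square cells of side `cell_m` meters on a
#' local equirectangular projection about the data centroid, producing the
#' kind of contact-zone map used to locate social hot spots (watering
#' troughs, resting areas) in a pasture.
#'
#' @param ctable contact table from [detect_contacts()].
#' @param cell_m cell side length in meters (default 5).
#' @param bbox optional bounding box `c(lon_min, lat_min, lon_max, lat_max)`;
#'   defaults to the data extent.
#' @return An object of class `contact_grid`: list with `counts` (matrix,
#'   rows = y/northing, columns = x/easting), `x_breaks`, `y_breaks` (local
#'   meters), `anchor` (lon/lat of the projection origin), `cell_m`, `n`.
#' @export
contact_grid <- function(ctable, cell_m = 5, bbox = NULL) {
  if (!is.numeric(cell_m) || cell_m <= 0) stop("cell_m must be positive")
  if (nrow(ctable) == 0) {
    return(structure(list(counts = matrix(numeric(0), 0, 0),
                          x_breaks = numeric(0), y_breaks = numeric(0),
                          anchor = c(lon = NA_real_, lat = NA_real_),
                          cell_m = cell_m, n = 0L), class = "contact_grid"))
  }
  anchor <- c(lon = mean(ctable$mid_lon), lat = mean(ctable$mid_lat))
  xy <- .local_xy(ctable$mid_lon, ctable$mid_lat, anchor["lon"], anchor["lat"])
  if (is.null(bbox)) {
    xr <- range(xy$x); yr <- range(xy$y)
  } else {
    c1 <- .local_xy(bbox[1], bbox[2], anchor["lon"], anchor["lat"])
    c2 <- .local_xy(bbox[3], bbox[4], anchor["lon"], anchor["lat"])
    xr <- sort(c(c1$x, c2$x)); yr <- sort(c(c1$y, c2$y))
  }
  x_breaks <- seq(xr[1], xr[2] + cell_m, by = cell_m)
  y_breaks <- seq(yr[1], yr[2] + cell_m, by = cell_m)
  ix <- pmin(pmax(findInterval(xy$x, x_breaks), 1L), length(x_breaks) - 1L)
  iy <- pmin(pmax(findInterval(xy$y, y_breaks), 1L), length(y_breaks) - 1L)
  counts <- matrix(0, length(y_breaks) - 1L, length(x_breaks) - 1L)
  for (k in seq_along(ix)) counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1
  structure(list(counts = counts, x_breaks = x_breaks, y_breaks = y_breaks,
                 anchor = anchor, cell_m = cell_m, n = nrow(ctable)),
            class = "contact_grid")
}

#' @export
print.contact_grid <- function(x, ...) {
  cat("<contact_grid> ", nrow(x$counts), " x ", ncol(x$counts),
      " cells of ", x$cell_m, " m, ", x$n, " contacts\n", sep = "")
  invisible(x)
}

#' Export a contact grid as CSV (long form) or GeoJSON polygons
#'
#' @param grid a `contact_grid`.
#' @param path output path.
#' @param format `"csv"` (one row per nonzero cell: cell center in local
#'   meters and lon/lat, count) or `"geojson"` (one polygon feature per
#'   nonzero cell with a `count` property).
#' @return `path`, invisibly.
#' @export
write_contact_grid <- function(grid, path, format = c("csv", "geojson")) {
  stopifnot(inherits(grid, "contact_grid"))
  format <- match.arg(format)
  nz <- which(grid$counts > 0, arr.ind = TRUE)
  xc <- (grid$x_breaks[-length(grid$x_breaks)] + grid$x_breaks[-1]) / 2
  yc <- (grid$y_breaks[-length(grid$y_breaks)] + grid$y_breaks[-1]) / 2
  if (format == "csv") {
    ll <- if (nrow(nz) > 0)
      .lonlat_from_xy(xc[nz[, 2]], yc[nz[, 1]], grid$anchor["lon"], grid$anchor["lat"])
    else list(longitude = numeric(0), latitude = numeric(0))
    df <- data.frame(x_m = xc[nz[, 2]], y_m = yc[nz[, 1]],
                     longitude = ll$longitude, latitude = ll$latitude,
                     count = grid$counts[nz])
    write.csv(df, path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(nz)), function(k) {
      i <- nz[k, 1]; j <- nz[k, 2]
      xs <- grid$x_breaks[c(j, j + 1L)]; ys <- grid$y_breaks[c(i, i + 1L)]
      crn <- .lonlat_from_xy(c(xs[1], xs[2], xs[2], xs[1], xs[1]),
                             c(ys[1], ys[1], ys[2], ys[2], ys[1]),
                             grid$anchor["lon"], grid$anchor["lat"])
      list(type = "Feature",
           properties = list(count = grid$counts[i, j]),
           geometry = list(type = "Polygon",
                           coordinates = list(Map(c, crn$longitude, crn$latitude))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
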