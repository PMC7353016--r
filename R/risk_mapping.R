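#' Probability that the true value lies below a threshold
#'
#' Under the plug-in Gaussian prediction distribution of ordinary kriging
#' (mean = the kriging prediction, variance = the kriging variance), the
#' probability of sub-threshold status is `Phi((t - zhat) / sigma)`. With a
#' zero kriging variance the distribution is degenerate: the probability is 1
#' when the prediction is below the threshold, 0 above, 0.5 at equality.
#'
#' @param prediction Kriging predictions, ug/L.
#' @param kriging_variance Kriging variances, (ug/L)^2, `>= 0`.
#' @param threshold Deficiency threshold, ug/L.
#' @return Probabilities in `[0, 1]`, vectorised over the inputs.
#' @export
prob_below <- function(prediction, kriging_variance, threshold) {
  if (any(kriging_variance < 0)) stop("negative kriging variance", call. = FALSE)
  sigma <- sqrt(kriging_variance)
  out <- ifelse(sigma > 0,
                stats::pnorm((threshold - prediction) / ifelse(sigma > 0, sigma, 1)),
                ifelse(prediction < threshold, 1, ifelse(prediction > threshold, 0, 0.5)))
  out
}

#' Calibrated likelihood phrases
#'
#' The IPCC-style verbal probability scale used to communicate deficiency
#' risk to non-specialist audiences, made non-overlapping: bins are closed on
#' the left and open on the right (a boundary probability belongs to the
#' upper bin), except the last bin which includes 1.
#'
#' @param bins Tibble with columns `lower`, `upper`, `label`; the default is
#'   the seven-phrase scale from "exceptionally unlikely" (< 1%) to
#'   "virtually certain" (>= 99%).
#' @return A `likelihood_scale` tibble.
#' @export
likelihood_scale <- function(bins = NULL) {
  if (is.null(bins)) {
    bins <- tibble::tibble(
      lower = c(0, 0.01, 0.10, 0.33, 0.66, 0.90, 0.99),
      upper = c(0.01, 0.10, 0.33, 0.66, 0.90, 0.99, 1),
      label = c("exceptionally unlikely", "very unlikely", "unlikely",
                "about as likely as not", "likely", "very likely",
                "virtually certain")
    )
  }
  stopifnot(all(bins$lower < bins$upper), !anyDuplicated(bins$label))
  bins <- bins[order(bins$lower), , drop = FALSE]
  if (bins$lower[1] != 0 || bins$upper[nrow(bins)] != 1 ||
      any(bins$upper[-nrow(bins)] != bins$lower[-1])) {
    stop("bins must partition [0, 1]", call. = FALSE)
  }
  structure(tibble::as_tibble(bins), class = c("likelihood_scale", class(bins)))
}

#' Map probabilities to calibrated phrases
#'
#' @param p Probabilities in `[0, 1]`.
#' @param scale A [likelihood_scale()].
#' @return Character vector of phrase labels (a factor ordered by the scale).
#' @examples
#' classify_likelihood(c(0.005, 0.5, 0.995))
#' @export
classify_likelihood <- function(p, scale = likelihood_scale()) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities outside [0, 1]", call. = FALSE)
  edges <- c(scale$lower, 1)
  idx <- findInterval(p, edges, rightmost.closed = TRUE)
  factor(scale$label[idx], levels = scale$label, ordered = TRUE)
}

#' Regular prediction grid over a bounding box or polygon
#'
#' Builds a lattice of nodes in geographic coordinates with an approximately
#' constant metric spacing: the requested spacing in km is converted to
#' degrees at the domain's central latitude. Nodes outside the boundary
#' polygon (when given) are dropped by even-odd ray casting.
#'
#' @param bbox Named numeric `c(lon_min, lon_max, lat_min, lat_max)`, or a
#'   data frame boundary polygon with `lon`, `lat` vertex columns (its
#'   bounding box is used for the lattice and the polygon as the filter).
#' @param spacing_km Node spacing in km, `> 0`.
#' @param radius Sphere radius in km (sets the km-per-degree conversion).
#' @return Tibble of grid nodes with `lat`, `lon` columns.
#' @export
make_grid <- function(bbox, spacing_km, radius = 6378.137) {
  if (spacing_km <= 0) stop("spacing must be positive", call. = FALSE)
  poly <- NULL
  if (is.data.frame(bbox)) {
    poly <- bbox
    bbox <- c(lon_min = min(poly$lon), lon_max = max(poly$lon),
              lat_min = min(poly$lat), lat_max = max(poly$lat))
  }
  km_per_deg <- pi * radius / 180
  lat_c <- (bbox[["lat_min"]] + bbox[["lat_max"]]) / 2
  dlat <- spacing_km / km_per_deg
  dlon <- spacing_km / (km_per_deg * cos(lat_c * pi / 180))
  lats <- seq(bbox[["lat_min"]], bbox[["lat_max"]], by = dlat)
  lons <- seq(bbox[["lon_min"]], bbox[["lon_max"]], by = dlon)
  grid <- tidyr::expand_grid(lat = lats, lon = lons)
  if (!is.null(poly)) {
    inside <- point_in_polygon(grid$lon, grid$lat, poly$lon, poly$lat)
    grid <- grid[inside, , drop = FALSE]
  }
  if (nrow(grid) == 0) stop("grid does not intersect the boundary", call. = FALSE)
  grid
}

# Even-odd rule point-in-polygon test; boundary points count as inside.
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Probability-of-deficiency surface
#'
#' Converts a kriging prediction surface into a per-node probability of
#' sub-threshold serum status plus a calibrated likelihood phrase.
#'
#' @param predictions Tibble from [krige_ok()] (`lat`, `lon`, `prediction`,
#'   `kriging_variance`).
#' @param threshold Deficiency threshold, ug/L, `> 0`.
#' @param scale A [likelihood_scale()].
#' @return A `probability_surface` tibble: `lat`, `lon`, `probability`,
#'   `phrase`, with the threshold and scale as attributes.
#' @export
build_surface <- function(predictions, threshold, scale = likelihood_scale()) {
  if (nrow(predictions) == 0) stop("no predictions supplied", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  p <- prob_below(predictions$prediction, predictions$kriging_variance, threshold)
  out <- tibble::tibble(
    lat = predictions$lat, lon = predictions$lon,
    probability = p, phrase = classify_likelihood(p, scale)
  )
  structure(out, threshold = threshold, scale = scale,
            class = c("probability_surface", class(out)))
}

#' Export a probability surface as CSV and GeoJSON
#'
#' The CSV holds the data layer (`lon, lat, probability, phrase`); the
#' GeoJSON is a point feature collection with the same properties, plus a
#' metadata JSON describing the threshold and the phrase vocabulary so map
#' legends can be reproduced.
#'
#' @param surface A `probability_surface`.
#' @param path CSV output path; `.geojson` and `_meta.json` companions are
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  df <- tibble::as_tibble(surface)
  df$phrase <- as.character(df$phrase)
  readr::write_csv(df[, c("lon", "lat", "probability", "phrase")], path,
                   progress = FALSE)
  features <- purrr::pmap(df, function(lat, lon, probability, phrase) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(lon, lat)),
         properties = list(probability = probability, phrase = phrase))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       sub("\\.csv$", ".geojson", path),
                       auto_unbox = TRUE, digits = NA)
  scale <- attr(surface, "scale")
  jsonlite::write_json(list(
    threshold_ugL = attr(surface, "threshold"),
    phrases = purrr::pmap(scale, function(lower, upper, label) {
      list(lower = lower, upper = upper, label = label)
    })
  ), sub("\\.csv$", "_meta.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
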