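# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for stochastic operations", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default study bounding box
#'
#' A longitude/latitude box (33-48 degrees E, 3-15 degrees N) covering
#' Ethiopia, the default simulation and mapping domain.
#'
#' @return Named numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @export
ethiopia_bbox <- function() {
  c(lon_min = 33, lon_max = 48, lat_min = 3, lat_max = 15)
}

#' Coarse Ethiopia boundary polygon (synthetic stand-in)
#'
#' A hand-drawn, deliberately coarse polygon approximating Ethiopia's outline
#' for masking prediction grids. It is a synthetic stand-in for real
#' administrative boundaries, which this package does not ship.
#'
#' @return Tibble of polygon vertices with `lon`, `lat` columns.
#' @export
ethiopia_polygon <- function() {
  tibble::tibble(
    lon = c(33.0, 36.0, 37.5, 41.5, 43.0, 48.0, 46.5, 45.0, 41.0, 39.5,
            36.0, 35.0, 34.0, 33.0),
    lat = c(8.0, 14.0, 14.5, 13.8, 12.5, 8.0, 5.0, 4.0, 3.8, 3.4,
            4.5, 5.2, 6.5, 8.0)
  )
}
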