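#' Configuration for a synthetic serum selenium survey
#'
#' Collects the knobs of the synthetic-survey generator. The defaults state a
#' world mirroring the 2015 Ethiopian national survey as the reference
#' condition: 346 enumeration areas in a lon 33-48E, lat 3-15N box; an
#' exponential spatial model for EA-mean serum Se with nugget 2.51,
#' spatially correlated variance 26.23 (ug/L)^2 and distance parameter
#' 132.8 km; a field mean of 103.6 ug/L (the reported WRA median); 3376
#' individual records split YC 584, SAC 1034, MEN 419, WRA 1339; and
#' missingness rates that reproduce, in expectation, the 101 GPS-missing and
#' 5 demographic-missing records of that survey. The within-EA standard
#' deviation (individual-level variation around the EA mean) is not reported
#' anywhere and defaults to 20 ug/L, a realistic serum-biomarker spread.
#'
#' @param n_eas Number of enumeration areas.
#' @param bbox Simulation domain, `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param model An [exp_variogram()] for the EA-mean field.
#' @param field_mean Mean of the EA-level field, ug/L.
#' @param n_per_group Named integer vector of total individuals per
#'   demographic group.
#' @param within_ea_sd Individual-level standard deviation around the EA
#'   mean, ug/L.
#' @param p_missing_gps,p_missing_demographic Per-record missingness
#'   probabilities in `[0, 1]`.
#' @param outliers List describing outlier injection: `n` records set to
#'   `value` ug/L within group `group`.
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_eas = 346,
                       bbox = ethiopia_bbox(),
                       model = exp_variogram(2.51, 26.23, 132.8),
                       field_mean = 103.6,
                       n_per_group = c(YC = 584, SAC = 1034, MEN = 419, WRA = 1339),
                       within_ea_sd = 20,
                       p_missing_gps = 101 / 3376,
                       p_missing_demographic = 5 / 3376,
                       outliers = list(n = 1, group = "WRA", value = 400),
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config() requires an explicit seed", call. = FALSE)
  stopifnot(n_eas >= 2, within_ea_sd >= 0,
            p_missing_gps >= 0, p_missing_gps <= 1,
            p_missing_demographic >= 0, p_missing_demographic <= 1,
            inherits(model, "exp_variogram"))
  structure(list(
    n_eas = n_eas, bbox = bbox, model = model, field_mean = field_mean,
    n_per_group = n_per_group, within_ea_sd = within_ea_sd,
    p_missing_gps = p_missing_gps, p_missing_demographic = p_missing_demographic,
    outliers = outliers, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Uniform enumeration-area locations
#'
#' Draws EA locations uniformly within the bounding box. Uniform placement is
#' a deliberate simplification: the spatial model operates on EA means, so
#' the survey's probability-proportional-to-size selection is outside the
#' generator's scope.
#'
#' @param n_eas Number of locations (`>= 2`).
#' @param bbox Domain box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed.
#' @return Tibble with `lat`, `lon`.
#' @export
simulate_ea_locations <- function(n_eas, bbox = ethiopia_bbox(), seed) {
  if (n_eas < 2) stop("need at least 2 enumeration areas", call. = FALSE)
  if (bbox[["lon_min"]] >= bbox[["lon_max"]] || bbox[["lat_min"]] >= bbox[["lat_max"]]) {
    stop("degenerate bounding box", call. = FALSE)
  }
  local_seed(seed, tibble::tibble(
    lat = stats::runif(n_eas, bbox[["lat_min"]], bbox[["lat_max"]]),
    lon = stats::runif(n_eas, bbox[["lon_min"]], bbox[["lon_max"]])
  ))
}

# Upper-triangular Cholesky factor of the model covariance at the given
# locations: c1 * exp(-h/a) plus the nugget c0 on the diagonal, with a small
# jitter (1e-8 of the sill) for numerical stability.
grf_factor <- function(model, lat, lon, radius = 6378.137) {
  D <- gc_dist_matrix(lat, lon, radius = radius)
  S <- model$c1 * exp(-D / model$a)
  jitter <- 1e-8 * max(model$c0 + model$c1, 1)
  diag(S) <- model$c1 + model$c0 + jitter
  out <- tryCatch(chol(S), error = function(e) {
    stop("covariance matrix not positive definite after jitter: ",
         conditionMessage(e), call. = FALSE)
  })
  out
}

#' Simulate a Gaussian random field at given locations
#'
#' One (or several) draws of a Gaussian field whose spatially correlated
#' component has covariance `c1 * exp(-h / a)` on great-circle distances,
#' plus independent nugget variance `c0`, around a constant mean. Simulation
#' is by Cholesky factorization of the dense covariance matrix, suitable for
#' up to a few thousand locations.
#'
#' @param model An [exp_variogram()].
#' @param lat,lon Location coordinates, decimal degrees.
#' @param mean Field mean, ug/L.
#' @param seed Integer seed.
#' @param n_draws Number of independent field draws (default 1).
#' @param radius Sphere radius in km.
#' @return Numeric vector of field values (or an `n x n_draws` matrix when
#'   `n_draws > 1`).
#' @export
simulate_grf <- function(model, lat, lon, mean = 0, seed, n_draws = 1,
                         radius = 6378.137) {
  n <- length(lat)
  if (n > 3000) stop("dense factorization limited to ~3000 locations", call. = FALSE)
  L <- grf_factor(model, lat, lon, radius = radius)
  Z <- local_seed(seed, matrix(stats::rnorm(n * n_draws), n, n_draws))
  out <- mean + crossprod(L, Z)
  if (n_draws == 1) as.vector(out) else out
}

#' Simulate an individual-level serum selenium survey
#'
#' Generates a full synthetic survey: EA locations, a spatially correlated
#' EA-mean field from [simulate_grf()], individual serum values as EA mean
#' plus independent within-EA noise (re-drawn below 1 ug/L, since serum
#' concentrations are positive), demographic groups allocated round-robin
#' across EAs so realized group totals match the configuration exactly,
#' survey weights, residence, region labels by longitude band, and
#' missingness and outlier injection at the configured rates.
#'
#' @param config A [sim_config()].
#' @return Tibble of survey records in the dialect of [read_survey()], with
#'   the true EA field attached as attribute `"truth"` (tibble of `ea_id`,
#'   `lat`, `lon`, `ea_mean`).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- sum(config$n_per_group)
  if (n_total < config$n_eas) stop("fewer individuals than enumeration areas", call. = FALSE)
  eas <- simulate_ea_locations(config$n_eas, config$bbox, seed = config$seed)
  ea_mean <- simulate_grf(config$model, eas$lat, eas$lon, mean = config$field_mean,
                          seed = config$seed + 1L)
  ea_ids <- sprintf("EA%04d", seq_len(config$n_eas))

  # round-robin allocation: group totals are met exactly, EAs filled evenly
  group <- rep(names(config$n_per_group), config$n_per_group)
  ea_idx <- rep_len(seq_len(config$n_eas), n_total)

  records <- local_seed(config$seed + 2L, {
    se <- ea_mean[ea_idx] + stats::rnorm(n_total, 0, config$within_ea_sd)
    for (it in 1:50) {
      low <- se < 1
      if (!any(low)) break
      se[low] <- ea_mean[ea_idx][low] + stats::rnorm(sum(low), 0, config$within_ea_sd)
    }
    se[se < 1] <- 1
    sex <- ifelse(group == "WRA", "F",
                  ifelse(group == "MEN", "M", sample(c("M", "F"), n_total, TRUE)))
    out <- tibble::tibble(
      person_id = sprintf("P%05d", seq_len(n_total)),
      ea_id = ea_ids[ea_idx],
      region = cut(eas$lon[ea_idx], breaks = 11, labels = paste0("R", 1:11)) |>
        as.character(),
      group = group,
      sex = sex,
      residence = sample(c("urban", "rural"), n_total, TRUE, prob = c(0.26, 0.74)),
      weight = stats::runif(n_total, 0.5, 1.5),
      lat = eas$lat[ea_idx],
      lon = eas$lon[ea_idx],
      serum_se_ugL = se
    )
    miss_gps <- stats::runif(n_total) < config$p_missing_gps
    out$lat[miss_gps] <- NA_real_
    out$lon[miss_gps] <- NA_real_
    miss_dem <- stats::runif(n_total) < config$p_missing_demographic
    out$group[miss_dem] <- NA_character_
    if (config$outliers$n > 0) {
      pool <- which(out$group %in% config$outliers$group & !miss_gps & !miss_dem)
      pick <- sample(pool, min(config$outliers$n, length(pool)))
      out$serum_se_ugL[pick] <- config$outliers$value
    }
    out
  })
  attr(records, "truth") <- tibble::tibble(
    ea_id = ea_ids, lat = eas$lat, lon = eas$lon, ea_mean = ea_mean
  )
  records
}

#' Deterministic fixture with the reference survey's exclusion structure
#'
#' Builds a 3376-record survey whose exclusion structure reproduces the 2015
#' Ethiopian national survey exactly: 101 records with missing GPS
#' coordinates (MEN 5, YC 63, SAC 24, WRA 9), 5 with missing demographic
#' data (SAC 3, WRA 2), and one flagged WRA outlier, leaving 3269 retained
#' records whose composition matches the published participant table (group
#' totals YC 521, SAC 1007, MEN 414, WRA 1327; region totals; 841 urban /
#' 2428 rural). Coordinates, weights and serum values are deterministic, so
#' the fixture is identical on every call; the outlier record carries
#' `person_id` `"OUTLIER"` and an extreme serum value.
#'
#' @return Tibble of survey records.
#' @export
enms_count_fixture <- function() {
  retained_groups <- c(YC = 521L, SAC = 1007L, MEN = 414L, WRA = 1327L)
  gps_missing <- c(YC = 63L, SAC = 24L, MEN = 5L, WRA = 9L)
  dem_missing <- c(YC = 0L, SAC = 3L, MEN = 0L, WRA = 2L)
  outlier <- c(YC = 0L, SAC = 0L, MEN = 0L, WRA = 1L)
  region_counts <- c(
    "Addis Ababa" = 243L, "Afar" = 254L, "Amhara" = 492L,
    "Benishangul-Gumuz" = 213L, "Dire Dawa" = 152L, "Gambela" = 199L,
    "Harari" = 243L, "Oromia" = 523L, "SNNP" = 365L, "Somali" = 204L,
    "Tigray" = 381L
  )
  sex_by_group <- list(  # male counts among retained YC/SAC; MEN male, WRA female
    YC = 284L, SAC = 451L
  )
  groups <- names(retained_groups)

  n_eas <- 346L
  bbox <- ethiopia_bbox()
  side <- ceiling(sqrt(n_eas))
  ea_lat <- bbox[["lat_min"]] + ((seq_len(n_eas) - 1) %/% side + 0.5) *
    (bbox[["lat_max"]] - bbox[["lat_min"]]) / side
  ea_lon <- bbox[["lon_min"]] + ((seq_len(n_eas) - 1) %% side + 0.5) *
    (bbox[["lon_max"]] - bbox[["lon_min"]]) / side

  make_block <- function(g, n, status) {
    if (n == 0) return(NULL)
    tibble::tibble(group = g, status = status, .rows = n)
  }
  blocks <- purrr::map(groups, function(g) dplyr::bind_rows(
    make_block(g, retained_groups[[g]], "retained"),
    make_block(g, gps_missing[[g]], "missing_gps"),
    make_block(g, dem_missing[[g]], "missing_demographic"),
    make_block(g, outlier[[g]], "outlier")
  ))
  df <- dplyr::bind_rows(blocks)
  n <- nrow(df)
  df$person_id <- sprintf("P%04d", seq_len(n))
  df$person_id[df$status == "outlier"] <- "OUTLIER"
  df$ea_id <- sprintf("EA%04d", rep_len(seq_len(n_eas), n))
  df$lat <- ea_lat[rep_len(seq_len(n_eas), n)]
  df$lon <- ea_lon[rep_len(seq_len(n_eas), n)]
  df$lat[df$status == "missing_gps"] <- NA_real_
  df$lon[df$status == "missing_gps"] <- NA_real_

  # deterministic serum values, positive and varied; extreme for the outlier
  df$serum_se_ugL <- 40 + 110 * (seq_len(n) %% 97) / 96
  df$serum_se_ugL[df$status == "outlier"] <- 420

  df$sex <- "F"
  for (g in names(sex_by_group)) {
    idx <- which(df$group == g & df$status == "retained")
    df$sex[idx[seq_len(sex_by_group[[g]])]] <- "M"
  }
  df$sex[df$group == "MEN"] <- "M"

  ret <- which(df$status == "retained")
  df$region <- "Oromia"
  df$region[ret] <- rep(names(region_counts), region_counts)
  df$residence <- "rural"
  df$residence[ret[seq_len(841L)]] <- "urban"
  df$sex[df$status == "missing_demographic"] <- NA_character_
  df$group[df$status == "missing_demographic"] <- NA_character_
  df$weight <- 0.5 + (seq_len(n) %% 10) / 9

  validate_survey(df[, c("person_id", "ea_id", "region", "group", "sex",
                         "residence", "weight", "lat", "lon", "serum_se_ugL")])
}
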