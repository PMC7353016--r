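#' Read a serum selenium survey CSV
#'
#' Reads individual-level survey records from the package's CSV dialect:
#' header `person_id, ea_id, region, group, sex, residence, weight, lat, lon,
#' serum_se_ugL`, UTF-8, decimal point, empty string = missing.
#'
#' @param path Path to the CSV file.
#' @return Tibble of survey records with columns `person_id`, `ea_id`,
#'   `region`, `group`, `sex`, `residence`, `weight`, `lat`, `lon`,
#'   `serum_se_ugL`.
#' @export
read_survey <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      ea_id = readr::col_character(),
      region = readr::col_character(),
      group = readr::col_character(),
      sex = readr::col_character(),
      residence = readr::col_character(),
      weight = readr::col_double(),
      lat = readr::col_double(),
      lon = readr::col_double(),
      serum_se_ugL = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  validate_survey(out)
}

#' Write survey records in the package CSV dialect
#'
#' @param records Tibble of survey records (see [read_survey()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

validate_survey <- function(records) {
  need <- c("person_id", "ea_id", "region", "group", "sex", "residence",
            "weight", "lat", "lon", "serum_se_ugL")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("survey records missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ok_lat <- is.na(records$lat) | (records$lat >= -90 & records$lat <= 90)
  ok_lon <- is.na(records$lon) | (records$lon >= -180 & records$lon <= 180)
  if (!all(ok_lat) || !all(ok_lon)) stop("coordinates outside valid range", call. = FALSE)
  if (any(records$serum_se_ugL <= 0, na.rm = TRUE)) {
    stop("serum Se concentrations must be positive", call. = FALSE)
  }
  if (any(records$weight < 0, na.rm = TRUE)) stop("survey weights must be >= 0", call. = FALSE)
  tibble::as_tibble(records)
}

#' Apply the survey exclusion rules
#'
#' Filters individual records in a fixed precedence so that each record is
#' counted under exactly one exclusion reason: missing GPS coordinates first
#' (either latitude or longitude absent), then missing demographic data
#' (group, sex or residence absent), then flagged marginal outliers. The
#' returned log reconciles exactly: retained + sum of reasons = input.
#'
#' @param records Tibble of survey records.
#' @param outlier_ids Character vector of `person_id`s flagged as marginal
#'   outliers (e.g. by a Tukey-fence screen of the serum distribution).
#' @return List with `records` (the retained tibble) and `log`, an exclusion
#'   log: total counts plus a per-group breakdown tibble.
#' @export
apply_exclusions <- function(records, outlier_ids = character()) {
  records <- validate_survey(records)
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  unknown <- setdiff(outlier_ids, records$person_id)
  if (length(unknown)) {
    stop("unknown outlier id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  reason <- dplyr::case_when(
    is.na(records$lat) | is.na(records$lon) ~ "missing_gps",
    is.na(records$group) | is.na(records$sex) | is.na(records$residence) ~ "missing_demographic",
    records$person_id %in% outlier_ids ~ "outlier",
    TRUE ~ "retained"
  )
  by_group <- tibble::tibble(group = records$group, reason = reason) |>
    dplyr::filter(reason != "retained") |>
    dplyr::count(.data$reason, .data$group, name = "n")
  log <- list(
    n_input = nrow(records),
    n_missing_gps = sum(reason == "missing_gps"),
    n_missing_demographic = sum(reason == "missing_demographic"),
    n_outlier = sum(reason == "outlier"),
    n_retained = sum(reason == "retained"),
    by_group = by_group
  )
  class(log) <- c("exclusion_log", class(log))
  stopifnot(log$n_retained ==
              log$n_input - log$n_missing_gps - log$n_missing_demographic - log$n_outlier)
  list(records = records[reason == "retained", , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion log:", x$n_input, "records in,", x$n_retained, "retained\n")
  cat("  missing GPS:        ", x$n_missing_gps, "\n")
  cat("  missing demographic:", x$n_missing_demographic, "\n")
  cat("  outlier:            ", x$n_outlier, "\n")
  invisible(x)
}

#' Write an exclusion log as JSON
#'
#' @param log An exclusion log from [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Survey-weighted quantiles
#'
#' Weighted quantiles under a cumulative-weight inverse-CDF rule: with values
#' sorted and `P_i` the cumulative weight share up to and including value
#' `x_i`, the `p` quantile is the smallest `x_i` with `P_i >= p`; when `p`
#' falls exactly on a cumulative boundary `P_i` the quantile interpolates
#' midway between `x_i` and the next value, so that with equal weights the
#' weighted median reproduces the ordinary sample median.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, same length as `values`; at least one
#'   must be positive.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(1:4, rep(1, 4), 0.5)  # 2.5
#' @export
weighted_quantile <- function(values, weights, probs) {
  if (length(values) != length(weights)) stop("values and weights lengths differ", call. = FALSE)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]", call. = FALSE)
  keep <- weights > 0 & !is.na(values)
  o <- order(values[keep])
  x <- values[keep][o]
  w <- weights[keep][o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p - 1e-12)[1]
    if (i < length(x) && abs(cw[i] - p) <= 1e-12) (x[i] + x[i + 1]) / 2 else x[i]
  }, numeric(1))
}

#' Weighted prevalence below a deficiency threshold
#'
#' Percentage of the (weighted) population whose serum concentration falls
#' strictly below a threshold.
#'
#' @param values Serum concentrations, ug/L.
#' @param weights Survey weights; defaults to equal weights.
#' @param threshold Deficiency threshold, ug/L.
#' @return Percentage in `[0, 100]`.
#' @examples
#' prevalence_below(c(60, 80, 60), c(1, 1, 2), 70)  # 75
#' @export
prevalence_below <- function(values, weights = rep(1, length(values)), threshold) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) != length(weights)) stop("values and weights lengths differ", call. = FALSE)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  keep <- !is.na(values)
  100 * sum(weights[keep][values[keep] < threshold]) / sum(weights[keep])
}

#' Default serum selenium deficiency thresholds
#'
#' Three thresholds in ug/L: optimal glutathione peroxidase 3 activity
#' (GPx3, 84.9), optimal iodothyronine deiodinase activity (IDI, 64.8), and
#' the conventional deficiency cut-off (70). The GPx3 value is the midpoint
#' of the 1.00-1.15 umol/L optimal-activity range converted with the molar
#' mass of selenium; see [threshold_from_molar_range()].
#'
#' @param gpx3,idi,conventional Threshold values in ug/L.
#' @return Named numeric vector of thresholds.
#' @export
se_thresholds <- function(gpx3 = 84.9, idi = 64.8, conventional = 70) {
  stopifnot(gpx3 > 0, idi > 0, conventional > 0, gpx3 > idi)
  c(gpx3 = gpx3, idi = idi, conventional = conventional)
}

#' Convert a molar serum range to a ug/L threshold
#'
#' Takes the midpoint of a `[lo, hi]` range in umol/L and converts to ug/L
#' using the molar mass of selenium, rounding to 0.1 ug/L. The default molar
#' mass 78.97 g/mol reproduces the GPx3 threshold 84.9 ug/L from the
#' 1.00-1.15 umol/L optimal-activity range.
#'
#' @param lo,hi Range bounds in umol/L, `0 <= lo <= hi`.
#' @param molar_mass Molar mass of Se in g/mol.
#' @return Threshold in ug/L, rounded to one decimal.
#' @examples
#' threshold_from_molar_range(1.00, 1.15)  # 84.9
#' @export
threshold_from_molar_range <- function(lo, hi, molar_mass = 78.97) {
  if (lo < 0 || hi < 0) stop("molar concentrations must be non-negative", call. = FALSE)
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  round((lo + hi) / 2 * molar_mass, 1)
}

#' Tukey fences and outlier flags
#'
#' Computes Tukey's inner (1.5 IQR) and outer (3 IQR) fences from type-7
#' sample quartiles. Values beyond the inner fences are "possible" outliers;
#' values beyond the outer fences are "probable" outliers, the criterion used
#' to screen marginal outliers before variogram estimation.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return List with `inner` and `outer` fences (length-2 `c(lower, upper)`),
#'   and logical vectors `possible` and `probable` flagging values beyond
#'   each fence pair.
#' @export
tukey_fences <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values for Tukey fences", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  inner <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  outer <- c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  list(
    inner = inner,
    outer = outer,
    possible = values < inner[1] | values > inner[2],
    probable = values < outer[1] | values > outer[2]
  )
}

#' Stratified survey summaries of serum selenium
#'
#' One row per stratum with the (optionally survey-weighted) median and
#' quartiles of serum Se and the prevalence of deficiency for each threshold.
#' Records with missing serum values are dropped with a message. Strata with
#' zero eligible records are omitted with a warning.
#'
#' @param records Retained survey records (after [apply_exclusions()]).
#' @param by Stratifier: `"national"`, `"region"` or `"group"`.
#' @param thresholds Named vector of thresholds in ug/L, see [se_thresholds()].
#' @param weighted Use survey weights for quantiles and prevalence (default
#'   `TRUE`); set `FALSE` for unweighted summaries.
#' @return Tibble with columns `stratum`, `n`, `median`, `q1`, `q3` and one
#'   `prevalence_<name>` column per threshold.
#' @export
summarize_se <- function(records, by = c("national", "region", "group"),
                         thresholds = se_thresholds(), weighted = TRUE) {
  by <- match.arg(by)
  records <- validate_survey(records)
  n_miss <- sum(is.na(records$serum_se_ugL))
  if (n_miss > 0) {
    message(n_miss, " record(s) without a serum value dropped from summaries")
    records <- records[!is.na(records$serum_se_ugL), , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records with serum values", call. = FALSE)
  records$stratum <- switch(by,
    national = "National",
    region = records$region,
    group = records$group
  )
  if (anyNA(records$stratum)) {
    warning("records with missing stratum omitted", call. = FALSE)
    records <- records[!is.na(records$stratum), , drop = FALSE]
  }
  w_of <- function(w) if (weighted) w else rep(1, length(w))
  out <- records |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(function(d, key) {
      q <- weighted_quantile(d$serum_se_ugL, w_of(d$weight), c(0.25, 0.5, 0.75))
      prev <- vapply(thresholds, function(t) {
        prevalence_below(d$serum_se_ugL, w_of(d$weight), t)
      }, numeric(1))
      names(prev) <- paste0("prevalence_", names(thresholds))
      dplyr::bind_cols(
        tibble::tibble(n = nrow(d), median = q[2], q1 = q[1], q3 = q[3]),
        tibble::as_tibble_row(prev)
      )
    }) |>
    dplyr::ungroup()
  out
}

#' Aggregate survey records to enumeration-area means
#'
#' Averages serum values and coordinates within each enumeration area (EA),
#' the spatial unit of variography and kriging. Coordinates are averaged as
#' raw degrees: EAs are geographically tiny relative to the spatial scales of
#' interest, so the planar-averaging error is negligible.
#'
#' @param records Survey records; rows without coordinates or serum values
#'   are not eligible and are dropped.
#' @param group Optional demographic group filter (e.g. `"WRA"`).
#' @return Tibble with one row per EA: `ea_id`, `mean_lat`, `mean_lon`,
#'   `mean_se` (ug/L) and `n` contributing individuals.
#' @export
aggregate_by_ea <- function(records, group = NULL) {
  records <- validate_survey(records)
  if (!is.null(group)) records <- records[records$group %in% group, , drop = FALSE]
  eligible <- !is.na(records$lat) & !is.na(records$lon) & !is.na(records$serum_se_ugL)
  records <- records[eligible, , drop = FALSE]
  if (nrow(records) == 0) stop("no eligible records to aggregate", call. = FALSE)
  records |>
    dplyr::group_by(.data$ea_id) |>
    dplyr::summarise(
      mean_lat = mean(.data$lat),
      mean_lon = mean(.data$lon),
      mean_se = mean(.data$serum_se_ugL),
      n = dplyr::n(),
      .groups = "drop"
    )
}
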