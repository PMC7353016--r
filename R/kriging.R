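#' Ordinary kriging weights at a target location
#'
#' Solves the ordinary kriging (OK) system built from the variogram evaluated
#' on great-circle distances: the bordered linear system whose unknowns are
#' the data weights and a Lagrange multiplier enforcing unbiasedness
#' (weights sum to one).
#'
#' @param model An [exp_variogram()] model.
#' @param data EA samples (tibble with `mean_lat`, `mean_lon`, `mean_se` or
#'   `lat`, `lon`, `value`).
#' @param target Length-2 numeric `c(lat, lon)` or one-row data frame.
#' @param radius Sphere radius in km.
#' @return List with `weights` (length `n`), `lagrange`, and the semivariance
#'   vector `gamma0` from each datum to the target.
#' @export
ok_weights <- function(model, data, target, radius = 6378.137) {
  prep <- ok_prepare(model, data, radius)
  if (is.data.frame(target)) {
    t_ll <- latlon_cols(target)
    target <- c(t_ll$lat[1], t_ll$lon[1])
  }
  g0 <- predict(model, gc_distance(prep$lat, prep$lon, target[1], target[2], radius = radius))
  sol <- solve(prep$A, c(g0, 1))
  n <- length(prep$lat)
  list(weights = sol[seq_len(n)], lagrange = sol[n + 1], gamma0 = g0)
}

# Shared set-up for OK solves: collapses duplicate locations to their mean
# (singular otherwise when c0 = 0) and factors nothing yet -- callers decide.
ok_prepare <- function(model, data, radius = 6378.137) {
  xy <- latlon_cols(data)
  z <- if ("mean_se" %in% names(data)) data$mean_se else data$value
  if (is.null(z)) stop("need a mean_se or value column", call. = FALSE)
  if (nrow(xy) < 2) stop("need at least 2 data points", call. = FALSE)
  key <- paste(xy$lat, xy$lon)
  if (anyDuplicated(key)) {
    warning("duplicate locations collapsed to their mean value before kriging",
            call. = FALSE)
    agg <- tibble::tibble(key = key, lat = xy$lat, lon = xy$lon, z = z) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(lat = .data$lat[1], lon = .data$lon[1], z = mean(.data$z),
                       .groups = "drop")
    xy <- tibble::tibble(lat = agg$lat, lon = agg$lon)
    z <- agg$z
  }
  n <- nrow(xy)
  D <- gc_dist_matrix(xy$lat, xy$lon, radius = radius)
  G <- matrix(predict(model, as.vector(D)), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  list(lat = xy$lat, lon = xy$lon, z = z, A = A, G = G)
}

gc_dist_matrix <- function(lat, lon, radius = 6378.137) {
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    d <- gc_distance(lat[i], lon[i], lat[jj], lon[jj], radius = radius)
    D[i, jj] <- d
    D[jj, i] <- d
  }
  D
}

#' Ordinary kriging prediction and variance at target locations
#'
#' Predicts `sum(lambda_i z_i)` with kriging variance
#' `sum(lambda_i gamma(d_i0)) + mu` at each target. With a zero nugget the
#' predictor interpolates exactly: at a data location the prediction equals
#' the datum and the variance is zero.
#'
#' @inheritParams ok_weights
#' @param targets Data frame of target locations with `lat`, `lon` columns.
#' @return Tibble with `lat`, `lon`, `prediction` (ug/L) and
#'   `kriging_variance` ((ug/L)^2; tiny negative round-off is clamped to 0).
#' @export
krige_ok <- function(model, data, targets, radius = 6378.137) {
  prep <- ok_prepare(model, data, radius)
  t_ll <- latlon_cols(targets)
  n <- length(prep$z)
  m <- nrow(t_ll)
  # n x m matrix of data-to-target semivariances; one multi-RHS solve
  G0 <- vapply(seq_len(m), function(k) {
    predict(model, gc_distance(prep$lat, prep$lon, t_ll$lat[k], t_ll$lon[k],
                               radius = radius))
  }, numeric(n))
  G0 <- matrix(G0, nrow = n)
  sol <- solve(prep$A, rbind(G0, 1))
  L <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  tibble::tibble(
    lat = t_ll$lat, lon = t_ll$lon,
    prediction = as.vector(crossprod(L, prep$z)),
    kriging_variance = pmax(colSums(L * G0) + mu, 0)
  )
}

#' Theoretical median of the standardized squared prediction error
#'
#' Under a valid variogram model with Gaussian kriging errors, each
#' standardized squared prediction error `(z - zhat)^2 / sigma^2` is
#' chi-squared on one degree of freedom, whose median is 0.455 (3 dp).
#'
#' @return The 0.5 quantile of the chi-squared distribution with 1 df.
#' @export
sspe_expected_median <- function() stats::qchisq(0.5, df = 1)

# Leave-one-out weight matrix: row i holds the OK weights for predicting
# site i from all others (0 on the diagonal), plus the kriging variance.
# Geometry-only, so it can be reused across simulated fields at the same
# locations.
loo_weights <- function(model, data, radius = 6378.137) {
  prep <- ok_prepare(model, data, radius)
  n <- length(prep$z)
  W <- matrix(0, n, n)
  v <- numeric(n)
  for (i in seq_len(n)) {
    g0 <- prep$G[-i, i]
    A <- rbind(cbind(prep$G[-i, -i], 1), c(rep(1, n - 1), 0))
    sol <- solve(A, c(g0, 1))
    lambda <- sol[seq_len(n - 1)]
    W[i, -i] <- lambda
    v[i] <- max(sum(lambda * g0) + sol[n], 0)
  }
  list(W = W, variance = v, z = prep$z, lat = prep$lat, lon = prep$lon)
}

#' Leave-one-out kriging cross-validation
#'
#' Each observation is removed in turn and predicted from the rest by
#' ordinary kriging under `model`. The squared prediction error at each site
#' is standardized by the kriging variance (SSPE). Under a valid model with
#' Gaussian errors the SSPE is chi-squared(1), so the median SSPE has
#' expected value 0.455; a median well outside a simulation-based validity
#' interval indicates a mis-fitted model.
#'
#' @inheritParams ok_weights
#' @param interval Optional validity interval `c(lo, hi)` for the median SSPE
#'   (e.g. from [sspe_interval()]); when supplied, the report carries a
#'   verdict.
#' @return A `cv_report`: list with `sites` (per-site tibble of observed,
#'   predicted, kriging variance, error and SSPE), `median_sspe`, `interval`
#'   and `verdict` (`"valid"`, `"invalid"` or `NA` when no interval given).
#' @export
loo_cv <- function(model, data, interval = NULL, radius = 6378.137) {
  lw <- loo_weights(model, data, radius)
  n <- length(lw$z)
  if (n < 10) stop("need at least 10 data points for cross-validation", call. = FALSE)
  pred <- as.vector(lw$W %*% lw$z)
  if (any(lw$variance <= 0)) {
    stop("non-positive kriging variance in cross-validation (duplicate locations ",
         "with a zero nugget?)", call. = FALSE)
  }
  err <- lw$z - pred
  sspe <- err^2 / lw$variance
  med <- stats::median(sspe)
  verdict <- NA_character_
  if (!is.null(interval)) {
    verdict <- if (med >= interval[1] && med <= interval[2]) "valid" else "invalid"
  }
  structure(list(
    sites = tibble::tibble(
      lat = lw$lat, lon = lw$lon, observed = lw$z, predicted = pred,
      kriging_variance = lw$variance, error = err, sspe = sspe
    ),
    median_sspe = med,
    interval = interval,
    verdict = verdict
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Leave-one-out kriging cross-validation (", nrow(x$sites), " sites)\n", sep = "")
  cat(sprintf("  median SSPE: %.4f (expected %.3f under a valid model)\n",
              x$median_sspe, sspe_expected_median()))
  if (!is.null(x$interval)) {
    cat(sprintf("  validity interval: [%.3f, %.3f] -> %s\n",
                x$interval[1], x$interval[2], x$verdict))
  }
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$sites

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites),
    median_sspe = x$median_sspe,
    mean_sspe = mean(x$sites$sspe),
    interval_lo = if (is.null(x$interval)) NA_real_ else x$interval[1],
    interval_hi = if (is.null(x$interval)) NA_real_ else x$interval[2],
    verdict = x$verdict
  )
}

#' Export a cross-validation report as CSV + JSON
#'
#' @param report A `cv_report`.
#' @param path CSV path for the per-site table; the summary JSON lands at the
#'   same path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  readr::write_csv(report$sites, path, progress = FALSE)
  jsonlite::write_json(list(
    n_sites = nrow(report$sites),
    median_sspe = report$median_sspe,
    interval = report$interval,
    verdict = report$verdict
  ), sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Monte-Carlo validity interval for the median SSPE
#'
#' Simulates `n_sim` Gaussian random fields under `model` at the actual data
#' locations, cross-validates each by leave-one-out ordinary kriging, and
#' returns the 2.5th and 97.5th percentiles of the median SSPE. Because the
#' kriging weights depend only on the geometry and model, they are computed
#' once and reused across simulations, which makes the interval cheap even
#' for many simulations.
#'
#' @inheritParams ok_weights
#' @param n_sim Number of simulated fields (at least 500).
#' @param seed Integer seed for the simulation.
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
sspe_interval <- function(model, data, n_sim = 1000, seed, radius = 6378.137) {
  if (n_sim < 500) stop("n_sim must be at least 500 for a stable interval", call. = FALSE)
  lw <- loo_weights(model, data, radius)
  n <- length(lw$z)
  L <- grf_factor(model, lw$lat, lw$lon, radius = radius)
  meds <- local_seed(seed, {
    Z <- t(L) %*% matrix(stats::rnorm(n * n_sim), n, n_sim)
    E <- Z - lw$W %*% Z
    S <- E^2 / lw$variance
    apply(S, 2, stats::median)
  })
  stats::quantile(meds, c(0.025, 0.975), names = FALSE, type = 7)
}

#' Select a variogram model by cross-validation
#'
#' Implements the efficiency-first selection procedure: the model fitted to
#' Matheron estimates is cross-validated first, and accepted if its median
#' SSPE lies within the validity interval (the Matheron estimator is the most
#' statistically efficient, so when it is not distorted by outliers it is
#' preferred). Only if it fails are the fits to the robust estimators
#' (Cressie-Hawkins, Dowd) cross-validated, and the candidate whose median
#' SSPE is closest to the theoretical 0.455 is chosen. If no candidate is
#' valid the selection fails explicitly rather than falling back silently.
#'
#' @param fits Named list of `variogram_fit` objects; must include
#'   `"matheron"`, optionally `"cressie_hawkins"` and `"dowd"`.
#' @param data EA samples used for cross-validation.
#' @param n_sim,seed Passed to [sspe_interval()] (one interval per candidate
#'   model, at the same locations).
#' @param radius Sphere radius in km.
#' @return List with `status` (`"ok"` or `"failed"`), `chosen` (estimator
#'   name or `NA`), `model`, and `audit`, a tibble recording every candidate
#'   examined with its median SSPE, interval and verdict.
#' @export
select_model <- function(fits, data, n_sim = 1000, seed, radius = 6378.137) {
  if (!"matheron" %in% names(fits)) stop("candidates must include the Matheron fit",
                                         call. = FALSE)
  audit <- tibble::tibble(estimator = character(), median_sspe = numeric(),
                          interval_lo = numeric(), interval_hi = numeric(),
                          verdict = character())
  examine <- function(name, offset) {
    fit <- fits[[name]]
    iv <- sspe_interval(fit$model, data, n_sim = n_sim, seed = seed + offset,
                        radius = radius)
    cv <- loo_cv(fit$model, data, interval = iv, radius = radius)
    audit <<- dplyr::bind_rows(audit, tibble::tibble(
      estimator = name, median_sspe = cv$median_sspe,
      interval_lo = iv[1], interval_hi = iv[2], verdict = cv$verdict
    ))
    cv
  }
  cv_m <- examine("matheron", 0)
  if (cv_m$verdict == "valid") {
    return(list(status = "ok", chosen = "matheron", model = fits$matheron$model,
                audit = audit))
  }
  robust <- intersect(c("cressie_hawkins", "dowd"), names(fits))
  for (k in seq_along(robust)) examine(robust[k], k)
  valid <- audit$verdict == "valid"
  if (!any(valid)) {
    return(list(status = "failed", chosen = NA_character_, model = NULL, audit = audit))
  }
  cand <- audit[valid, , drop = FALSE]
  pick <- cand$estimator[which.min(abs(cand$median_sspe - sspe_expected_median()))]
  list(status = "ok", chosen = pick, model = fits[[pick]]$model, audit = audit)
}
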