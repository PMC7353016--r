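#' Variogram cloud on great-circle lags
#'
#' All unordered pairs of enumeration-area samples with their great-circle
#' distance (km), folded arrival bearing, and difference in mean serum value.
#'
#' @param ea Tibble of EA samples from [aggregate_by_ea()] (columns
#'   `mean_lat`, `mean_lon`, `mean_se`), or any data frame with `lat`, `lon`
#'   and a `value` column.
#' @param radius Sphere radius in km.
#' @return Tibble with columns `i`, `j`, `distance`, `bearing`, `diff`.
#' @export
build_cloud <- function(ea, radius = 6378.137) {
  z <- if ("mean_se" %in% names(ea)) ea$mean_se else ea$value
  if (is.null(z)) stop("need a mean_se or value column", call. = FALSE)
  if (nrow(ea) < 2) stop("need at least 2 samples", call. = FALSE)
  lags <- pairwise_lags(ea, radius = radius)
  lags$diff <- z[lags$i] - z[lags$j]
  lags
}

#' Default lag bins for an empirical variogram
#'
#' Equal-width bins from 0 to `cutoff_frac` times the maximum inter-point
#' distance. The default cutoff of one third of the maximum distance follows
#' common variography practice: it concentrates the bins at the short and
#' intermediate lags where the empirical variogram is reliable and where the
#' nugget and distance parameter are identified, instead of spending them on
#' long lags whose estimates fluctuate strongly between realizations.
#'
#' @param cloud Variogram cloud from [build_cloud()].
#' @param n_bins Number of bins (default 25).
#' @param cutoff_frac Fraction of the maximum inter-point distance used as
#'   the largest lag (default 1/3).
#' @return Numeric vector of bin edges (length `n_bins + 1`).
#' @export
default_lag_bins <- function(cloud, n_bins = 25, cutoff_frac = 1 / 3) {
  seq(0, max(cloud$distance) * cutoff_frac, length.out = n_bins + 1)
}

#' Empirical variogram by Matheron, Cressie-Hawkins or Dowd estimators
#'
#' Bins the variogram cloud by lag distance and estimates the semivariance in
#' each bin. With pair differences `d` in a bin of `N` pairs:
#'
#' * Matheron (method of moments): `sum(d^2) / (2 N)`.
#' * Cressie-Hawkins (robust to heavy tails):
#'   `(mean(sqrt(|d|)))^4 / (2 (0.457 + 0.494 / N))`.
#' * Dowd (median-based, robust): `2.198 * median(|d|)^2 / 2`.
#'
#' Bins with fewer than `min_pairs` pairs are dropped with a warning; such
#' bins give unstable estimates and would distort the model fit.
#'
#' @param cloud Variogram cloud from [build_cloud()].
#' @param bins Strictly increasing lag bin edges in km; default
#'   [default_lag_bins()].
#' @param estimator One of `"matheron"`, `"cressie_hawkins"`, `"dowd"`.
#' @param min_pairs Minimum pair count for a bin to be reported (default 30).
#' @return An `empirical_variogram`: a tibble with columns `lag` (bin
#'   midpoint, km), `gamma` (semivariance, (ug/L)^2) and `n_pairs`, carrying
#'   the estimator and bin edges as attributes.
#' @export
estimate_variogram <- function(cloud, bins = default_lag_bins(cloud),
                               estimator = c("matheron", "cressie_hawkins", "dowd"),
                               min_pairs = 30) {
  estimator <- match.arg(estimator)
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  keep <- cloud$distance > 0
  cl <- cloud[keep, , drop = FALSE]
  bin <- cut(cl$distance, breaks = bins, labels = FALSE, include.lowest = FALSE)
  cl <- cl[!is.na(bin), , drop = FALSE]
  bin <- bin[!is.na(bin)]
  mids <- (bins[-length(bins)] + bins[-1]) / 2
  est_fun <- switch(estimator,
    matheron = function(d) sum(d^2) / (2 * length(d)),
    cressie_hawkins = function(d) {
      mean(sqrt(abs(d)))^4 / (2 * (0.457 + 0.494 / length(d)))
    },
    dowd = function(d) 2.198 * stats::median(abs(d))^2 / 2
  )
  ub <- sort(unique(bin))
  out <- tibble::tibble(
    lag = mids[ub],
    gamma = vapply(ub, function(b) est_fun(cl$diff[bin == b]), numeric(1)),
    n_pairs = vapply(ub, function(b) sum(bin == b), integer(1))
  )
  thin <- out$n_pairs < min_pairs
  if (any(thin)) {
    warning(sum(thin), " bin(s) under the ", min_pairs, "-pair minimum dropped",
            call. = FALSE)
    out <- out[!thin, , drop = FALSE]
  }
  new_empirical_variogram(out, estimator = estimator, bins = bins)
}

new_empirical_variogram <- function(x, estimator, bins, bearing_class = NA_real_) {
  structure(x,
            estimator = estimator, bins = bins, bearing_class = bearing_class,
            class = c("empirical_variogram", class(x)))
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat("Empirical variogram (", attr(x, "estimator"), " estimator, ",
      nrow(x), " bins)\n", sep = "")
  if (!is.na(attr(x, "bearing_class"))) {
    cat("Direction class centred on", attr(x, "bearing_class"), "degrees\n")
  }
  NextMethod()
}

#' Directional empirical variograms
#'
#' Splits the lag cloud into bearing classes of width `180 / n_classes`
#' degrees (class centres at `0, 180/n, 2*180/n, ...`) and estimates one
#' empirical variogram per class. Comparable class-wise variograms indicate
#' isotropy; a marked difference indicates directional dependence.
#'
#' @inheritParams estimate_variogram
#' @param n_classes Number of direction classes (default 4, i.e. 45-degree
#'   classes centred on 0, 45, 90, 135).
#' @return List of `empirical_variogram` objects, one per class, named by the
#'   class centre in degrees. Classes left with no usable bins are flagged
#'   with a warning and returned empty.
#' @export
directional_variograms <- function(cloud, n_classes = 4,
                                   bins = default_lag_bins(cloud),
                                   estimator = "matheron", min_pairs = 30) {
  if (n_classes < 2) stop("need at least 2 direction classes", call. = FALSE)
  width <- 180 / n_classes
  centres <- (seq_len(n_classes) - 1) * width
  cl <- cloud[!is.na(cloud$bearing), , drop = FALSE]
  cls <- (floor((cl$bearing + width / 2) / width) %% n_classes) + 1
  out <- lapply(seq_len(n_classes), function(k) {
    sub <- cl[cls == k, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("direction class ", centres[k], " has no pairs", call. = FALSE)
      return(new_empirical_variogram(
        tibble::tibble(lag = numeric(), gamma = numeric(), n_pairs = integer()),
        estimator = estimator, bins = bins, bearing_class = centres[k]
      ))
    }
    v <- suppressWarnings(
      estimate_variogram(sub, bins = bins, estimator = estimator, min_pairs = min_pairs)
    )
    attr(v, "bearing_class") <- centres[k]
    v
  })
  names(out) <- paste0(centres, "deg")
  out
}

#' Exponential variogram model
#'
#' The isotropic exponential semivariance model
#' `gamma(h) = c0 + c1 * (1 - exp(-h / a))` for `h > 0`, `gamma(0) = 0`:
#' nugget `c0` (spatially uncorrelated variance, including measurement
#' error), partial sill `c1` (spatially correlated variance) and distance
#' parameter `a` (effective range about `3 a`). The exponential family is a
#' valid (conditionally negative definite) model for great-circle distances
#' on the sphere, which is why it is the model used throughout this package.
#'
#' @param c0 Nugget variance, `>= 0`, (ug/L)^2.
#' @param c1 Partial sill, `>= 0`, (ug/L)^2.
#' @param a Distance parameter, `> 0`, km.
#' @return Object of class `exp_variogram`.
#' @export
exp_variogram <- function(c0, c1, a) {
  if (c0 < 0 || c1 < 0 || a <= 0) {
    stop("require c0 >= 0, c1 >= 0, a > 0", call. = FALSE)
  }
  structure(list(c0 = unname(c0), c1 = unname(c1), a = unname(a)),
            class = "exp_variogram")
}

#' @export
print.exp_variogram <- function(x, ...) {
  cat("Exponential variogram model\n")
  cat(sprintf("  nugget c0:          %.4g (ug/L)^2\n", x$c0))
  cat(sprintf("  partial sill c1:    %.4g (ug/L)^2\n", x$c1))
  cat(sprintf("  distance param a:   %.4g km (effective range ~%.4g km)\n",
              x$a, 3 * x$a))
  invisible(x)
}

#' Evaluate an exponential variogram model
#'
#' @param object An `exp_variogram` model.
#' @param h Lag distances in km, `>= 0`.
#' @param ... Unused.
#' @return Semivariances `gamma(h)`; exactly 0 at `h = 0`.
#' @export
predict.exp_variogram <- function(object, h, ...) {
  if (any(h < 0)) stop("negative lag distance", call. = FALSE)
  ifelse(h == 0, 0, object$c0 + object$c1 * (1 - exp(-h / object$a)))
}

#' Fit an exponential variogram by weighted least squares
#'
#' Minimises `sum_k w_k (gamma_hat_k - gamma(h_k; c0, c1, a))^2` over the
#' model parameters with non-negativity enforced. The default weights are the
#' bin pair counts `n_k`; `weights = "cressie"` uses `n_k / gamma(h_k)^2`,
#' re-evaluated inside the objective. Optimisation runs bounded quasi-Newton
#' (`nlminb`) from several perturbed starts to reduce the risk of a local
#' minimum; the best objective wins.
#'
#' The distance parameter is bounded above by `a_max`, by default one third
#' of the largest empirical lag: the exponential model's effective range is
#' about `3 a`, and a range beyond the span of the empirical variogram is not
#' identifiable from it — unbounded fits drift to arbitrarily large `a` and
#' `c1` whenever a realization's variogram keeps creeping upward at the
#' longest lags.
#'
#' @param emp An `empirical_variogram` (at least 4 usable bins).
#' @param init Optional starting triple `c(c0, c1, a)`. The default is a
#'   method-of-moments guess from the empirical values.
#' @param weights `"npairs"` (default) or `"cressie"`.
#' @param n_starts Number of optimisation starts (default 3).
#' @param a_max Upper bound for the distance parameter, km; default
#'   `max(lag) / 3` (effective range bounded by the variogram span).
#' @return A `variogram_fit`: list with `model` (an [exp_variogram()]),
#'   `objective`, `converged`, `estimator`, `weights` and the fitted bin
#'   table `emp`. `tidy()` and `glance()` methods are available.
#' @export
fit_variogram <- function(emp, init = NULL, weights = c("npairs", "cressie"),
                          n_starts = 3, a_max = NULL) {
  weights <- match.arg(weights)
  emp <- emp[is.finite(emp$gamma), , drop = FALSE]
  if (nrow(emp) < 4) stop("need at least 4 usable bins to fit 3 parameters", call. = FALSE)
  h <- emp$lag
  g <- emp$gamma
  n <- emp$n_pairs
  if (is.null(a_max)) a_max <- max(h) / 3
  if (is.null(init)) {
    sill0 <- max(mean(g[h >= stats::median(h)]), 1e-6)
    c00 <- max(min(g) / 2, 1e-6)
    init <- c(c0 = c00, c1 = max(sill0 - c00, 1e-6), a = a_max / 2)
  }
  if (any(init[1:2] < 0) || init[3] <= 0) stop("init must be positive", call. = FALSE)
  obj <- function(th) {
    gm <- th[1] + th[2] * (1 - exp(-h / th[3]))
    w <- if (weights == "npairs") n else n / pmax(gm, 1e-12)^2
    sum(w * (g - gm)^2)
  }
  lower <- c(0, 0, 1e-6)
  upper <- c(Inf, Inf, a_max)
  starts <- list(init)
  if (n_starts > 1) {
    mult <- rbind(c(0.25, 2, 0.3), c(2, 0.5, 3), c(1, 1, 0.1), c(0.1, 1.5, 1))
    for (k in seq_len(min(n_starts - 1, nrow(mult)))) {
      starts[[k + 1]] <- pmax(init * mult[k, ], lower + 1e-8)
    }
  }
  starts <- lapply(starts, function(s) pmin(s, upper - 1e-9))
  fits <- lapply(starts, function(s) {
    stats::nlminb(s, obj, lower = lower, upper = upper,
                  control = list(iter.max = 500, eval.max = 1000,
                                 rel.tol = 1e-12, x.tol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (!best$convergence %in% c(0, 1)) {
    stop("variogram fit did not converge: ", best$message, call. = FALSE)
  }
  structure(list(
    model = exp_variogram(best$par[1], best$par[2], best$par[3]),
    objective = best$objective,
    converged = best$convergence %in% c(0, 1),
    convergence_code = best$convergence,
    estimator = attr(emp, "estimator"),
    weights = weights,
    emp = tibble::as_tibble(emp)
  ), class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat("Weighted-least-squares variogram fit (", x$estimator, " estimates, ",
      nrow(x$emp), " bins, ", x$weights, " weights)\n", sep = "")
  print(x$model)
  cat(sprintf("  objective: %.6g; converged: %s\n", x$objective, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted variogram model
#'
#' @param x A `variogram_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "partial_sill", "distance_parameter"),
    estimate = c(x$model$c0, x$model$c1, x$model$a),
    unit = c("(ug/L)^2", "(ug/L)^2", "km")
  )
}

#' One-row summary of a variogram fit
#'
#' @param x A `variogram_fit`.
#' @param ... Unused.
#' @return Tibble with the parameters, total sill, effective range,
#'   objective, estimator and convergence flag.
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(
    nugget = x$model$c0, partial_sill = x$model$c1,
    distance_parameter = x$model$a,
    sill = x$model$c0 + x$model$c1, effective_range = 3 * x$model$a,
    objective = x$objective, n_bins = nrow(x$emp),
    estimator = x$estimator, converged = x$converged
  )
}

#' Export an empirical variogram and fit as CSV + JSON
#'
#' Writes the bin table as CSV and (when a fit is supplied) the model
#' parameters and settings as JSON next to it, so published-style variogram
#' figures can be reproduced from the artifacts.
#'
#' @param emp An `empirical_variogram`.
#' @param path CSV output path; the JSON lands at the same path with
#'   extension `.json`.
#' @param fit Optional `variogram_fit`.
#' @return `path`, invisibly.
#' @export
write_variogram <- function(emp, path, fit = NULL) {
  readr::write_csv(tibble::as_tibble(emp), path, progress = FALSE)
  if (!is.null(fit)) {
    jpath <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(list(
      model = list(c0 = fit$model$c0, c1 = fit$model$c1, a = fit$model$a),
      estimator = fit$estimator, weights = fit$weights,
      objective = fit$objective, converged = fit$converged
    ), jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
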