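test_that("the variogram cloud enumerates pair differences", {
  ea <- tibble::tibble(ea_id = c("a", "b"), mean_lat = c(5, 6),
                       mean_lon = c(35, 36), mean_se = c(90, 100), n = 1L)
  cl <- build_cloud(ea)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$diff, -10)
  expect_equal(cl$distance, gc_distance(5, 35, 6, 36))

  const <- make_ea_field(n = 15, seed = 9)
  const$mean_se <- 77
  expect_true(all(build_cloud(const)$diff == 0))

  # brute-force subtraction oracle
  ea2 <- make_ea_field(n = 20, seed = 10)
  cl2 <- build_cloud(ea2)
  for (r in seq_len(nrow(cl2))) {
    expect_equal(cl2$diff[r], ea2$mean_se[cl2$i[r]] - ea2$mean_se[cl2$j[r]])
  }
  expect_error(build_cloud(ea2[1, ]), "at least 2")
})

test_that("estimators reproduce hand-computed bin values", {
  one <- function(d) tibble::tibble(i = 1L, j = 2L, distance = 10,
                                    bearing = 45, diff = d)
  expect_equal(
    estimate_variogram(one(-2), bins = c(0, 20), estimator = "matheron",
                       min_pairs = 1)$gamma, 2)
  expect_equal(
    estimate_variogram(one(4), bins = c(0, 20), estimator = "cressie_hawkins",
                       min_pairs = 1)$gamma,
    16 / (2 * (0.457 + 0.494)))
  three <- tibble::tibble(i = 1:3, j = 4:6, distance = 10, bearing = 45,
                          diff = c(1, -2, 3))
  expect_equal(
    estimate_variogram(three, bins = c(0, 20), estimator = "dowd",
                       min_pairs = 1)$gamma,
    2.198 * 2^2 / 2)
  expect_error(estimate_variogram(one(1), bins = c(0, 20), estimator = "banana"))
  expect_error(estimate_variogram(one(1), bins = c(20, 0)), "increasing")
})

test_that("Matheron estimates equal brute-force pair enumeration", {
  ea <- make_ea_field(n = 25, seed = 14)
  cl <- build_cloud(ea)
  bins <- default_lag_bins(cl, n_bins = 8)
  emp <- suppressWarnings(estimate_variogram(cl, bins = bins, min_pairs = 1))

  # independent oracle: loop every ordered pair once, bin by distance
  n <- nrow(ea)
  oracle <- lapply(seq_len(length(bins) - 1), function(b) c(s = 0, n = 0))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- gc_distance(ea$mean_lat[i], ea$mean_lon[i], ea$mean_lat[j], ea$mean_lon[j])
      b <- findInterval(d, bins, left.open = TRUE)
      if (b >= 1 && b <= length(bins) - 1 && d > bins[1]) {
        oracle[[b]]["s"] <- oracle[[b]]["s"] + (ea$mean_se[i] - ea$mean_se[j])^2
        oracle[[b]]["n"] <- oracle[[b]]["n"] + 1
      }
    }
  }
  for (r in seq_len(nrow(emp))) {
    b <- which.min(abs((bins[-length(bins)] + bins[-1]) / 2 - emp$lag[r]))
    expect_equal(emp$gamma[r], oracle[[b]]["s"] / (2 * oracle[[b]]["n"]),
                 ignore_attr = TRUE)
    expect_equal(emp$n_pairs[r], unname(oracle[[b]]["n"]), ignore_attr = TRUE)
  }
})

test_that("all estimators vanish on a constant field", {
  ea <- make_ea_field(n = 18, seed = 15)
  ea$mean_se <- 100
  cl <- build_cloud(ea)
  for (est in c("matheron", "cressie_hawkins", "dowd")) {
    emp <- suppressWarnings(estimate_variogram(cl, estimator = est, min_pairs = 1))
    expect_true(all(emp$gamma == 0))
  }
})

test_that("robust estimators converge to Matheron for Gaussian differences", {
  withr::with_seed(77, {
    d <- rnorm(4000, 0, 3)
    cl <- tibble::tibble(i = 1L, j = 2L, distance = 50, bearing = 10, diff = d)
    g <- vapply(c("matheron", "cressie_hawkins", "dowd"), function(est) {
      estimate_variogram(cl, bins = c(0, 100), estimator = est, min_pairs = 1)$gamma
    }, numeric(1))
    expect_equal(g[["cressie_hawkins"]] / g[["matheron"]], 1, tolerance = 0.1)
    expect_equal(g[["dowd"]] / g[["matheron"]], 1, tolerance = 0.1)
  })
})

test_that("Dowd resists a single spike where Matheron does not", {
  withr::with_seed(78, {
    d <- rnorm(15, 0, 2)
    spiked <- c(d[-1], 1e4)
    cl <- function(x) tibble::tibble(i = 1L, j = 2L, distance = 50, bearing = 10, diff = x)
    dowd <- function(x) estimate_variogram(cl(x), bins = c(0, 100),
                                           estimator = "dowd", min_pairs = 1)$gamma
    math <- function(x) estimate_variogram(cl(x), bins = c(0, 100),
                                           estimator = "matheron", min_pairs = 1)$gamma
    expect_equal(dowd(spiked) / dowd(d), 1, tolerance = 0.25)
    expect_gt(math(spiked) / math(d), 100)
  })
})

test_that("directional variograms partition the cloud", {
  ea <- make_ea_field(n = 30, seed = 16)
  cl <- build_cloud(ea)
  full_bins <- seq(0, max(cl$distance) * 1.01, length.out = 9)
  dvs <- suppressWarnings(directional_variograms(cl, n_classes = 4,
                                                 bins = full_bins, min_pairs = 1))
  expect_length(dvs, 4)
  expect_equal(sum(vapply(dvs, function(v) sum(v$n_pairs), numeric(1))),
               nrow(cl))

  # pairs aligned east-west populate only the 90-degree class
  ew <- tibble::tibble(ea_id = letters[1:5], mean_lat = 10,
                       mean_lon = seq(35, 39), mean_se = rnorm(5, 100), n = 1L)
  dv_ew <- suppressWarnings(directional_variograms(build_cloud(ew),
                                                   n_classes = 4, min_pairs = 1))
  pops <- vapply(dv_ew, function(v) sum(v$n_pairs), numeric(1))
  expect_equal(unname(pops[c("0deg", "45deg", "135deg")]), c(0, 0, 0))
  expect_gt(pops[["90deg"]], 0)
  expect_error(directional_variograms(cl, n_classes = 1), "at least 2")
})

test_that("class-wise estimates agree under isotropy", {
  ea <- make_ea_field(n = 200, model = exp_variogram(0.5, 25, 200), seed = 17)
  cl <- build_cloud(ea)
  bins <- seq(0, 700, length.out = 8)
  dvs <- suppressWarnings(directional_variograms(cl, n_classes = 4, bins = bins,
                                                 min_pairs = 10))
  # mean semivariance over mid-range lags, per class, within a factor ~2
  mids <- vapply(dvs, function(v) mean(v$gamma[v$lag > 200]), numeric(1))
  expect_lt(max(mids) / min(mids), 2.5)
})

test_that("the exponential model evaluates and validates", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  expect_equal(predict(m, 0), 0)
  expect_equal(predict(m, 1e9), 2.51 + 26.23, tolerance = 1e-9)
  expect_equal(predict(m, 132.8), 2.51 + 26.23 * (1 - exp(-1)))
  h <- seq(0, 2000, by = 10)
  g <- predict(m, h)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g <= m$c0 + m$c1))
  expect_error(predict(m, -1), "negative")
  expect_error(exp_variogram(-1, 1, 1))
  expect_error(exp_variogram(1, 1, 0))
})

test_that("WLS fitting recovers noiseless parameters exactly", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  h <- seq(20, 600, length.out = 12)
  emp <- as_emp(h, predict(m, h))
  f <- fit_variogram(emp)
  expect_equal(f$model$c0, m$c0, tolerance = 1e-6)
  expect_equal(f$model$c1, m$c1, tolerance = 1e-6)
  expect_equal(f$model$a, m$a, tolerance = 1e-6)
  expect_true(f$converged)

  # flat empirical variogram collapses to a pure-nugget model
  f0 <- fit_variogram(as_emp(h, rep(7, 12)))
  expect_equal(f0$model$c0, 7, tolerance = 1e-4)
  expect_equal(f0$model$c1, 0, tolerance = 1e-4)

  expect_error(fit_variogram(as_emp(h[1:3], predict(m, h[1:3]))), "at least 4")
  expect_error(fit_variogram(emp, init = c(-1, 1, 1)), "positive")
})

test_that("tidy and glance expose the fitted parameters", {
  m <- exp_variogram(1, 20, 150)
  h <- seq(25, 640, length.out = 10)
  f <- fit_variogram(as_emp(h, predict(m, h)))
  td <- tidy(f)
  expect_equal(td$term, c("nugget", "partial_sill", "distance_parameter"))
  expect_equal(td$estimate, c(1, 20, 150), tolerance = 1e-5)
  gl <- glance(f)
  expect_equal(gl$sill, 21, tolerance = 1e-5)
  expect_equal(gl$effective_range, 450, tolerance = 1e-4)
  expect_equal(gl$estimator, "matheron")
})
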