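test_that("OK weights solve the kriging system", {
  m <- exp_variogram(0, 20, 150)
  ea <- make_ea_field(n = 10, seed = 30)

  # target on a datum with zero nugget: that datum carries all the weight
  w <- ok_weights(m, ea, c(ea$mean_lat[4], ea$mean_lon[4]))
  expect_equal(w$weights[4], 1, tolerance = 1e-8)
  expect_equal(sum(abs(w$weights[-4])), 0, tolerance = 1e-8)

  # two data symmetric about the target share the weight equally
  two <- tibble::tibble(ea_id = c("a", "b"), mean_lat = c(10, 10),
                        mean_lon = c(38, 40), mean_se = c(90, 110), n = 1L)
  w2 <- ok_weights(m, two, c(10, 39))
  expect_equal(w2$weights, c(0.5, 0.5), tolerance = 1e-10)

  # five-point configuration against an independent dense solve
  m2 <- exp_variogram(3, 15, 120)
  five <- make_ea_field(n = 5, seed = 31)
  target <- c(9, 40)
  w5 <- ok_weights(m2, five, target)
  n <- 5
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) {
      G[i, j] <- m2$c0 + m2$c1 *
        (1 - exp(-gc_distance(five$mean_lat[i], five$mean_lon[i],
                              five$mean_lat[j], five$mean_lon[j]) / m2$a))
    }
  }
  g0 <- m2$c0 + m2$c1 *
    (1 - exp(-gc_distance(five$mean_lat, five$mean_lon, target[1], target[2]) / m2$a))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- solve(A, c(g0, 1))
  expect_equal(w5$weights, sol[1:n], tolerance = 1e-10)
  expect_equal(w5$lagrange, sol[n + 1], tolerance = 1e-10)
})

test_that("weights sum to one at every target", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  ea <- make_ea_field(n = 40, seed = 32)
  withr::with_seed(33, {
    for (k in 1:15) {
      tg <- c(runif(1, 3, 15), runif(1, 33, 48))
      w <- ok_weights(m, ea, tg)
      expect_lt(abs(sum(w$weights) - 1), 1e-10)
    }
  })
})

test_that("kriging predictions behave at data, far away, and under shifts", {
  m <- exp_variogram(0, 26.23, 132.8)
  ea <- make_ea_field(n = 30, seed = 34)

  # constant data predict the constant everywhere, for any model
  eac <- ea; eac$mean_se <- 88
  grid <- tibble::tibble(lat = c(4, 9, 14), lon = c(34, 40, 47))
  pc <- krige_ok(exp_variogram(5, 10, 200), eac, grid)
  expect_equal(pc$prediction, rep(88, 3))

  # exact interpolation with zero nugget
  p0 <- krige_ok(m, ea, tibble::tibble(lat = ea$mean_lat[1:3], lon = ea$mean_lon[1:3]))
  expect_equal(p0$prediction, ea$mean_se[1:3], tolerance = 1e-8)
  expect_equal(p0$kriging_variance, rep(0, 3), tolerance = 1e-8)

  # far target (h >> a): prediction near the generalized data mean, variance
  # at the full-sill level of the direct solve
  far <- tibble::tibble(lat = -60, lon = -120)
  pf <- krige_ok(m, ea, far)
  w <- ok_weights(m, ea, c(-60, -120))
  expect_equal(pf$prediction, sum(w$weights * ea$mean_se), tolerance = 1e-8)
  expect_gt(pf$kriging_variance, m$c0 + m$c1)

  # adding a constant passes through; variance unchanged
  ea2 <- ea; ea2$mean_se <- ea$mean_se + 50
  p1 <- krige_ok(m, ea, grid)
  p2 <- krige_ok(m, ea2, grid)
  expect_equal(p2$prediction, p1$prediction + 50, tolerance = 1e-8)
  expect_equal(p2$kriging_variance, p1$kriging_variance, tolerance = 1e-10)

  # variance bounded on tested configurations
  big <- krige_ok(m, ea, make_grid(ethiopia_bbox(), 200))
  expect_true(all(big$kriging_variance >= 0))
  expect_true(all(big$kriging_variance <= 2 * (m$c0 + m$c1)))
})

test_that("duplicate locations collapse with a warning", {
  ea <- make_ea_field(n = 8, seed = 35)
  dup <- dplyr::bind_rows(ea, ea[1, ])
  expect_warning(p <- krige_ok(exp_variogram(0, 10, 100), dup,
                               tibble::tibble(lat = 9, lon = 40)),
                 "duplicate")
  expect_true(is.finite(p$prediction))
})

test_that("two-point leave-one-out matches the closed form", {
  m <- exp_variogram(1.5, 12, 90)
  two <- tibble::tibble(ea_id = c("a", "b"), mean_lat = c(8, 10),
                        mean_lon = c(38, 39), mean_se = c(85, 115), n = 1L)
  lw <- selmapr:::loo_weights(m, two)
  d <- gc_distance(8, 38, 10, 39)
  gd <- m$c0 + m$c1 * (1 - exp(-d / m$a))
  # single remaining datum: weight 1, variance 2 * gamma(d)
  expect_equal(lw$W[1, 2], 1, tolerance = 1e-12)
  expect_equal(lw$W[2, 1], 1, tolerance = 1e-12)
  expect_equal(lw$variance, c(2 * gd, 2 * gd), tolerance = 1e-10)
  sspe <- (two$mean_se - c(115, 85))^2 / (2 * gd)
  expect_equal(sspe[1], (85 - 115)^2 / (2 * gd))
})

test_that("SSPE is invariant to joint scaling of data and variance parameters", {
  m <- exp_variogram(1.5, 12, 90)
  ea <- make_ea_field(n = 15, model = m, mean = 0, seed = 36)
  cv1 <- loo_cv(m, ea)
  k2 <- 9
  ea2 <- ea; ea2$mean_se <- ea$mean_se * sqrt(k2)
  cv2 <- loo_cv(exp_variogram(m$c0 * k2, m$c1 * k2, m$a), ea2)
  expect_equal(cv2$sites$sspe, cv1$sites$sspe, tolerance = 1e-8)
  expect_equal(cv2$median_sspe, cv1$median_sspe, tolerance = 1e-8)
})

test_that("cross-validation under the true model is calibrated", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  ea <- make_ea_field(n = 120, model = m, seed = 37)
  iv <- sspe_interval(m, ea, n_sim = 600, seed = 38)
  expect_lt(iv[1], sspe_expected_median())
  expect_gt(iv[2], sspe_expected_median())
  cv <- loo_cv(m, ea, interval = iv)
  expect_equal(cv$verdict, "valid")
  expect_equal(cv$median_sspe, median(cv$sites$sspe))
  expect_true(all(cv$sites$sspe >= 0))
  expect_error(loo_cv(m, ea[1:5, ]), "at least 10")
})

test_that("the SSPE interval is deterministic given a seed and narrows with n", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  ea_small <- make_ea_field(n = 40, seed = 39)
  iv1 <- sspe_interval(m, ea_small, n_sim = 600, seed = 40)
  iv2 <- sspe_interval(m, ea_small, n_sim = 600, seed = 40)
  expect_identical(iv1, iv2)
  ea_big <- make_ea_field(n = 160, seed = 41)
  iv3 <- sspe_interval(m, ea_big, n_sim = 600, seed = 40)
  expect_lt(diff(iv3), diff(iv1))
  expect_error(sspe_interval(m, ea_small, n_sim = 100, seed = 1), "at least 500")
})

test_that("model selection follows the efficiency-first rule", {
  m <- exp_variogram(2.51, 26.23, 132.8)
  ea <- make_ea_field(n = 80, model = m, seed = 42)
  fake_fit <- function(model, est) {
    structure(list(model = model, objective = 0, converged = TRUE,
                   estimator = est, weights = "npairs",
                   emp = tibble::tibble()), class = "variogram_fit")
  }
  # truth as the Matheron candidate: accepted without touching the others
  fits <- list(matheron = fake_fit(m, "matheron"),
               cressie_hawkins = fake_fit(exp_variogram(50, 1, 10), "cressie_hawkins"),
               dowd = fake_fit(exp_variogram(0.1, 80, 900), "dowd"))
  sel <- select_model(fits, ea, n_sim = 600, seed = 43)
  expect_equal(sel$status, "ok")
  expect_equal(sel$chosen, "matheron")
  expect_equal(nrow(sel$audit), 1)

  # a badly wrong Matheron model fails; the near-truth robust fit is chosen
  fits2 <- list(matheron = fake_fit(exp_variogram(900, 1, 10), "matheron"),
                cressie_hawkins = fake_fit(exp_variogram(40, 250, 700), "cressie_hawkins"),
                dowd = fake_fit(m, "dowd"))
  sel2 <- select_model(fits2, ea, n_sim = 600, seed = 44)
  expect_equal(sel2$status, "ok")
  expect_equal(sel2$chosen, "dowd")
  expect_equal(nrow(sel2$audit), 3)

  # every candidate invalid: explicit failure, all medians reported
  fits3 <- list(matheron = fake_fit(exp_variogram(900, 1, 10), "matheron"),
                cressie_hawkins = fake_fit(exp_variogram(500, 1, 10), "cressie_hawkins"),
                dowd = fake_fit(exp_variogram(700, 1, 10), "dowd"))
  sel3 <- select_model(fits3, ea, n_sim = 600, seed = 45)
  expect_equal(sel3$status, "failed")
  expect_true(is.na(sel3$chosen))
  expect_equal(nrow(sel3$audit), 3)
  expect_error(select_model(fits3[-1], ea, n_sim = 600, seed = 1), "Matheron")
})
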