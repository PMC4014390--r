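test_that("fit_spline with zero smoothing interpolates the means exactly
           and matches a hand-built natural cubic spline", {
  # collinear means reproduce the line at the knots
  lin <- data.frame(time_min = c(0, 10, 20, 40, 60),
                    mean = 0.1 * c(0, 10, 20, 40, 60) + 1)
  cl <- fit_spline(lin, smoothing = 0)
  expect_equal(cl$fun(lin$time_min), lin$mean, tolerance = 1e-12)
  # natural spline reproduces a line everywhere, not only at knots
  expect_equal(cl$fun(c(5, 33)), 0.1 * c(5, 33) + 1, tolerance = 1e-10)

  # independent oracle: natural cubic spline built from the tridiagonal
  # second-derivative system, evaluated as piecewise polynomials
  x <- c(0, 5, 12, 25, 40, 60)
  y <- c(0.2, 1.0, 0.8, 0.5, 0.35, 0.3)
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n); b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m2 <- solve(A, b)    # second derivatives at the knots
  oracle <- function(t) {
    vapply(t, function(tt) {
      i <- max(1, min(n - 1, findInterval(tt, x)))
      dl <- x[i + 1] - tt; dr <- tt - x[i]
      (m2[i] * dl^3 + m2[i + 1] * dr^3) / (6 * h[i]) +
        (y[i] / h[i] - m2[i] * h[i] / 6) * dl +
        (y[i + 1] / h[i] - m2[i + 1] * h[i] / 6) * dr
    }, numeric(1))
  }
  curve <- fit_spline(data.frame(time_min = x, mean = y), smoothing = 0)
  tt <- seq(0, 60, length.out = 601)
  ise <- mean((curve$fun(tt) - oracle(tt))^2) * 60
  expect_lt(ise, 1e-10)

  expect_error(fit_spline(data.frame(time_min = c(0, 1, 2),
                                     mean = c(0, 1, 0))), "at least 4")
})

test_that("auto-smoothed splines stay within one SEM of the replicate
           means", {
  for (nm in c("erk_p", "cjun_p")) {
    d <- generate_dataset(canonical_shapes()[[nm]],
                          c(0, 3, 5, 10, 20, 30, 45, 60, 90, 120),
                          n_reps = 4, noise_cv = 0.1, seed = 21)
    curve <- fit_spline(d, smoothing = "auto")
    expect_true(all(abs(curve$fun(d$time_min) - d$mean) <= d$sem + 1e-9),
                label = nm)
  }
})

test_that("the synthetic ERK dataset peaks where the measurements do", {
  d <- generate_dataset(canonical_shapes()$erk_p,
                        c(0, 1, 2, 3, 4, 5, 7, 10, 15, 20, 30, 60),
                        n_reps = 3, noise_cv = 0.1, seed = 4)
  curve <- fit_spline(d)
  tt <- seq(0, 60, by = 0.1)
  expect_true(tt[which.max(curve$fun(tt))] >= 2 &&
                tt[which.max(curve$fun(tt))] <= 5)
})

test_that("feature target validation rejects malformed tables and bounds", {
  expect_error(feature_targets("erk_p", "nope", target = 1), "feature")
  expect_error(feature_targets("erk_p", "fraction_of_max_at_min",
                               argument = 60, target = 1.4), "fraction")
  expect_error(feature_targets("erk_p", "peak_time_min", target = 3,
                               weight = 0), "weights")
  tg <- feature_targets("erk_p", "peak_time_min", target = 3)
  expect_error(calibrate_submodel(tg, character(), "BASE"), "free_params")
  expect_error(calibrate_submodel(tg, "d_erk", "BASE",
                                  bounds = list(d_erk = c(2e-3, 1e-3))),
               "positive interval")
})

test_that("calibration recovers the generating rates of each signalling
           sub-model within 5%", {
  cases <- list(
    list(variant = "BASE", obs = "erk_p", free = c("k2", "d_erk"),
         times = c(10, 30, 60)),
    list(variant = "EXT2_RTF", obs = "rsk_p", free = c("k9", "d10"),
         times = c(10, 20, 30, 60)),
    list(variant = "BASE", obs = "tf_p_atf3_promoter",
         free = c("k5", "km5"), times = c(5, 20, 60)))
  for (cs in cases) {
    truth <- default_parameters(cs$variant)
    tg <- recovery_targets(cs$variant, cs$obs, cs$times)
    start <- truth
    fac <- c(3, 1 / 3)
    for (i in seq_along(cs$free)) {
      start <- apply_override(start, cs$free[i], fac[i])
    }
    fit <- calibrate_submodel(tg, cs$free, cs$variant, params = start)
    for (nm in cs$free) {
      expect_lt(abs(param_value(fit, nm) / param_value(truth, nm) - 1),
                0.05, label = paste(cs$variant, nm))
      expect_equal(fit$provenance[match(nm, fit$name)], "FITTED")
    }
    expect_lt(attr(fit, "residual"), 1e-6)
  }
})

test_that("calibration is deterministic from a fixed start", {
  tg <- recovery_targets("BASE", "erk_p", c(10, 60))
  start <- apply_override(default_parameters("BASE"), "d_erk", 2)
  f1 <- calibrate_submodel(tg, "d_erk", "BASE", params = start)
  f2 <- calibrate_submodel(tg, "d_erk", "BASE", params = start)
  expect_identical(param_value(f1, "d_erk"), param_value(f2, "d_erk"))
})

test_that("a faster dephosphorylation rate never increases the remaining
           fraction at a fixed post-peak time", {
  fr60 <- vapply(c(0.1, 1, 10), function(fc) {
    p <- apply_override(default_parameters("BASE"), "km5", fc)
    tc <- simulate_model("BASE", p, duration_h = 1.5, n_points = 181)
    f <- extract_features(time_min(tc),
                          observable(tc, "tf_p_atf3_promoter"),
                          query_times = 60)
    unname(f$fraction_of_peak[1])
  }, numeric(1))
  expect_true(all(diff(fr60) <= 1e-9))
})

test_that("calibration reports serialise as JSON", {
  tg <- recovery_targets("BASE", "erk_p", c(10, 60))
  start <- apply_override(default_parameters("BASE"), "d_erk", 1.5)
  fit <- calibrate_submodel(tg, "d_erk", "BASE", params = start)
  path <- withr_local_tempfile(".json")
  write_calibration_report(fit, "d_erk", path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$fitted$d_erk, param_value(fit, "d_erk"),
               tolerance = 1e-12)
  expect_true(rep$residual >= 0)
})
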