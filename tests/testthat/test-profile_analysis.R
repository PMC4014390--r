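test_that("extract_features matches closed forms on analytic pulses", {
  # triangle: basal 0, rises to 1 at 30 min, back to 0 at 60 min;
  # threshold 0.1 is crossed at 30 + 0.9*30 = 57 min
  tm <- 0:90
  tri <- pmax(pmin(tm / 30, (60 - tm) / 30), 0)
  f <- extract_features(tm, tri, basal = 0, query_times = c(45, 57),
                        basal_threshold = 0.1)
  expect_equal(f$peak_time, 30)
  expect_equal(f$return_to_basal_time, 57)
  expect_equal(unname(f$fraction_of_peak), c(0.5, 0.1), tolerance = 1e-12)

  # single exponential decay from the peak at t = 0: e^{-t/20}
  tm2 <- seq(0, 120, by = 0.5)
  ex <- exp(-tm2 / 20)
  f2 <- extract_features(tm2, ex, basal = 0, query_times = 20,
                         basal_threshold = 0.1)
  expect_equal(f2$peak_time, 0)
  expect_equal(unname(f2$fraction_of_peak), exp(-1), tolerance = 1e-12)
  # analytic crossing at 20*log(10) = 46.05; grid step 0.5
  expect_lt(abs(f2$return_to_basal_time - 20 * log(10)), 0.5 + 1e-9)
})

test_that("degenerate profiles get the flat flag, not divisions by zero", {
  f <- extract_features(0:10, rep(2, 11), query_times = 5)
  expect_true(f$flat)
  expect_true(is.na(f$peak_time))
  expect_true(is.na(f$fraction_of_peak[1]))
  # declining-only series with basal set to the first value is flat too
  f2 <- extract_features(0:10, seq(1, 0, length.out = 11))
  expect_true(f2$flat)
  expect_error(extract_features(numeric(), numeric()), "empty")
  expect_error(extract_features(0:10, rep(1, 11), basal_threshold = 1.2),
               "basal_threshold")
})

test_that("fractions are clipped to [0, 1] and peak ties break earliest", {
  tm <- 0:10
  v <- c(0, 1, 1, 1, 0, -0.5, 0, 0, 0, 0, 0)
  f <- extract_features(tm, v, basal = 0, query_times = c(2, 5))
  expect_equal(f$peak_time, 1)                 # earliest of the tied maxima
  expect_equal(unname(f$fraction_of_peak), c(1, 0))  # -0.5 clips to 0
})

test_that("normalize_to_max: examples, idempotence, scale invariance,
           all-zero error", {
  expect_equal(normalize_to_max(c(0, 2, 4)), c(0, 0.5, 1))
  s <- c(0.3, 2.5, 1.1)
  expect_equal(normalize_to_max(normalize_to_max(s)), normalize_to_max(s))
  expect_equal(normalize_to_max(s * 17), normalize_to_max(s))
  expect_error(normalize_to_max(c(0, 0)), "maximum")
})

test_that("profile_distance: zero on self, scale invariant, hand-computed
           3-point value", {
  ds <- generate_dataset(canonical_shapes()$erk_p,
                         times = c(0, 3, 10, 30, 60, 120),
                         noise_cv = 0, seed = 1)
  curve <- fit_spline(ds)
  tm <- seq(0, 120, by = 1)
  self <- curve$fun(tm)
  d1 <- profile_distance(tm, self, curve, c(3, 30, 90))
  expect_lt(d1, 1e-4)   # only grid-discretisation of the two maxima remains
  s <- self * 3.7       # distance uses max-normalised profiles
  expect_equal(profile_distance(tm, s, curve, c(3, 30, 90)), d1,
               tolerance = 1e-9)
  # hand-computed toy case: model {0, 1, 0.5}, curve values {0, 2, 2} at
  # the same times -> normalised diffs {0, 0, -0.5}, distance 0.25
  toy_curve <- list(fun = function(t) approx(c(0, 10, 20, 30),
                                             c(0, 2, 2, 2), xout = t)$y,
                    support = c(0, 30),
                    knots = data.frame(time_min = c(0, 10, 20, 30),
                                       value = c(0, 2, 2, 2)))
  class(toy_curve) <- "smooth_curve"
  d <- profile_distance(c(0, 10, 20), c(0, 1, 0.5), toy_curve,
                        c(0, 10, 20))
  expect_equal(d, 0.25, tolerance = 1e-12)
  expect_error(profile_distance(tm, self, curve, numeric()), "empty")
  expect_error(profile_distance(tm, self, curve, 500), "support")
})

test_that("behaviour flags reproduce the headline scenario contrasts", {
  tc_base <- cached_sim("BASE", duration_h = 4)
  p_nofb <- .zero_params(default_parameters("BASE"), "k4")
  tc_nofb <- simulate_model("BASE", p_nofb, duration_h = 4, n_points = 241)
  fl <- qualitative_flags(list(base = tc_base, no_feedback = tc_nofb))
  expect_true(fl$egr1_acutely_inhibited[fl$scenario == "base"])
  expect_true(fl$egr1_sustained[fl$scenario == "no_feedback"])
  expect_false(fl$egr1_acutely_inhibited[fl$scenario == "no_feedback"])
})

test_that("headline flag conclusions are stable to +/-50% threshold
           variation", {
  tcs <- list(
    base = cached_sim("BASE", duration_h = 4),
    ext1_tight = simulate_model(
      "EXT1_AUTOREP",
      apply_override(default_parameters("EXT1_AUTOREP"), "lambda1", 1e6),
      duration_h = 4, n_points = 241),
    ext4_d8x4 = simulate_model(
      "EXT4_MIRNA",
      .set_value(default_parameters("EXT4_MIRNA"), "d8_mult", 4),
      duration_h = 4, n_points = 241))
  for (scale in c(0.5, 1, 1.5)) {
    th <- lapply(flag_thresholds(), `*`, scale)
    th$egr1_sustained <- min(th$egr1_sustained, 0.99)
    fl <- qualitative_flags(tcs, th)
    expect_true(fl$egr1_acutely_inhibited[fl$scenario == "base"],
                label = paste("base acute at scale", scale))
    expect_false(fl$egr1_acutely_inhibited[fl$scenario == "ext1_tight"],
                 label = paste("ext1 lost at scale", scale))
    expect_true(fl$atf3_protein_terminated[fl$scenario == "ext4_d8x4"],
                label = paste("protein terminated at scale", scale))
    expect_true(fl$atf3_mrna_transient[fl$scenario == "ext4_d8x4"],
                label = paste("mrna transient at scale", scale))
  }
})
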