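test_that("stimulated BASE dynamics: ERK-P pulses early and decays; zero
           stimulus stays at basal", {
  tc <- cached_sim("BASE", duration_h = 2, n_points = 241)
  erk <- observable(tc, "erk_p")
  expect_lt(time_min(tc)[which.max(erk)], 10)
  expect_lt(erk[length(erk)], 0.1 * max(erk))
  p0 <- .set_stimulus_off(default_parameters("BASE"))
  tc0 <- simulate_model("BASE", p0, duration_h = 1, n_points = 61)
  expect_true(all(apply(tc0$states, 2, function(s) diff(range(s)) <= 1e-9)))
})

test_that("conservation laws hold along trajectories to solver tolerance", {
  for (v in c("BASE", "EXT2_RTF", "EXT5_COMBINED")) {
    tc <- cached_sim(v, duration_h = 4)
    for (pool in conserved_pools(v)) {
      tot <- rowSums(tc$states[, pool, drop = FALSE])
      expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6,
                label = paste(v, paste(pool, collapse = "+")))
    }
  }
})

test_that("no species goes negative on the reproduction scenarios", {
  for (cfg in paper_scenarios(duration_h = 4)[c("base", "ext1_tight_binding",
                                                "ext4_d8x4", "ext5_d8x1")]) {
    res <- run_scenario(cfg)
    expect_gt(min(res$timecourse$states), -1e-9)
  }
})

test_that("solver tolerances are converged: halving changes nothing above
           1e-6 relative", {
  tc1 <- simulate_model("BASE", duration_h = 2, n_points = 121)
  tc2 <- simulate_model("BASE", duration_h = 2, n_points = 121,
                        rtol = 5e-9, atol = 5e-13)
  rel <- abs(tc1$states - tc2$states) / pmax(abs(tc1$states), 1e-6)
  expect_lt(max(rel), 1e-6)
})

test_that("grid refinement changes interpolants by less than 1e-4 relative", {
  # grids fine enough that linear interpolation resolves the 3-min ERK peak
  tc1 <- cached_sim("BASE", duration_h = 1, n_points = 1441)
  tc2 <- cached_sim("BASE", duration_h = 1, n_points = 2881)
  # past the quadratic launch from the exact zero state (t < ~2 min),
  # which would need sub-second sampling to interpolate to this accuracy
  keep <- tc2$time >= 120
  for (obs in c("erk_p", "atf3_mrna_total", "egr1_mrna")) {
    s1 <- approx(tc1$time, observable(tc1, obs), xout = tc2$time)$y
    s2 <- observable(tc2, obs)
    expect_lt(max(abs(s1 - s2)[keep]) / max(s2), 1e-4, label = obs)
  }
})

test_that("each extension collapses to BASE when its specific rates are
           zeroed", {
  tcb <- cached_sim("BASE", duration_h = 2, n_points = 121)
  zero_sets <- list(
    EXT1_AUTOREP = c("lambda1", "lambda_m1"),
    EXT2_RTF = c("lambda2", "lambda_m2"),
    EXT3_ITF = c("k13", "k15", "km15"),
    EXT4_MIRNA = c("k17", "k19"),
    EXT5_COMBINED = c("k13", "k15", "km15", "k17", "k19"))
  for (v in names(zero_sets)) {
    p <- .zero_params(default_parameters(v), zero_sets[[v]])
    tc <- simulate_model(v, p, duration_h = 2, n_points = 121)
    for (sp in species_names("BASE")) {
      rel <- max(abs(tc$states[, sp] - tcb$states[, sp])) /
        max(max(abs(tcb$states[, sp])), 1e-12)
      expect_lt(rel, 1e-6, label = paste(v, sp))
    }
  }
})

test_that("disabling Atf3 feedback sustains Egr1 mRNA over 2 h", {
  p <- .zero_params(default_parameters("BASE"), "k4")
  tc <- simulate_model("BASE", p, duration_h = 2, n_points = 121)
  egr1 <- observable(tc, "egr1_mrna")
  expect_gt(egr1[length(egr1)], 0.5 * max(egr1))
})

test_that("tight Atf3 own-promoter binding lowers peak Atf3 protein and
           releases Egr1 from acute inhibition", {
  tc_def <- cached_sim("EXT1_AUTOREP", duration_h = 4)
  p_tight <- apply_override(default_parameters("EXT1_AUTOREP"),
                            "lambda1", 1e6)
  tc_tight <- simulate_model("EXT1_AUTOREP", p_tight, duration_h = 4,
                             n_points = 241)
  expect_lt(max(observable(tc_tight, "atf3_protein")),
            max(observable(tc_def, "atf3_protein")))
  egr1 <- observable(tc_tight, "egr1_mrna")
  f <- extract_features(time_min(tc_tight), egr1, query_times = 120)
  expect_gt(unname(f$fraction_of_peak[1]), 0.5)
})

test_that("the miRNA extension terminates Atf3 protein under every
           complex-degradation scenario", {
  for (m in c(1, 2, 4)) {
    p <- .set_value(default_parameters("EXT4_MIRNA"), "d8_mult", m)
    tc <- simulate_model("EXT4_MIRNA", p, duration_h = 4, n_points = 241)
    prot <- observable(tc, "atf3_protein")
    f <- extract_features(time_min(tc), prot, query_times = 240)
    expect_lt(unname(f$fraction_of_peak[1]), 0.15, label = paste("d8 x", m))
  }
})

test_that("observables behave: absent series warn and return zeros, totals
           dominate free mRNA, ERK conservation holds", {
  tcb <- cached_sim("BASE", duration_h = 2, n_points = 121)
  expect_warning(s <- observable(tcb, "mirna"), "not defined")
  expect_true(all(s == 0))
  expect_error(observable(tcb, "not_a_series"), "valid names")
  tc4 <- cached_sim("EXT4_MIRNA", duration_h = 4)
  expect_true(all(observable(tc4, "atf3_mrna_total") >=
                    observable(tc4, "atf3_mrna_free") - 1e-15))
  expect_equal(observable(tcb, "erk_p") + tcb$states[, "ERK"],
               rep(param_value(tcb$params, "E0"), length(tcb$time)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("time-course CSV round-trips losslessly to 12 significant
           digits", {
  tc <- cached_sim("BASE", duration_h = 1, n_points = 61)
  path <- withr_local_tempfile(".csv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  wide <- as.data.frame(tc)
  expect_equal(names(back), names(wide))
  for (nm in names(wide)) {
    expect_equal(back[[nm]], wide[[nm]], tolerance = 1e-13, label = nm)
  }
})
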