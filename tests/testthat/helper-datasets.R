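# Canonical experimental-style datasets keyed by model observable, shared
# across calibration/sensitivity tests.

# self-consistency targets: fraction-of-max features extracted from a
# default simulation (used for parameter-recovery round trips)
recovery_targets <- function(variant, obs, times) {
  tc <- cached_sim(variant, duration_h = 2, n_points = 241)
  fr <- vapply(times, function(tq) {
    f <- extract_features(time_min(tc), observable(tc, obs),
                          query_times = tq)
    unname(f$fraction_of_peak[1])
  }, numeric(1))
  feature_targets(obs, "fraction_of_max_at_min", argument = times,
                  target = fr)
}

canonical_datasets <- local({
  cache <- NULL
  function(with_rsk = FALSE) {
    if (is.null(cache)) {
      sh <- canonical_shapes()
      sig_t <- c(0, 3, 5, 10, 20, 30, 45, 60, 90, 120)
      long_t <- c(0, 15, 30, 60, 90, 120, 180, 240)
      cache <<- list(
        erk_p = generate_dataset(sh$erk_p, sig_t, seed = 101),
        tf_p_atf3_promoter = generate_dataset(sh$creb_p, sig_t, seed = 102),
        tf_p_egr1_promoter = generate_dataset(sh$cjun_p, sig_t, seed = 103),
        atf3_mrna_total = generate_dataset(sh$atf3_mrna, long_t, seed = 104),
        atf3_protein = generate_dataset(sh$atf3_protein, long_t, seed = 105),
        egr1_mrna = generate_dataset(sh$egr1_mrna_with_atf3, long_t,
                                     seed = 106),
        rsk_p = generate_dataset(sh$rsk_p, sig_t, seed = 107))
    }
    if (with_rsk) cache else cache[setdiff(names(cache), "rsk_p")]
  }
})
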