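# Shared simulation cache so expensive trajectories are computed once per
# test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(variant, duration_h = 4, n_points = NULL,
                       params = NULL, key = NULL) {
  key <- key %||% paste(variant, duration_h, n_points %||% "default",
                        sep = "|")
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_model(variant,
                               params %||% default_parameters(variant),
                               duration_h = duration_h,
                               n_points = n_points),
           .sim_cache)
  }
  get(key, .sim_cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
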