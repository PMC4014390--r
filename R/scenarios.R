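## Scenario configuration, reproduction workflows and export.

#' Construct a scenario configuration
#'
#' @param variant One of [model_variants()].
#' @param overrides Named numeric vector of fold factors applied to
#'   parameters with [apply_override()] (names must exist for the variant).
#' @param d8_multiplier Multiplier on the miRNA.mRNA complex degradation
#'   rate (meaningful for EXT4_MIRNA / EXT5_COMBINED; a warning is issued
#'   otherwise).
#' @param feedback If \code{FALSE}, the Atf3 association with the Egr1
#'   promoter is switched off (k4 = 0), emulating Atf3 inhibition.
#' @param duration_h Simulated duration in hours.
#' @param seed Integer seed recorded in outputs (the model is
#'   deterministic; the seed only tags synthetic-data companions).
#' @param name Scenario label.
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(variant, overrides = NULL, d8_multiplier = 1,
                            feedback = TRUE, duration_h = 4, seed = 1L,
                            name = variant) {
  .check_variant(variant)
  defaults <- default_parameters(variant)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be a named numeric vector", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), defaults$name)
    if (length(unknown)) {
      stop("overrides reference unknown parameters: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!all(overrides > 0)) {
      stop("override factors must be positive", call. = FALSE)
    }
  }
  if (!(d8_multiplier > 0)) stop("d8_multiplier must be positive",
                                 call. = FALSE)
  if (d8_multiplier != 1 &&
      !variant %in% c("EXT4_MIRNA", "EXT5_COMBINED")) {
    warning("d8_multiplier has no effect for variant ", variant,
            call. = FALSE)
  }
  structure(list(name = name, variant = variant,
                 overrides = as.list(overrides),
                 d8_multiplier = d8_multiplier,
                 feedback = isTRUE(feedback),
                 duration_h = duration_h, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Write / read a scenario configuration as YAML
#'
#' Unknown keys in a config file are an error (this guards against silent
#' typos in parameter names).
#'
#' @param config A \code{scenario_config}.
#' @param path File path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns a \code{scenario_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  allowed <- c("name", "variant", "overrides", "d8_multiplier", "feedback",
               "duration_h", "seed")
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scenario_config(variant = obj$variant,
                  overrides = unlist(obj$overrides),
                  d8_multiplier = obj$d8_multiplier %||% 1,
                  feedback = obj$feedback %||% TRUE,
                  duration_h = obj$duration_h %||% 4,
                  seed = obj$seed %||% 1L,
                  name = obj$name %||% obj$variant)
}

## Materialise the parameter set implied by a scenario config.
.scenario_params <- function(config) {
  p <- default_parameters(config$variant)
  for (nm in names(config$overrides)) {
    p <- apply_override(p, nm, config$overrides[[nm]])
  }
  if (config$d8_multiplier != 1 && "d8_mult" %in% p$name) {
    p <- .set_param(p, "d8_mult", config$d8_multiplier)
  }
  if (!config$feedback) p <- .set_param(p, "k4", 0)
  p
}

#' Run one scenario
#'
#' Simulates the configured variant, extracts profile features for the main
#' observables and computes the behaviour flags.  If \code{outdir} is given,
#' writes \code{timecourse.csv} (wide), \code{features.json},
#' \code{flags.json}, \code{parameters.yaml} and \code{log.txt} there.
#'
#' @param config A \code{scenario_config}.
#' @param outdir Optional output directory (created if needed).
#' @return List with \code{config}, \code{params}, \code{timecourse}
#'   (a \code{time_course}), \code{features} (named list of
#'   \code{profile_features}), \code{flags} (one-row data frame).
#' @export
run_scenario <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  params <- .scenario_params(config)
  tc <- simulate_model(config$variant, params,
                       duration_h = config$duration_h)
  main_obs <- c("erk_p", "rsk_p", "tf_p_atf3_promoter",
                "tf_p_egr1_promoter", "atf3_mrna_total", "atf3_protein",
                "egr1_mrna", "mirna")
  features <- lapply(main_obs, function(obs) {
    s <- suppressWarnings(observable(tc, obs))
    extract_features(time_min(tc), s, query_times = c(30, 60, 120,
                                                      min(240, config$duration_h * 60)))
  })
  names(features) <- main_obs
  flags <- qualitative_flags(setNames(list(tc), config$name))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_timecourse(tc, file.path(outdir, "timecourse.csv"))
    jsonlite::write_json(
      lapply(features, function(f) {
        list(peak_time_min = f$peak_time, peak_value_nM = f$peak_value,
             basal_nM = f$basal,
             fraction_of_peak = as.list(f$fraction_of_peak),
             return_to_basal_min = f$return_to_basal_time, flat = f$flat)
      }),
      file.path(outdir, "features.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    jsonlite::write_json(as.list(flags), file.path(outdir, "flags.json"),
                         auto_unbox = TRUE, digits = NA)
    write_parameters(params, file.path(outdir, "parameters.yaml"))
    writeLines(c(
      paste0("scenario: ", config$name),
      paste0("variant: ", config$variant),
      paste0("feedback: ", config$feedback),
      paste0("d8_multiplier: ", config$d8_multiplier),
      paste0("duration_h: ", config$duration_h),
      paste0("seed: ", config$seed),
      paste0("solver: lsoda rtol=1e-8 atol=1e-12"),
      paste0("parameters with provenance PAPER: ",
             paste(params$name[params$provenance == "PAPER"],
                   collapse = ", ")),
      paste0("parameters with provenance DEFAULT: ",
             paste(params$name[params$provenance == "DEFAULT"],
                   collapse = ", "))),
      file.path(outdir, "log.txt"))
  }
  list(config = config, params = params, timecourse = tc,
       features = features, flags = flags)
}

#' The canonical reproduction scenario list
#'
#' BASE with and without Atf3 feedback; autorepression at default and with
#' the 1e6-fold tighter own-promoter binding; the RTF extension at default;
#' the ITF extension at default and with 1e6-fold faster ITF association;
#' and the miRNA and combined extensions at complex-degradation multipliers
#' 1, 2 and 4 (13 scenarios).
#'
#' @param duration_h Simulated duration per scenario.
#' @return Named list of \code{scenario_config} objects.
#' @export
paper_scenarios <- function(duration_h = 4) {
  sc <- list(
    base = scenario_config("BASE", duration_h = duration_h,
                           name = "base"),
    base_no_feedback = scenario_config("BASE", feedback = FALSE,
                                       duration_h = duration_h,
                                       name = "base_no_feedback"),
    ext1 = scenario_config("EXT1_AUTOREP", duration_h = duration_h,
                           name = "ext1"),
    ext1_tight_binding = scenario_config(
      "EXT1_AUTOREP", overrides = c(lambda1 = 1e6),
      duration_h = duration_h, name = "ext1_tight_binding"),
    ext2 = scenario_config("EXT2_RTF", duration_h = duration_h,
                           name = "ext2"),
    ext3 = scenario_config("EXT3_ITF", duration_h = duration_h,
                           name = "ext3"),
    ext3_tight_binding = scenario_config(
      "EXT3_ITF", overrides = c(k15 = 1e6),
      duration_h = duration_h, name = "ext3_tight_binding")
  )
  for (m in c(1, 2, 4)) {
    sc[[paste0("ext4_d8x", m)]] <- scenario_config(
      "EXT4_MIRNA", d8_multiplier = m, duration_h = duration_h,
      name = paste0("ext4_d8x", m))
    sc[[paste0("ext5_d8x", m)]] <- scenario_config(
      "EXT5_COMBINED", d8_multiplier = m, duration_h = duration_h,
      name = paste0("ext5_d8x", m))
  }
  sc
}

## Expected qualitative conclusions per scenario, encoded from the source
## study's figures and text, used for the verdict column.
.expected_flags <- function() {
  list(
    base = list(egr1_acutely_inhibited = TRUE),
    base_no_feedback = list(egr1_sustained = TRUE),
    ext1 = list(egr1_acutely_inhibited = TRUE),
    ext1_tight_binding = list(egr1_acutely_inhibited = FALSE),
    ext2 = list(egr1_acutely_inhibited = TRUE),
    ext3 = list(egr1_acutely_inhibited = TRUE),
    ext3_tight_binding = list(egr1_acutely_inhibited = FALSE),
    ext4_d8x1 = list(atf3_protein_terminated = TRUE,
                     atf3_mrna_transient = FALSE),
    ext4_d8x2 = list(atf3_protein_terminated = TRUE),
    ext4_d8x4 = list(atf3_protein_terminated = TRUE,
                     atf3_mrna_transient = TRUE),
    ext5_d8x1 = list(atf3_protein_terminated = TRUE,
                     atf3_mrna_transient = FALSE),
    ext5_d8x2 = list(atf3_protein_terminated = TRUE),
    ext5_d8x4 = list(atf3_protein_terminated = TRUE,
                     atf3_mrna_transient = TRUE)
  )
}

#' Run the full reproduction scenario set
#'
#' Runs [paper_scenarios()] and returns a one-row-per-scenario summary of
#' key features and behaviour flags, with a verdict column comparing each
#' scenario's flags against the study's stated conclusion for it.
#'
#' @param outdir Optional directory; per-scenario bundles are written to
#'   subdirectories and the summary to \code{summary.csv}.
#' @param duration_h Simulated duration per scenario.
#' @return Data frame, one row per scenario.
#' @export
reproduce_paper <- function(outdir = NULL, duration_h = 4) {
  scenarios <- paper_scenarios(duration_h)
  expected <- .expected_flags()
  rows <- lapply(names(scenarios), function(nm) {
    res <- try(run_scenario(scenarios[[nm]],
                            outdir = if (is.null(outdir)) NULL
                                     else file.path(outdir, nm)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      return(data.frame(scenario = nm, status = "failed",
                        variant = scenarios[[nm]]$variant,
                        stringsAsFactors = FALSE))
    }
    fl <- res$flags
    exp_nm <- expected[[nm]]
    verdict <- all(vapply(names(exp_nm), function(k) {
      identical(unname(fl[[k]]), exp_nm[[k]])
    }, logical(1)))
    data.frame(
      scenario = nm, status = "ok", variant = res$config$variant,
      erk_p_peak_min = res$features$erk_p$peak_time,
      egr1_frac_2h = fl$egr1_frac_2h,
      atf3_protein_frac_4h = fl$atf3_protein_frac_4h,
      atf3_mrna_total_frac_4h = fl$atf3_mrna_total_frac_4h,
      egr1_acutely_inhibited = fl$egr1_acutely_inhibited,
      egr1_sustained = fl$egr1_sustained,
      atf3_protein_terminated = fl$atf3_protein_terminated,
      atf3_mrna_transient = fl$atf3_mrna_transient,
      matches_reported_conclusion = verdict,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(outdir, "summary.csv"), row.names = FALSE)
  }
  out
}
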