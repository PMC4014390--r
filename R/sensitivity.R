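## One-at-a-time local parameter sensitivity analysis: each parameter varied
## 10- and 100-fold above and below its reference value, with effects
## measured as profile distances to smooth experimental-style curves and as
## qualitative behaviour flags.

#' Local one-at-a-time sensitivity scan
#'
#' For every parameter and fold change the model is re-simulated with that
#' single parameter multiplied by the fold, and the profile distance to each
#' reference dataset curve plus the qualitative behaviour flags are
#' recorded.  Simulation failures produce a failed row, not a scan abort.
#'
#' @param variant One of [model_variants()].
#' @param params Reference \code{parameter_set}.
#' @param datasets Named list of \code{experimental_dataset} objects (or
#'   \code{smooth_curve}s), keyed by observable name; each must use an
#'   observable valid for the variant.
#' @param parameters Parameter names to scan (default: all except the
#'   stimulus switch and the scenario multiplier).
#' @param fold_changes Numeric fold changes (default 0.01, 0.1, 10, 100).
#' @param duration_h,n_points Simulation grid.
#' @param thresholds Flag thresholds, see [flag_thresholds()].
#' @return A \code{sensitivity_table} data frame with one row per
#'   (parameter, fold change): per-observable distances
#'   (\code{dist_<observable>}), total distance, distance ratio vs the
#'   unperturbed reference, behaviour flags and a status column.  The
#'   reference (unperturbed) distances are stored once in attribute
#'   \code{reference}.
#' @export
local_scan <- function(variant, params = default_parameters(variant),
                       datasets, parameters = NULL,
                       fold_changes = c(0.01, 0.1, 10, 100),
                       duration_h = 4, n_points = 241,
                       thresholds = flag_thresholds()) {
  .check_variant(variant)
  if (length(datasets) == 0L || is.null(names(datasets))) {
    stop("datasets must be a non-empty named list", call. = FALSE)
  }
  curves <- lapply(datasets, function(d) {
    if (inherits(d, "smooth_curve")) d
    else if (inherits(d, "experimental_dataset")) fit_spline(d)
    else stop("datasets entries must be experimental_dataset or ",
              "smooth_curve objects", call. = FALSE)
  })
  bad <- setdiff(names(curves), observable_names())
  if (length(bad)) {
    stop("datasets keyed by unknown observables: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(parameters)) {
    parameters <- setdiff(params$name, c("S0", "d8_mult"))
  }
  unknown <- setdiff(parameters, params$name)
  if (length(unknown)) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  eval_one <- function(pset) {
    tc <- try(simulate_model(variant, pset, duration_h = duration_h,
                             n_points = n_points), silent = TRUE)
    if (inherits(tc, "try-error")) return(NULL)
    dists <- vapply(names(curves), function(obs) {
      cv <- curves[[obs]]
      qt <- cv$knots$time_min
      qt <- qt[qt <= duration_h * 60 & qt >= 0]
      s <- suppressWarnings(observable(tc, obs))
      if (all(s == 0)) return(NA_real_)
      profile_distance(time_min(tc), s, cv, qt)
    }, numeric(1))
    flags <- qualitative_flags(tc, thresholds)
    list(dists = dists, flags = flags)
  }

  ref <- eval_one(params)
  if (is.null(ref)) stop("reference simulation failed", call. = FALSE)
  ref_total <- sum(ref$dists, na.rm = TRUE)

  rows <- list()
  for (pm in parameters) {
    for (fc in fold_changes) {
      pert <- apply_override(params, pm, fc)
      r <- eval_one(pert)
      if (is.null(r)) {
        row <- data.frame(parameter = pm, fold_change = fc,
                          status = "failed", total_distance = NA_real_,
                          distance_ratio = NA_real_,
                          stringsAsFactors = FALSE)
        for (obs in names(curves)) row[[paste0("dist_", obs)]] <- NA_real_
        row$egr1_acutely_inhibited <- NA
        row$egr1_sustained <- NA
        row$atf3_protein_terminated <- NA
        row$atf3_mrna_transient <- NA
      } else {
        tot <- sum(r$dists, na.rm = TRUE)
        row <- data.frame(parameter = pm, fold_change = fc, status = "ok",
                          total_distance = tot,
                          distance_ratio = tot / ref_total,
                          stringsAsFactors = FALSE)
        for (obs in names(curves)) {
          row[[paste0("dist_", obs)]] <- unname(r$dists[obs])
        }
        row$egr1_acutely_inhibited <- r$flags$egr1_acutely_inhibited
        row$egr1_sustained <- r$flags$egr1_sustained
        row$atf3_protein_terminated <- r$flags$atf3_protein_terminated
        row$atf3_mrna_transient <- r$flags$atf3_mrna_transient
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  ## canonical order: by parameter name then fold change
  tab <- tab[order(tab$parameter, tab$fold_change), ]
  rownames(tab) <- NULL
  structure(tab, class = c("sensitivity_table", "data.frame"),
            variant = variant,
            reference = list(distances = ref$dists, total = ref_total,
                             flags = ref$flags))
}

#' Rank parameters by sensitivity for one observable
#'
#' Parameters are ordered by their maximum (over fold changes) distance
#' ratio for the named observable, descending; ties break alphabetically.
#'
#' @param table A \code{sensitivity_table}.
#' @param observable Observable name present in the table.
#' @return Character vector of parameter names, most sensitive first.
#' @export
rank_sensitivities <- function(table, observable) {
  col <- paste0("dist_", observable)
  if (!col %in% names(table)) {
    stop("observable '", observable, "' not present in the table",
         call. = FALSE)
  }
  refd <- attr(table, "reference")$distances[observable]
  score <- tapply(table[[col]], table$parameter, function(v) {
    if (all(is.na(v))) -Inf else max(v / refd, na.rm = TRUE)
  })
  nm <- names(score)
  nm[order(-unlist(score), nm)]
}

#' Summarise flag-flipping parameters as JSON
#'
#' @param table A \code{sensitivity_table}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_sensitivity_summary <- function(table, path) {
  ref <- attr(table, "reference")$flags
  flagcols <- c("egr1_acutely_inhibited", "egr1_sustained",
                "atf3_protein_terminated", "atf3_mrna_transient")
  flips <- unique(table$parameter[rowSums(
    sapply(flagcols, function(fc) table[[fc]] != ref[[fc]])
    , na.rm = TRUE) > 0])
  jsonlite::write_json(
    list(variant = attr(table, "variant"),
         n_rows = nrow(table),
         flag_flipping_parameters = flips),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
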