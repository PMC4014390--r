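## Reproducible calibration of the signalling sub-models.
##
## The source profiles were fitted "by eye"; here calibration minimises a
## weighted sum of squared mismatches between simulated profile features
## (peak time, fraction of maximum at stated times, return-to-basal time)
## and their targets, by bounded quasi-Newton search on log-parameters from
## a fixed, documented start.  The result is deterministic.

#' Fit a smooth curve to a replicate dataset
#'
#' With \code{smoothing = 0} the curve is the natural cubic interpolation
#' spline through the per-time means; with \code{smoothing > 0} a smoothing
#' spline ([stats::smooth.spline()] with \code{spar = smoothing}) is used.
#' The curve is clamped at zero.
#'
#' @param dataset An \code{experimental_dataset}, or a data frame with
#'   columns \code{time_min} and \code{mean}.
#' @param smoothing Non-negative smoothing parameter (\code{spar} scale),
#'   or \code{"auto"} to use the largest smoothing for which the curve
#'   stays within one SEM of every replicate mean (requires a dataset with
#'   SEMs; falls back to interpolation when no positive smoothing
#'   qualifies).
#' @return A \code{smooth_curve}: list with \code{fun(t_min)},
#'   \code{knots} (data frame time/value), \code{basal} (value at the first
#'   knot), \code{support} (time range).
#' @export
fit_spline <- function(dataset, smoothing = 0) {
  tt <- dataset$time_min; mm <- dataset$mean
  ss_sem <- dataset$sem
  keep <- !duplicated(tt)
  tt <- tt[keep]; mm <- mm[keep]
  if (!is.null(ss_sem)) ss_sem <- ss_sem[keep]
  if (length(tt) < 4L) {
    stop("need at least 4 distinct time points to fit a spline",
         call. = FALSE)
  }
  o <- order(tt); tt <- tt[o]; mm <- mm[o]
  if (!is.null(ss_sem)) ss_sem <- ss_sem[o]
  if (identical(smoothing, "auto")) {
    if (is.null(ss_sem)) {
      stop("smoothing = \"auto\" needs a dataset with SEMs", call. = FALSE)
    }
    smoothing <- 0
    for (sp in rev(seq(0.05, 1, by = 0.05))) {
      cand <- smooth.spline(tt, mm, spar = sp)
      if (all(abs(pmax(predict(cand, tt)$y, 0) - mm) <= ss_sem + 1e-12)) {
        smoothing <- sp
        break
      }
    }
  }
  if (smoothing < 0) stop("smoothing must be non-negative", call. = FALSE)
  if (smoothing == 0) {
    f0 <- splinefun(tt, mm, method = "natural")
  } else {
    ss <- smooth.spline(tt, mm, spar = smoothing)
    f0 <- function(t) predict(ss, t)$y
  }
  fun <- function(t_min) pmax(f0(t_min), 0)
  structure(list(fun = fun, knots = data.frame(time_min = tt, value = mm),
                 basal = unname(fun(tt[1])), support = range(tt),
                 smoothing = smoothing),
            class = "smooth_curve")
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("Smooth curve: ", nrow(x$knots), " knots on [",
      x$support[1], ", ", x$support[2], "] min (smoothing ",
      x$smoothing, ")\n", sep = "")
  invisible(x)
}

#' Construct a feature-target table
#'
#' @param observable Observable name ([observable_names()]).
#' @param feature One of \code{"peak_time_min"},
#'   \code{"fraction_of_max_at_min"}, \code{"return_to_basal_by_min"}.
#' @param argument Feature argument (query time in minutes for fractions;
#'   the basal threshold for return times; \code{NA} for peak time).
#' @param target Target value.
#' @param weight Positive weight.
#' @return A \code{feature_targets} data frame; rows from multiple calls can
#'   be combined with \code{rbind}.
#' @export
feature_targets <- function(observable, feature, argument = NA_real_,
                            target, weight = 1) {
  feats <- c("peak_time_min", "fraction_of_max_at_min",
             "return_to_basal_by_min")
  n <- max(length(observable), length(feature), length(argument),
           length(target), length(weight))
  df <- data.frame(observable = rep_len(observable, n),
                   feature = rep_len(feature, n),
                   argument = rep_len(argument, n),
                   target = rep_len(target, n),
                   weight = rep_len(weight, n), stringsAsFactors = FALSE)
  if (!all(df$feature %in% feats)) {
    stop("feature must be one of: ", paste(feats, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$weight > 0)) stop("weights must be positive", call. = FALSE)
  bad <- df$feature == "fraction_of_max_at_min" &
    !(df$target > 0 & df$target <= 1)
  if (any(bad)) stop("fraction targets must lie in (0, 1]", call. = FALSE)
  if (!all(df$target > 0)) stop("targets must be positive", call. = FALSE)
  class(df) <- c("feature_targets", "data.frame")
  df
}

## Evaluate one feature of a simulated time course.
.eval_feature <- function(tc, obs, feature, argument) {
  s <- observable(tc, obs)
  tmin <- time_min(tc)
  switch(feature,
    peak_time_min = {
      f <- extract_features(tmin, s)
      if (f$flat) max(tmin) else f$peak_time
    },
    fraction_of_max_at_min = {
      f <- extract_features(tmin, s, query_times = argument)
      if (f$flat) 0 else unname(f$fraction_of_peak[1])
    },
    return_to_basal_by_min = {
      thr <- if (is.na(argument)) 0.1 else argument
      f <- extract_features(tmin, s, basal_threshold = thr)
      if (f$flat || is.na(f$return_to_basal_time)) max(tmin)
      else f$return_to_basal_time
    },
    stop("unknown feature ", feature, call. = FALSE))
}

#' Calibrate model parameters to feature targets
#'
#' Minimises the weighted squared mismatch between simulated features and
#' targets over the named free parameters, within positive bounds, starting
#' from the values in \code{params} (the package defaults unless
#' overridden).  Optimisation is bounded L-BFGS-B on log-transformed
#' parameters, which is deterministic for a fixed start.
#'
#' @param targets A \code{feature_targets} table.
#' @param free_params Character vector of parameter names to fit.
#' @param variant Model variant to simulate.
#' @param bounds Named list of length-2 numeric vectors (positive lower and
#'   upper bounds) per free parameter; defaults to a factor of 100 around
#'   the starting values.
#' @param params Starting \code{parameter_set}.
#' @param duration_h,n_points Simulation grid used during fitting.
#' @param control Passed to [stats::optim()].
#' @return The full \code{parameter_set} with fitted entries updated and
#'   provenance retagged \code{"FITTED"}; attributes \code{residual},
#'   \code{counts}, \code{convergence} and \code{start} carry the fit
#'   report.
#' @export
calibrate_submodel <- function(targets, free_params, variant,
                               bounds = NULL,
                               params = default_parameters(variant),
                               duration_h = 2, n_points = 241,
                               control = list(maxit = 200)) {
  stopifnot(inherits(targets, "feature_targets"), nrow(targets) > 0)
  if (length(free_params) == 0L) {
    stop("free_params must name at least one parameter", call. = FALSE)
  }
  start <- vapply(free_params, function(nm) param_value(params, nm),
                  numeric(1))
  if (is.null(bounds)) {
    bounds <- lapply(start, function(v) c(v / 100, v * 100))
    names(bounds) <- free_params
  }
  for (nm in free_params) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)) ||
        !(b[1] > 0) || !(b[2] > b[1])) {
      stop("bounds for '", nm, "' must be a finite positive interval",
           call. = FALSE)
    }
  }
  lower <- log(vapply(free_params, function(nm) bounds[[nm]][1], numeric(1)))
  upper <- log(vapply(free_params, function(nm) bounds[[nm]][2], numeric(1)))

  objective <- function(theta) {
    pset <- params
    for (i in seq_along(free_params)) {
      pset <- .set_param(pset, free_params[i], exp(theta[i]))
    }
    tc <- try(simulate_model(variant, pset, duration_h = duration_h,
                             n_points = n_points), silent = TRUE)
    if (inherits(tc, "try-error")) return(1e6)
    res <- 0
    for (i in seq_len(nrow(targets))) {
      v <- .eval_feature(tc, targets$observable[i], targets$feature[i],
                         targets$argument[i])
      ## scale-free residual so minute-valued and fraction-valued features
      ## carry comparable weight
      res <- res + targets$weight[i] * ((v - targets$target[i]) /
                                          targets$target[i])^2
    }
    res
  }

  fit <- optim(log(start), objective, method = "L-BFGS-B",
               lower = lower, upper = upper, control = control)
  if (fit$convergence != 0 && fit$convergence != 1) {
    stop("calibration failed to converge (code ", fit$convergence, "): ",
         fit$message, "; best residual ", signif(fit$value, 6),
         call. = FALSE)
  }
  out <- params
  for (i in seq_along(free_params)) {
    out <- .set_param(out, free_params[i], exp(fit$par[i]))
    out$provenance[match(free_params[i], out$name)] <- "FITTED"
  }
  attr(out, "residual") <- fit$value
  attr(out, "counts") <- fit$counts
  attr(out, "convergence") <- fit$convergence
  attr(out, "start") <- start
  out
}

#' Write a calibration report as JSON
#'
#' @param fitted A \code{parameter_set} returned by [calibrate_submodel()].
#' @param free_params The fitted parameter names.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_calibration_report <- function(fitted, free_params, path) {
  rep <- list(
    fitted = as.list(setNames(
      vapply(free_params, function(nm) param_value(fitted, nm), numeric(1)),
      free_params)),
    start = as.list(attr(fitted, "start")),
    residual = attr(fitted, "residual"),
    evaluations = unname(attr(fitted, "counts")[1]),
    convergence = attr(fitted, "convergence"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
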