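## Profile feature extraction: peak times, percent declines, return-to-basal
## times, normalised profiles, model-vs-data distances and behaviour flags.
##
## All decline/return features are computed on peak-minus-basal elevation,
## (value - basal) / (peak - basal), so nonzero basal expression does not
## distort percentages.  Peak ties break toward the earliest time.

#' Extract profile features from a time series
#'
#' @param time_min Time grid in minutes.
#' @param values Series values (same length).
#' @param basal Basal value subtracted before computing fractions (default:
#'   the value at the first time point).
#' @param query_times Times (minutes) at which the fraction of peak
#'   elevation is evaluated.
#' @param basal_threshold Elevation fraction at or below which the series
#'   counts as returned to basal (default 0.1).
#' @return A \code{profile_features} list: \code{peak_time} (min),
#'   \code{peak_value}, \code{basal}, \code{fraction_of_peak} (named by
#'   query time), \code{return_to_basal_time} (min, \code{NA} if not
#'   reached), \code{flat} (TRUE when the series never rises above basal).
#' @export
#' @examples
#' tc <- simulate_model("BASE", duration_h = 2, n_points = 241)
#' extract_features(time_min(tc), observable(tc, "erk_p"),
#'                  query_times = 60)
extract_features <- function(time_min, values, basal = values[1],
                             query_times = numeric(),
                             basal_threshold = 0.1) {
  if (length(values) == 0L) stop("empty series", call. = FALSE)
  if (length(time_min) != length(values)) {
    stop("time and value vectors must have equal length", call. = FALSE)
  }
  if (!(basal_threshold > 0 && basal_threshold < 1)) {
    stop("basal_threshold must lie in (0, 1)", call. = FALSE)
  }
  i_peak <- which.max(values)          # earliest maximum on ties
  peak <- values[i_peak]
  elev <- peak - basal
  flat <- !(elev > 0)
  frac_at <- function(tq) {
    if (flat) return(NA_real_)
    v <- approx(time_min, values, xout = tq, rule = 2)$y
    min(max((v - basal) / elev, 0), 1)
  }
  fractions <- vapply(query_times, frac_at, numeric(1))
  names(fractions) <- format(query_times, trim = TRUE)
  ret <- NA_real_
  if (!flat) {
    post <- seq(i_peak, length(values))
    fr <- pmin(pmax((values[post] - basal) / elev, 0), 1)
    j <- which(fr <= basal_threshold)[1]
    if (!is.na(j)) ret <- time_min[post[j]]
  }
  structure(list(
    peak_time = if (flat) NA_real_ else time_min[i_peak],
    peak_value = peak, basal = basal,
    fraction_of_peak = fractions,
    return_to_basal_time = ret,
    basal_threshold = basal_threshold,
    flat = flat), class = "profile_features")
}

#' @export
print.profile_features <- function(x, ...) {
  if (x$flat) {
    cat("Profile features: flat series (no response above basal)\n")
  } else {
    cat(sprintf(
      "Profile features: peak %.4g at %.4g min; return to <=%g%% at %s min\n",
      x$peak_value, x$peak_time, 100 * x$basal_threshold,
      if (is.na(x$return_to_basal_time)) "not reached"
      else format(x$return_to_basal_time)))
    if (length(x$fraction_of_peak)) {
      cat("  fraction of peak elevation at (min):\n")
      print(round(x$fraction_of_peak, 4))
    }
  }
  invisible(x)
}

#' Normalise a series to its maximum
#'
#' @param values Numeric series with a positive maximum.
#' @return The series divided by its maximum (so the output maximum is 1).
#' @export
normalize_to_max <- function(values) {
  m <- max(values)
  if (!(m > 0)) stop("cannot normalise: series maximum is not positive",
                     call. = FALSE)
  values / m
}

#' Squared distance between a model series and a smooth experimental curve
#'
#' Both the model series and the curve are max-normalised before comparison,
#' matching how the experimental profiles are expressed relative to their
#' maxima; the result is the sum of squared differences at the queried
#' times.
#'
#' @param model_time_min,model_values Model series and its grid (minutes).
#' @param curve A \code{smooth_curve} (see [fit_spline()]).
#' @param times Query times in minutes (within the curve support).
#' @return Non-negative scalar; 0 iff the normalised profiles agree at all
#'   queried times.
#' @export
profile_distance <- function(model_time_min, model_values, curve, times) {
  if (length(times) == 0L) stop("empty query time list", call. = FALSE)
  rng <- curve$support
  if (any(times < rng[1] - 1e-9) || any(times > rng[2] + 1e-9)) {
    stop("query times outside curve support [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  mnorm <- normalize_to_max(model_values)
  mv <- approx(model_time_min, mnorm, xout = times, rule = 2)$y
  dense <- seq(rng[1], rng[2], length.out = 512)
  cmax <- max(curve$fun(dense))
  if (!(cmax > 0)) stop("curve maximum is not positive", call. = FALSE)
  cv <- curve$fun(times) / cmax
  sum((mv - cv)^2)
}

#' Default behaviour-flag thresholds
#'
#' Elevation-fraction thresholds used by [qualitative_flags()]:
#' \code{egr1_acute} (Egr1 mRNA fraction at 2 h at or below which acute
#' inhibition holds), \code{egr1_sustained} (fraction at 2 h at or above
#' which Egr1 counts as sustained), \code{protein_terminated} (Atf3 protein
#' fraction at 4 h), \code{mrna_transient} (total Atf3 mRNA fraction at
#' 4 h).
#'
#' @return Named list of thresholds.
#' @export
flag_thresholds <- function() {
  list(egr1_acute = 0.25, egr1_sustained = 0.5,
       protein_terminated = 0.15, mrna_transient = 0.2)
}

.tc_fraction_at <- function(tc, obs, at_min) {
  s <- observable(tc, obs)
  f <- extract_features(time_min(tc), s, query_times = at_min)
  if (f$flat) 0 else unname(f$fraction_of_peak[1])
}

#' Qualitative behaviour flags for one or more scenarios
#'
#' Computes, per time course, the boolean flags used to compare model
#' behaviour against the experimental conclusions:
#' \code{egr1_acutely_inhibited} (Egr1 mRNA elevation fraction at 2 h at or
#' below the acute threshold), \code{egr1_sustained} (fraction at 2 h at or
#' above the sustained threshold), \code{atf3_protein_terminated} (Atf3
#' protein fraction at 4 h at or below threshold) and
#' \code{atf3_mrna_transient} (total Atf3 mRNA fraction at 4 h at or below
#' threshold).  Time courses shorter than 4 h evaluate the 4 h flags at
#' their final time.
#'
#' @param tcs A named list of \code{time_course} objects (or a single one).
#' @param thresholds See [flag_thresholds()].
#' @return Data frame with one row per scenario.
#' @export
qualitative_flags <- function(tcs, thresholds = flag_thresholds()) {
  if (inherits(tcs, "time_course")) tcs <- list(scenario = tcs)
  if (is.null(names(tcs)) || any(names(tcs) == "")) {
    names(tcs) <- paste0("scenario_", seq_along(tcs))
  }
  rows <- lapply(names(tcs), function(nm) {
    tc <- tcs[[nm]]
    end_min <- max(time_min(tc))
    t4 <- min(240, end_min)
    fe <- .tc_fraction_at(tc, "egr1_mrna", min(120, end_min))
    fp <- .tc_fraction_at(tc, "atf3_protein", t4)
    fm <- .tc_fraction_at(tc, "atf3_mrna_total", t4)
    data.frame(
      scenario = nm, variant = tc$variant,
      egr1_frac_2h = fe, atf3_protein_frac_4h = fp,
      atf3_mrna_total_frac_4h = fm,
      egr1_acutely_inhibited = fe <= thresholds$egr1_acute,
      egr1_sustained = fe >= thresholds$egr1_sustained,
      atf3_protein_terminated = fp <= thresholds$protein_terminated,
      atf3_mrna_transient = fm <= thresholds$mrna_transient,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
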