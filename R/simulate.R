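## Time-course simulation and derived observables.

.OBSERVABLES <- c("erk_p", "rsk_p", "atf3_mrna_total", "atf3_mrna_free",
                  "atf3_protein", "egr1_mrna", "itf_mrna", "itf_protein",
                  "mirna", "tf_p_atf3_promoter", "tf_p_egr1_promoter",
                  "rtf_p_bound")

.observable_series <- function(states, name) {
  col <- function(nm) {
    if (nm %in% colnames(states)) states[, nm] else NULL
  }
  switch(name,
    erk_p = col("ERK_P"),
    rsk_p = col("RSK_P"),
    atf3_mrna_free = col("mATF3"),
    atf3_mrna_total = {
      cp <- col("MIR_mATF3")
      if (is.null(cp)) col("mATF3") else col("mATF3") + cp
    },
    atf3_protein = col("ATF3"),
    egr1_mrna = col("mEGR1"),
    itf_mrna = col("mITF"),
    itf_protein = col("ITF"),
    mirna = col("MIR"),
    tf_p_atf3_promoter = col("PA_TFP"),
    tf_p_egr1_promoter = col("PE_TFP"),
    rtf_p_bound = col("PA_RTFP"))
}

#' Simulate a model variant
#'
#' Integrates the variant from its unstimulated steady state with the step
#' stimulus switched on at t = 0, using a stiff-capable solver
#' ([deSolve::lsoda()]) at relative tolerance 1e-8 and absolute tolerance
#' 1e-12 nM.  The result is deterministic: identical inputs give identical
#' grids and values on one platform.
#'
#' @param variant One of [model_variants()].
#' @param params A \code{parameter_set}; defaults to
#'   \code{default_parameters(variant)}.
#' @param duration_h Simulated duration in hours (default 4).
#' @param n_points Number of reporting grid points including t = 0 (default:
#'   one point every 30 s).
#' @param rtol,atol Solver tolerances.
#' @return A \code{time_course}: list with elements \code{time} (seconds),
#'   \code{states} (matrix, one row per time point), \code{variant},
#'   \code{params}.
#' @export
#' @examples
#' tc <- simulate_model("BASE", duration_h = 1, n_points = 121)
#' head(observable(tc, "erk_p"))
simulate_model <- function(variant, params = default_parameters(variant),
                           duration_h = 4, n_points = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  .check_variant(variant)
  if (!(duration_h > 0)) stop("duration_h must be positive", call. = FALSE)
  if (is.null(n_points)) n_points <- round(duration_h * 3600 / 30) + 1L
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  times <- seq(0, duration_h * 3600, length.out = n_points)
  y0 <- basal_state(variant, params)
  rhs <- build_rhs(variant, params)
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  diagn <- attributes(out)$istate
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    stop("solver failed at t = ", last[1], " s; last state: ",
         paste(sprintf("%s=%.4g", colnames(out)[-1], last[-1]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(time = as.numeric(out[, 1]),
                 states = out[, -1, drop = FALSE],
                 variant = variant, params = params),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("Time course: ", x$variant, ", ", length(x$time), " points over ",
      round(max(x$time) / 3600, 3), " h, ", ncol(x$states), " species\n",
      sep = "")
  invisible(x)
}

#' Observable names
#'
#' @return Character vector of derived observable identifiers.
#' @export
observable_names <- function() .OBSERVABLES

#' Extract a derived observable series from a time course
#'
#' Observables absent from the simulated variant (for example \code{mirna}
#' in BASE) return an all-zero series with a warning and attribute
#' \code{absent = TRUE}, so one analysis script can serve all variants.
#'
#' @param tc A \code{time_course}.
#' @param name One of [observable_names()].
#' @return Numeric vector aligned with \code{tc$time}.
#' @export
observable <- function(tc, name) {
  stopifnot(inherits(tc, "time_course"))
  if (!(is.character(name) && length(name) == 1L && name %in% .OBSERVABLES)) {
    stop("unknown observable '", paste(name, collapse = ","),
         "'; valid names: ", paste(.OBSERVABLES, collapse = ", "),
         call. = FALSE)
  }
  s <- .observable_series(tc$states, name)
  if (is.null(s)) {
    warning("observable '", name, "' is not defined for variant ",
            tc$variant, "; returning zeros", call. = FALSE)
    s <- structure(numeric(length(tc$time)), absent = TRUE)
  }
  s
}

#' Time in minutes for a time course
#' @param tc A \code{time_course}.
#' @return Numeric vector of times in minutes.
#' @export
time_min <- function(tc) tc$time / 60

#' Convert a time course to a data frame of observables
#'
#' @param x A \code{time_course}.
#' @param row.names,optional Ignored (base generic signature).
#' @param format \code{"wide"} (one column per observable) or \code{"tidy"}
#'   (columns \code{time_min}, \code{observable}, \code{value_nM}).
#' @param ... Ignored.
#' @return A data frame.
#' @export
as.data.frame.time_course <- function(x, row.names = NULL, optional = FALSE,
                                      format = c("wide", "tidy"), ...) {
  format <- match.arg(format)
  present <- Filter(function(nm) !is.null(.observable_series(x$states, nm)),
                    .OBSERVABLES)
  wide <- data.frame(time_min = x$time / 60)
  for (nm in present) wide[[nm]] <- .observable_series(x$states, nm)
  if (format == "wide") return(wide)
  data.frame(
    time_min = rep(wide$time_min, length(present)),
    observable = rep(present, each = nrow(wide)),
    value_nM = unlist(wide[present], use.names = FALSE))
}

#' Write / read a time course as CSV
#'
#' Values are written with 17 significant digits, so a round trip is
#' lossless to well beyond 12 significant digits.
#'
#' @param tc A \code{time_course}.
#' @param path Output file.
#' @param format \code{"wide"} or \code{"tidy"} (only \code{"wide"} files
#'   can be read back).
#' @return \code{write_timecourse} returns \code{path} invisibly;
#'   \code{read_timecourse} returns a wide data frame.
#' @export
write_timecourse <- function(tc, path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  df <- as.data.frame(tc, format = format)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  read.csv(path, check.names = FALSE)
}
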