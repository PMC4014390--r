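## Synthetic experimental-style datasets.
##
## Shapes are difference-of-two-exponentials pulses,
##   y(t) = basal + a * (exp(-kd t) - exp(-kr t)),  kr > kd > 0,
## the impulse response of the linear activation cascades in the model
## itself.  The two rate constants are solved so that the curve peaks at the
## stated time and retains a stated fraction of its peak elevation at a
## stated late time; the curve is normalised so its maximum is 1.

.dexp_g <- function(t, kd, kr) exp(-kd * t) - exp(-kr * t)

## Solve (kd, kr) for peak time tp and elevation fraction f at time tq.
.solve_dexp <- function(peak_min, late_min, late_frac) {
  stopifnot(peak_min > 0, late_min > peak_min,
            late_frac > 0, late_frac < 1)
  kd_of_r <- function(r) log(r) / (peak_min * (r - 1))
  frac_of_r <- function(r) {
    kd <- kd_of_r(r); kr <- r * kd
    .dexp_g(late_min, kd, kr) / .dexp_g(peak_min, kd, kr)
  }
  ## frac_of_r decreases in r is not guaranteed globally; bracket by scan
  rs <- exp(seq(log(1 + 1e-6), log(1e8), length.out = 400))
  fr <- vapply(rs, frac_of_r, numeric(1)) - late_frac
  i <- which(fr[-1] * fr[-length(fr)] <= 0)[1]
  if (is.na(i)) {
    stop("no difference-of-exponentials pulse satisfies peak ", peak_min,
         " min with fraction ", late_frac, " at ", late_min, " min",
         call. = FALSE)
  }
  r <- uniroot(function(r) frac_of_r(r) - late_frac,
               c(rs[i], rs[i + 1]), tol = 1e-12)$root
  kd <- kd_of_r(r)
  c(kd = kd, kr = r * kd)
}

#' Construct a pulse shape specification
#'
#' Two pulse families are available.  The difference-of-exponentials family
#' cannot decline below ~59% of peak elevation at 2.4x the peak time (its
#' slowest-rise limit), so shapes outside its reach (the delayed c-Jun-like
#' profile) use a log-normal pulse,
#' \code{basal + a * exp(-log(t / tp)^2 / (2 s^2))}, whose peak time and
#' late fraction have closed-form parameters.  \code{family = "auto"}
#' (default) picks the difference of exponentials when feasible.
#'
#' @param observable Observable name the shape emulates.
#' @param peak_min Peak time in minutes.
#' @param late_min Late reference time in minutes.
#' @param late_frac Fraction of peak elevation remaining at \code{late_min}.
#' @param basal_frac Basal level as a fraction of the peak value (default
#'   0.05).
#' @param family \code{"auto"}, \code{"diff_exp"} or \code{"lognormal"}.
#' @return A \code{shape_spec} with a vectorised evaluation function
#'   \code{fun(t_min)} whose maximum is 1.
#' @export
shape_spec <- function(observable, peak_min, late_min, late_frac,
                       basal_frac = 0.05,
                       family = c("auto", "diff_exp", "lognormal")) {
  family <- match.arg(family)
  ks <- NULL
  if (family %in% c("auto", "diff_exp")) {
    ks <- tryCatch(.solve_dexp(peak_min, late_min, late_frac),
                   error = function(e) if (family == "diff_exp") stop(e)
                           else NULL)
  }
  if (!is.null(ks)) {
    gmax <- .dexp_g(peak_min, ks["kd"], ks["kr"])
    a <- (1 - basal_frac) / gmax
    fun <- function(t_min) {
      pmax(basal_frac + a * .dexp_g(t_min, ks["kd"], ks["kr"]), 0)
    }
    pars <- list(family = "diff_exp", kd = unname(ks["kd"]),
                 kr = unname(ks["kr"]))
  } else {
    sig <- abs(log(late_min / peak_min)) / sqrt(-2 * log(late_frac))
    a <- 1 - basal_frac
    fun <- function(t_min) {
      g <- ifelse(t_min > 0,
                  exp(-log(t_min / peak_min)^2 / (2 * sig^2)), 0)
      pmax(basal_frac + a * g, 0)
    }
    pars <- list(family = "lognormal", sigma = sig)
  }
  structure(c(list(observable = observable,
                   peak_min = peak_min, late_min = late_min,
                   late_frac = late_frac, basal_frac = basal_frac,
                   fun = fun), pars),
            class = "shape_spec")
}

#' Canonical shapes for the measured profiles
#'
#' Feature values follow the reported time courses: ERK1/2 phosphorylation
#' peaks at ~3 min and declines ~90% by 1 h; CREB phosphorylation peaks at
#' ~10 min and is ~25% of maximum at 60 min; c-Jun phosphorylation peaks at
#' ~50 min and is ~50% at 2 h; RSK phosphorylation peaks at ~10 min and is
#' ~25% at 30 min; Atf3 mRNA peaks at ~30 min and is near basal by ~4 h;
#' Atf3 protein peaks at ~60 min; Egr1 mRNA peaks at ~30 min and is near
#' basal by ~2 h with Atf3 present but sustained without it.
#'
#' @return Named list of \code{shape_spec} objects.
#' @export
canonical_shapes <- function() {
  list(
    erk_p        = shape_spec("erk_p", 3, 60, 0.10),
    creb_p       = shape_spec("creb_p", 10, 60, 0.25),
    cjun_p       = shape_spec("cjun_p", 50, 120, 0.50),
    rsk_p        = shape_spec("rsk_p", 10, 30, 0.25),
    atf3_mrna    = shape_spec("atf3_mrna", 30, 240, 0.15),
    atf3_protein = shape_spec("atf3_protein", 60, 240, 0.10),
    egr1_mrna_with_atf3    = shape_spec("egr1_mrna_with_atf3", 30, 120, 0.08),
    egr1_mrna_without_atf3 = shape_spec("egr1_mrna_without_atf3", 30, 120, 0.60)
  )
}

#' Generate a replicate time-course dataset from a shape
#'
#' Replicates are the shape curve multiplied by (1 + Gaussian noise with the
#' given coefficient of variation), truncated at zero.  The generator uses a
#' private RNG stream, so the global random seed is left untouched, and the
#' same seed always reproduces the same dataset bitwise.
#'
#' @param spec A \code{shape_spec}.
#' @param times Sampling times in minutes.
#' @param n_reps Number of replicates (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.15).
#' @param seed Integer seed.
#' @return An \code{experimental_dataset}: list with \code{observable},
#'   \code{time_min}, \code{replicates} (n_reps x n_times matrix),
#'   \code{mean}, \code{sem}, \code{spec}, \code{seed}, \code{noise_cv}.
#' @export
generate_dataset <- function(spec, times, n_reps = 3, noise_cv = 0.15,
                             seed = 1L) {
  stopifnot(inherits(spec, "shape_spec"))
  if (!(n_reps >= 2 && n_reps == round(n_reps))) {
    stop("n_reps must be an integer >= 2", call. = FALSE)
  }
  if (!(noise_cv >= 0 && noise_cv < 1)) {
    stop("noise_cv must lie in [0, 1)", call. = FALSE)
  }
  curve <- spec$fun(times)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eps <- matrix(rnorm(n_reps * length(times), mean = 0, sd = noise_cv),
                nrow = n_reps)
  reps <- pmax(sweep(1 + eps, 2, curve, `*`), 0)
  dimnames(reps) <- list(paste0("rep_", seq_len(n_reps)),
                         format(times, trim = TRUE))
  m <- colMeans(reps)
  sem <- apply(reps, 2, sd) / sqrt(n_reps)
  structure(list(observable = spec$observable, time_min = times,
                 replicates = reps, mean = unname(m), sem = unname(sem),
                 spec = spec, seed = as.integer(seed),
                 noise_cv = noise_cv),
            class = "experimental_dataset")
}

#' @export
print.experimental_dataset <- function(x, ...) {
  cat("Experimental-style dataset: ", x$observable, ", ",
      nrow(x$replicates), " replicates x ", length(x$time_min),
      " time points (seed ", x$seed, ", cv ", x$noise_cv, ")\n", sep = "")
  invisible(x)
}

#' Write / read a replicate dataset as CSV
#'
#' Comment header lines (\code{# key=value}) record the observable, seed
#' and noise level; columns are \code{time_min}, \code{rep_1..rep_n},
#' \code{mean}, \code{sem}.  Values round-trip losslessly to more than 12
#' significant digits.
#'
#' @param dataset An \code{experimental_dataset}.
#' @param path File path.
#' @return \code{write_dataset} returns \code{path} invisibly;
#'   \code{read_dataset} returns an \code{experimental_dataset} (without
#'   the generating shape).
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# observable=", dataset$observable),
               paste0("# seed=", dataset$seed),
               paste0("# noise_cv=", sprintf("%.17g", dataset$noise_cv))),
             con)
  df <- data.frame(time_min = sprintf("%.17g", dataset$time_min))
  for (i in seq_len(nrow(dataset$replicates))) {
    df[[paste0("rep_", i)]] <- sprintf("%.17g", dataset$replicates[i, ])
  }
  df$mean <- sprintf("%.17g", dataset$mean)
  df$sem <- sprintf("%.17g", dataset$sem)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  repcols <- grep("^rep_", names(df), value = TRUE)
  reps <- t(as.matrix(df[repcols]))
  dimnames(reps) <- list(repcols, format(df$time_min, trim = TRUE))
  structure(list(observable = meta$observable %||% "unknown",
                 time_min = df$time_min, replicates = reps,
                 mean = df$mean, sem = df$sem, spec = NULL,
                 seed = as.integer(meta$seed %||% NA),
                 noise_cv = as.numeric(meta$noise_cv %||% NA)),
            class = "experimental_dataset")
}

#' miRNA fold-change table (in-text fixture)
#'
#' The published fold-change table for miRNA probesets upregulated in
#' cardiomyocytes by ET-1 via ERK1/2 and RSKs: unstimulated control,
#' PD184352 (MKK1/2-ERK1/2 inhibition), BI-D1870 (RSK inhibition), ET-1,
#' and ET-1 in the presence of each inhibitor; values are means (n = 3)
#' relative to control.  This table motivates the miRNA model extension.
#'
#' @return Data frame with one row per probeset.
#' @export
#' @examples
#' t1 <- table1_fixture()
#' t1[t1$gene_symbol == "Mir222", "ET1"]   # 2.970
table1_fixture <- function() {
  data.frame(
    probeset = c(7070060L, 7135292L, 7373217L, 7288447L),
    gene_symbol = c("Mir193", "Mir19b-1", "Mir222", "Mir31"),
    raw_value = c(118, 41, 37, 102),
    Control = c(1.00, 1.00, 1.00, 1.00),
    PD184352 = c(0.993, 0.845, 1.039, 0.680),
    BI_D1870 = c(0.642, 0.901, 1.007, 0.602),
    ET1 = c(2.329, 1.506, 2.970, 2.354),
    PD184352_ET1 = c(1.370, 1.043, 0.979, 1.140),
    BI_D1870_ET1 = c(0.760, 0.751, 1.603, 0.827),
    stringsAsFactors = FALSE)
}
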