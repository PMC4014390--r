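## Model variants, species lists and parameter sets.
##
## Units: concentrations in nM, time in seconds.  Bimolecular rate constants
## quoted in the literature as (Ms)^-1 are stored in (nM s)^-1, i.e. x 1e-9.

#' Model variant labels
#'
#' @return Character vector of the six recognised model variants.
#' @export
#' @examples
#' model_variants()
model_variants <- function() {
  c("BASE", "EXT1_AUTOREP", "EXT2_RTF", "EXT3_ITF", "EXT4_MIRNA",
    "EXT5_COMBINED")
}

.check_variant <- function(variant) {
  if (!(is.character(variant) && length(variant) == 1L &&
        variant %in% model_variants())) {
    stop("unknown model variant ", deparse(substitute(variant)), ": ",
         paste(deparse(variant), collapse = ""),
         "; valid variants are: ", paste(model_variants(), collapse = ", "),
         call. = FALSE)
  }
  variant
}

.BASE_SPECIES <- c(
  "MKK_I", "MKK_A", "MKK_R",       # upstream kinase pool (inactive/active/refractory)
  "ERK", "ERK_P",
  "PA_TF", "PA_TFP",               # Atf3 promoter with bound activator TF
  "PE_TF", "PE_TFP", "PE_ATF3",    # Egr1 promoter (activator / Atf3-repressed)
  "mATF3", "ATF3", "mEGR1"
)
.RSK_SPECIES  <- c("RSK", "RSK_P")
.EXT1_SPECIES <- "PA_ATF3"
.EXT2_SPECIES <- c(.RSK_SPECIES, "RTF", "RTF_P", "PA_RTFP")
.EXT3_SPECIES <- c(.RSK_SPECIES, "mITF", "ITF", "PA_ITF")
.EXT4_SPECIES <- c(.RSK_SPECIES, "MI_RTF", "MI_RTFP", "preMIR", "MIR",
                   "MIR_mATF3")

#' Species names for a model variant
#'
#' Every variant's species list is a superset of the BASE list; the combined
#' variant is the union of the ITF and miRNA extensions.
#'
#' @param variant One of [model_variants()].
#' @return Character vector of state-variable names (concentrations in nM).
#' @export
species_names <- function(variant) {
  .check_variant(variant)
  extra <- switch(variant,
    BASE          = character(),
    EXT1_AUTOREP  = .EXT1_SPECIES,
    EXT2_RTF      = .EXT2_SPECIES,
    EXT3_ITF      = .EXT3_SPECIES,
    EXT4_MIRNA    = .EXT4_SPECIES,
    EXT5_COMBINED = union(.EXT3_SPECIES, .EXT4_SPECIES))
  c(.BASE_SPECIES, extra)
}

.pentry <- function(name, value, units, provenance, description) {
  data.frame(name = name, value = value, units = units,
             provenance = provenance, description = description,
             stringsAsFactors = FALSE)
}

## Base-model defaults.  Rates printed in the source literature carry
## provenance "PAPER"; the remaining rates are package defaults calibrated so
## that the simulated profiles reproduce the measured timing features
## (ERK1/2-P peak ~3 min with ~90% decline by 1 h; CREB-like promoter TF peak
## ~10 min with ~25% of maximum at 60 min; Egr1 mRNA near basal by 2 h with
## Atf3 feedback and sustained without it).
.base_param_table <- function() {
  rbind(
    .pentry("S0",      1,       "-",         "DEFAULT", "step stimulus amplitude (ET-1 on at t = 0)"),
    .pentry("k1",      0.03,    "s-1",       "DEFAULT", "stimulus-driven MKK activation"),
    .pentry("d_mkk",   0.02,    "s-1",       "DEFAULT", "active MKK inactivation (to refractory state)"),
    .pentry("k_rec",   2e-6,    "s-1",       "DEFAULT", "refractory MKK recovery"),
    .pentry("M0",      10,      "nM",        "DEFAULT", "total MKK pool"),
    .pentry("k2",      6e-3,    "nM-1 s-1",  "DEFAULT", "ERK phosphorylation by active MKK"),
    .pentry("d_erk",   1.15e-3, "s-1",       "DEFAULT", "ERK-P dephosphorylation"),
    .pentry("E0",      40,      "nM",        "DEFAULT", "total ERK1/2 pool"),
    .pentry("k5",      1.4e-4,  "nM-1 s-1",  "DEFAULT", "phosphorylation of Atf3-promoter TF by ERK-P (CREB-like)"),
    .pentry("km5",     1.2e-3,  "s-1",       "DEFAULT", "dephosphorylation of Atf3-promoter TF"),
    .pentry("k3",      1e-4,    "nM-1 s-1",  "DEFAULT", "phosphorylation of Egr1-promoter TF by ERK-P"),
    .pentry("km3",     2e-5,    "s-1",       "DEFAULT", "dephosphorylation of Egr1-promoter TF (delayed)"),
    .pentry("k6",      0.012,   "s-1",       "DEFAULT", "Atf3 transcription per phospho-TF-bound promoter"),
    .pentry("k7",      0.012,   "s-1",       "DEFAULT", "Egr1 transcription per phospho-TF-bound promoter"),
    .pentry("k8",      0.25,    "s-1",       "PAPER",   "Atf3 translation (premiRNA maturation k18 is stated to be double this rate, 0.5/s)"),
    .pentry("d2",      1.5e-4,  "s-1",       "DEFAULT", "Atf3 mRNA degradation"),
    .pentry("d3",      3e-3,    "s-1",       "DEFAULT", "Atf3 protein degradation"),
    .pentry("d_megr1", 1e-3,    "s-1",       "DEFAULT", "Egr1 mRNA degradation"),
    .pentry("k4",      1e-4,    "nM-1 s-1",  "PAPER",   "Atf3 protein association with Egr1 promoter (1e5 (Ms)-1)"),
    .pentry("km4",     5e-5,    "s-1",       "DEFAULT", "Atf3 protein dissociation from Egr1 promoter"),
    .pentry("K10",     0.5,     "nM",        "DEFAULT", "TF/Atf3-promoter dissociation constant (used via K15 = K10)"),
    .pentry("P_atf3",  0.01,    "nM",        "DEFAULT", "total Atf3 promoter"),
    .pentry("P_egr1",  0.01,    "nM",        "DEFAULT", "total Egr1 promoter")
  )
}

.ext_param_table <- function(variant, base) {
  v <- function(nm) base$value[match(nm, base$name)]
  ext1 <- rbind(
    .pentry("K11",       0.1,       "nM",       "PAPER", "Atf3 protein / Atf3 promoter binding constant (initial value 0.1 nM)"),
    .pentry("lambda1",   1e-4,      "nM-1 s-1", "PAPER", "Atf3 protein association with own promoter (1e5 (Ms)-1)"),
    .pentry("lambda_m1", 1e-4 * 0.1, "s-1",     "PAPER", "Atf3 protein dissociation from own promoter (lambda_m1/lambda1 = K11)")
  )
  rsk <- rbind(
    .pentry("k9",  1e-4,   "nM-1 s-1", "PAPER", "RSK phosphorylation by ERK-P (1e5 (Ms)-1, fit)"),
    .pentry("d10", 5.9e-4, "s-1",      "PAPER", "RSK-P dephosphorylation (fit)"),
    .pentry("R0",  v("E0"), "nM",      "PAPER", "total RSK pool (stated equal to total ERK1/2)")
  )
  ext2 <- rbind(
    rsk,
    .pentry("k10",       v("k5"),  "nM-1 s-1", "PAPER", "RTF phosphorylation by RSK-P (stated equal to k5)"),
    .pentry("km10",      v("km5"), "s-1",      "PAPER", "RTF-P dephosphorylation (stated equal to km5)"),
    .pentry("lambda2",   1e-4,     "nM-1 s-1", "PAPER", "RTF-P association with Atf3 promoter (stated equal to lambda1)"),
    .pentry("lambda_m2", 1e-5,     "s-1",      "PAPER", "RTF-P dissociation from Atf3 promoter (stated equal to lambda_m1)"),
    .pentry("RTF0",      2,        "nM",       "DEFAULT", "total RTF pool")
  )
  ext3 <- rbind(
    rsk,
    .pentry("k13",   v("k6"),        "s-1",      "PAPER",   "ITF transcription (stated equal to k6)"),
    .pentry("k14",   v("k8"),        "s-1",      "PAPER",   "ITF translation (stated equal to k8)"),
    .pentry("d4",    v("d2"),        "s-1",      "PAPER",   "ITF mRNA degradation (stated equal to d2)"),
    .pentry("d5",    v("d3"),        "s-1",      "PAPER",   "ITF protein degradation (stated equal to d3)"),
    .pentry("K15",   v("K10"),       "nM",       "PAPER",   "ITF / Atf3-promoter dissociation constant (stated equal to K10)"),
    .pentry("k15",   1e-4,           "nM-1 s-1", "DEFAULT", "ITF association with Atf3 promoter"),
    .pentry("km15",  1e-4 * v("K10"), "s-1",     "DEFAULT", "ITF dissociation from Atf3 promoter (k15 * K15)"),
    .pentry("P_itf", 0.01,           "nM",       "DEFAULT", "total ITF promoter")
  )
  ext4 <- rbind(
    rsk,
    .pentry("k16",     v("k3"),          "nM-1 s-1", "PAPER",   "phosphorylation of miDNA-bound RTF by RSK-P (stated equal to k3)"),
    .pentry("km16",    v("km3"),         "s-1",      "PAPER",   "dephosphorylation of miDNA-bound RTF (stated equal to km3)"),
    .pentry("k17",     v("k6"),          "s-1",      "PAPER",   "premiRNA transcription (stated equal to k6)"),
    .pentry("k18",     0.5,              "s-1",      "PAPER",   "premiRNA maturation to miRNA (0.5/s)"),
    .pentry("k19",     1e-4,             "nM-1 s-1", "PAPER",   "miRNA association with Atf3 mRNA (1e5 (Ms)-1)"),
    .pentry("km19",    5e-5,             "s-1",      "PAPER",   "miRNA.mRNA complex dissociation (5e-5/s, best qualitative fit)"),
    .pentry("d6",      log(2) / 86400,   "s-1",      "PAPER",   "premiRNA decay (~24 h half-life)"),
    .pentry("d7",      log(2) / 86400,   "s-1",      "PAPER",   "miRNA decay (~24 h half-life)"),
    .pentry("d8",      v("d2"),          "s-1",      "PAPER",   "miRNA.mRNA complex decay, baseline equal to Atf3 mRNA degradation"),
    .pentry("d8_mult", 1,                "-",        "DEFAULT", "scenario multiplier on d8 (reproduction configs use 1, 2 or 4)"),
    .pentry("P_mi",    0.08,             "nM",       "DEFAULT", "total miDNA promoter (several co-regulated miRNA genes)")
  )
  switch(variant,
    BASE          = base[0, ],
    EXT1_AUTOREP  = ext1,
    EXT2_RTF      = ext2,
    EXT3_ITF      = ext3,
    EXT4_MIRNA    = ext4,
    EXT5_COMBINED = {
      both <- rbind(ext3, ext4)
      both[!duplicated(both$name), ]
    })
}

#' Default parameter set for a model variant
#'
#' Returns the full parameter table for a variant.  Every entry carries a
#' provenance tag: \code{"PAPER"} for values (or equalities) printed in the
#' source literature, \code{"TEXT_S1"} for values transcribed from its
#' supplementary model description (none in this build), and
#' \code{"DEFAULT"} for package-calibrated values.  Parameters stated to be
#' equal (for example \code{k10 = k5}) are stored as independent copies with
#' equal values, so a sensitivity scan can perturb one without the other.
#'
#' @param variant One of [model_variants()].
#' @return A \code{parameter_set}: data frame with columns \code{name},
#'   \code{value}, \code{units}, \code{provenance}, \code{description}.
#' @export
#' @examples
#' p <- default_parameters("EXT1_AUTOREP")
#' param_value(p, "K11")   # 0.1 nM
default_parameters <- function(variant) {
  .check_variant(variant)
  base <- .base_param_table()
  tab <- rbind(base, .ext_param_table(variant, base))
  rownames(tab) <- NULL
  stopifnot(!anyDuplicated(tab$name), all(tab$value > 0 | tab$name == "S0"))
  structure(tab, class = c("parameter_set", "data.frame"),
            variant = variant)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set (", attr(x, "variant"), "), ", nrow(x),
      " parameters\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Look up a parameter value
#'
#' @param params A \code{parameter_set}.
#' @param name Parameter name.
#' @return Numeric value.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) {
    stop("unknown parameter '", name, "'; valid names are: ",
         paste(params$name, collapse = ", "), call. = FALSE)
  }
  params$value[i]
}

#' Multiply one parameter by a fold factor
#'
#' Returns a new parameter set identical to \code{params} except that the
#' named entry is multiplied by \code{factor}; the input is not modified.
#' This is the perturbation primitive used by the tight-binding scenarios
#' (e.g. a 1e6-fold increase in a repressor association rate) and by the
#' local sensitivity scan.
#'
#' @param params A \code{parameter_set}.
#' @param name Parameter name to perturb.
#' @param factor Positive multiplier.
#' @return A new \code{parameter_set}.
#' @export
#' @examples
#' p <- default_parameters("EXT3_ITF")
#' p2 <- apply_override(p, "k15", 1e6)
apply_override <- function(params, name, factor) {
  if (!(is.numeric(factor) && length(factor) == 1L && is.finite(factor) &&
        factor > 0)) {
    stop("override factor must be a single positive finite number",
         call. = FALSE)
  }
  i <- match(name, params$name)
  if (is.na(i)) {
    stop("unknown parameter '", name, "'; valid names are: ",
         paste(params$name, collapse = ", "), call. = FALSE)
  }
  params$value[i] <- params$value[i] * factor
  params
}

## Set a parameter to an absolute value (internal; used for switches such as
## turning the stimulus or the Atf3->Egr1 feedback off).
.set_param <- function(params, name, value) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter '", name, "'", call. = FALSE)
  params$value[i] <- value
  params
}

## Named numeric vector view used by the ODE right-hand sides.
.param_vector <- function(params) setNames(params$value, params$name)

#' Write / read a parameter set as YAML
#'
#' The file is a flat mapping from parameter name to a mapping with keys
#' \code{value}, \code{units} and \code{provenance} (plus
#' \code{description}), together with the variant label.
#'
#' @param params A \code{parameter_set}.
#' @param path File path.
#' @return \code{write_parameters} returns \code{path} invisibly;
#'   \code{read_parameters} returns a \code{parameter_set}.
#' @export
write_parameters <- function(params, path) {
  entries <- lapply(seq_len(nrow(params)), function(i) {
    list(value = params$value[i], units = params$units[i],
         provenance = params$provenance[i],
         description = params$description[i])
  })
  names(entries) <- params$name
  yaml::write_yaml(list(variant = attr(params, "variant"),
                        parameters = entries), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(names(obj$parameters), function(nm) {
    e <- obj$parameters[[nm]]
    .pentry(nm, as.numeric(e$value), e$units, e$provenance,
            e$description %||% "")
  }))
  structure(tab, class = c("parameter_set", "data.frame"),
            variant = obj$variant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
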