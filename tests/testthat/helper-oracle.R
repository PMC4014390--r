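# Independent reaction-by-reaction oracle for the ODE right-hand sides.
#
# Each variant is described as an explicit list of reactions with
# stoichiometry (consumed / produced species) and a mass-action rate
# function; the oracle derivative is the stoichiometry-weighted sum of
# rates.  This is deliberately a different construction from the package's
# hand-coded derivative functions.

rxn <- function(rate, consume = character(), produce = character()) {
  list(rate = rate, consume = consume, produce = produce)
}

oracle_reactions <- function(variant, p) {
  r <- list(
    rxn(function(y) p["k1"] * p["S0"] * y["MKK_I"], "MKK_I", "MKK_A"),
    rxn(function(y) p["d_mkk"] * y["MKK_A"], "MKK_A", "MKK_R"),
    rxn(function(y) p["k_rec"] * y["MKK_R"], "MKK_R", "MKK_I"),
    rxn(function(y) p["k2"] * y["MKK_A"] * y["ERK"], "ERK", "ERK_P"),
    rxn(function(y) p["d_erk"] * y["ERK_P"], "ERK_P", "ERK"),
    rxn(function(y) p["k5"] * y["ERK_P"] * y["PA_TF"], "PA_TF", "PA_TFP"),
    rxn(function(y) p["km5"] * y["PA_TFP"], "PA_TFP", "PA_TF"),
    rxn(function(y) p["k3"] * y["ERK_P"] * y["PE_TF"], "PE_TF", "PE_TFP"),
    rxn(function(y) p["km3"] * y["PE_TFP"], "PE_TFP", "PE_TF"),
    rxn(function(y) p["k4"] * y["ATF3"] * y["PE_TF"],
        c("PE_TF", "ATF3"), "PE_ATF3"),
    rxn(function(y) p["k4"] * y["ATF3"] * y["PE_TFP"],
        c("PE_TFP", "ATF3"), "PE_ATF3"),
    rxn(function(y) p["km4"] * y["PE_ATF3"], "PE_ATF3",
        c("PE_TF", "ATF3")),
    rxn(function(y) p["k6"] * y["PA_TFP"], character(), "mATF3"),
    rxn(function(y) p["d2"] * y["mATF3"], "mATF3"),
    rxn(function(y) p["k8"] * y["mATF3"], character(), "ATF3"),
    rxn(function(y) p["d3"] * y["ATF3"], "ATF3"),
    rxn(function(y) p["k7"] * y["PE_TFP"], character(), "mEGR1"),
    rxn(function(y) p["d_megr1"] * y["mEGR1"], "mEGR1")
  )
  rsk <- list(
    rxn(function(y) p["k9"] * y["ERK_P"] * y["RSK"], "RSK", "RSK_P"),
    rxn(function(y) p["d10"] * y["RSK_P"], "RSK_P", "RSK"))
  if (variant == "EXT1_AUTOREP") {
    r <- c(r, list(
      rxn(function(y) p["lambda1"] * y["ATF3"] * y["PA_TF"],
          c("PA_TF", "ATF3"), "PA_ATF3"),
      rxn(function(y) p["lambda_m1"] * y["PA_ATF3"], "PA_ATF3",
          c("PA_TF", "ATF3"))))
  }
  if (variant == "EXT2_RTF") {
    r <- c(r, rsk, list(
      rxn(function(y) p["k10"] * y["RSK_P"] * y["RTF"], "RTF", "RTF_P"),
      rxn(function(y) p["km10"] * y["RTF_P"], "RTF_P", "RTF"),
      rxn(function(y) p["lambda2"] * y["RTF_P"] * y["PA_TF"],
          c("PA_TF", "RTF_P"), "PA_RTFP"),
      rxn(function(y) p["lambda2"] * y["RTF_P"] * y["PA_TFP"],
          c("PA_TFP", "RTF_P"), "PA_RTFP"),
      rxn(function(y) p["lambda_m2"] * y["PA_RTFP"], "PA_RTFP",
          c("PA_TF", "RTF_P"))))
  }
  if (variant %in% c("EXT3_ITF", "EXT5_COMBINED")) {
    r <- c(r, rsk, list(
      rxn(function(y) p["k13"] * p["P_itf"] * y["RSK_P"] / p["R0"],
          character(), "mITF"),
      rxn(function(y) p["d4"] * y["mITF"], "mITF"),
      rxn(function(y) p["k14"] * y["mITF"], character(), "ITF"),
      rxn(function(y) p["d5"] * y["ITF"], "ITF"),
      rxn(function(y) p["k15"] * y["ITF"] * y["PA_TF"],
          c("PA_TF", "ITF"), "PA_ITF"),
      rxn(function(y) p["km15"] * y["PA_ITF"], "PA_ITF",
          c("PA_TF", "ITF"))))
  }
  if (variant %in% c("EXT4_MIRNA", "EXT5_COMBINED")) {
    r <- c(r, rsk, list(
      rxn(function(y) p["k16"] * y["RSK_P"] * y["MI_RTF"], "MI_RTF",
          "MI_RTFP"),
      rxn(function(y) p["km16"] * y["MI_RTFP"], "MI_RTFP", "MI_RTF"),
      rxn(function(y) p["k17"] * y["MI_RTFP"], character(), "preMIR"),
      rxn(function(y) p["k18"] * y["preMIR"], "preMIR", "MIR"),
      rxn(function(y) p["d6"] * y["preMIR"], "preMIR"),
      rxn(function(y) p["d7"] * y["MIR"], "MIR"),
      rxn(function(y) p["k19"] * y["MIR"] * y["mATF3"],
          c("MIR", "mATF3"), "MIR_mATF3"),
      rxn(function(y) p["km19"] * y["MIR_mATF3"], "MIR_mATF3",
          c("MIR", "mATF3")),
      # complex decay destroys the mRNA, recycles the miRNA
      rxn(function(y) p["d8"] * p["d8_mult"] * y["MIR_mATF3"],
          "MIR_mATF3", "MIR")))
  }
  # EXT5 gained the shared RSK cycle twice; drop exact duplicates
  if (variant == "EXT5_COMBINED") {
    seen <- character()
    keep <- logical(length(r))
    for (i in seq_along(r)) {
      key <- paste(deparse(body(r[[i]]$rate)),
                   paste(r[[i]]$consume, collapse = ","),
                   paste(r[[i]]$produce, collapse = ","))
      keep[i] <- !(key %in% seen)
      seen <- c(seen, key)
    }
    r <- r[keep]
  }
  r
}

oracle_rhs <- function(variant, params, y) {
  p <- setNames(params$value, params$name)
  d <- setNames(numeric(length(y)), names(y))
  for (rx in oracle_reactions(variant, p)) {
    v <- rx$rate(y)
    for (s in rx$consume) d[s] <- d[s] - v
    for (s in rx$produce) d[s] <- d[s] + v
  }
  d
}

# Random strictly positive state for a variant, reproducible.
random_state <- function(variant, seed) {
  set.seed(seed)
  sp <- species_names(variant)
  setNames(exp(rnorm(length(sp), mean = -1, sd = 1.5)), sp)
}
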