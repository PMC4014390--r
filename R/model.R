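## Reaction networks and ODE right-hand sides for the six model variants.
##
## All reactions are mass action.  Promoters are modelled as conserved pools
## of mutually exclusive occupancy states; the activator TF stays
## promoter-associated and is toggled between unphosphorylated and
## phosphorylated forms by ERK-P (or RSK-P on the miDNA promoter).
## Repressors compete for promoters as follows: Atf3 displaces the Egr1
## activator in either phosphorylation state; on the Atf3 promoter the
## EXT1/EXT3 repressors (Atf3 itself, ITF) bind only the unphosphorylated
## activator complex, while the EXT2 phospho-RTF displaces either state.

.variant_has <- function(variant, what) {
  switch(what,
    rsk  = variant %in% c("EXT2_RTF", "EXT3_ITF", "EXT4_MIRNA", "EXT5_COMBINED"),
    ext1 = variant == "EXT1_AUTOREP",
    ext2 = variant == "EXT2_RTF",
    itf  = variant %in% c("EXT3_ITF", "EXT5_COMBINED"),
    mirna = variant %in% c("EXT4_MIRNA", "EXT5_COMBINED"),
    stop("internal: unknown feature ", what))
}

## Required parameter names per variant (beyond validation in
## default_parameters, build_rhs re-checks so hand-built sets fail loudly).
.required_params <- function(variant) {
  base <- .base_param_table()$name
  extra <- .ext_param_table(variant, .base_param_table())$name
  c(base, extra)
}

#' Build the ODE right-hand side for a model variant
#'
#' Returns a derivative function \code{f(t, state, parms)} in the form
#' expected by [deSolve::lsoda()].  The state is a named vector over
#' [species_names()] for the variant.
#'
#' @param variant One of [model_variants()].
#' @param params A \code{parameter_set} complete for the variant (see
#'   [default_parameters()]).
#' @return A function \code{(t, y, parms) -> list(dy)}.
#' @export
build_rhs <- function(variant, params) {
  .check_variant(variant)
  need <- .required_params(variant)
  missing_p <- setdiff(need, params$name)
  if (length(missing_p)) {
    stop("parameter set incomplete for ", variant, ": missing ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  p <- .param_vector(params)
  sp <- species_names(variant)
  has_rsk <- .variant_has(variant, "rsk")
  has_ext1 <- .variant_has(variant, "ext1")
  has_ext2 <- .variant_has(variant, "ext2")
  has_itf <- .variant_has(variant, "itf")
  has_mirna <- .variant_has(variant, "mirna")

  function(t, y, parms = NULL) {
    missing_s <- setdiff(sp, names(y))
    if (length(missing_s)) {
      stop("state vector missing species: ",
           paste(missing_s, collapse = ", "), call. = FALSE)
    }
    y <- y[sp]
    d <- setNames(numeric(length(sp)), sp)

    ## upstream kinase cascade
    act <- p["k1"] * p["S0"] * y["MKK_I"]
    inact <- p["d_mkk"] * y["MKK_A"]
    rec <- p["k_rec"] * y["MKK_R"]
    d["MKK_I"] <- rec - act
    d["MKK_A"] <- act - inact
    d["MKK_R"] <- inact - rec

    phos_e <- p["k2"] * y["MKK_A"] * y["ERK"]
    deph_e <- p["d_erk"] * y["ERK_P"]
    d["ERK"] <- deph_e - phos_e
    d["ERK_P"] <- phos_e - deph_e

    ## Atf3 promoter: activator TF phosphorylation cycle
    pa_on <- p["k5"] * y["ERK_P"] * y["PA_TF"]
    pa_off <- p["km5"] * y["PA_TFP"]
    d["PA_TF"] <- pa_off - pa_on
    d["PA_TFP"] <- pa_on - pa_off

    ## Egr1 promoter: activator cycle plus competitive Atf3 repression
    pe_on <- p["k3"] * y["ERK_P"] * y["PE_TF"]
    pe_off <- p["km3"] * y["PE_TFP"]
    bind_e <- p["k4"] * y["ATF3"] * (y["PE_TF"] + y["PE_TFP"])
    rel_e <- p["km4"] * y["PE_ATF3"]
    d["PE_TF"] <- pe_off - pe_on - p["k4"] * y["ATF3"] * y["PE_TF"] + rel_e
    d["PE_TFP"] <- pe_on - pe_off - p["k4"] * y["ATF3"] * y["PE_TFP"]
    d["PE_ATF3"] <- bind_e - rel_e

    ## transcription, translation, degradation
    d["mATF3"] <- p["k6"] * y["PA_TFP"] - p["d2"] * y["mATF3"]
    d["ATF3"] <- p["k8"] * y["mATF3"] - p["d3"] * y["ATF3"] - bind_e + rel_e
    d["mEGR1"] <- p["k7"] * y["PE_TFP"] - p["d_megr1"] * y["mEGR1"]

    if (has_rsk) {
      phos_r <- p["k9"] * y["ERK_P"] * y["RSK"]
      deph_r <- p["d10"] * y["RSK_P"]
      d["RSK"] <- deph_r - phos_r
      d["RSK_P"] <- phos_r - deph_r
    }

    if (has_ext1) {
      bind_a <- p["lambda1"] * y["ATF3"] * y["PA_TF"]
      rel_a <- p["lambda_m1"] * y["PA_ATF3"]
      d["PA_TF"] <- d["PA_TF"] - bind_a + rel_a
      d["ATF3"] <- d["ATF3"] - bind_a + rel_a
      d["PA_ATF3"] <- bind_a - rel_a
    }

    if (has_ext2) {
      phos_t <- p["k10"] * y["RSK_P"] * y["RTF"]
      deph_t <- p["km10"] * y["RTF_P"]
      bind_t <- p["lambda2"] * y["RTF_P"] * (y["PA_TF"] + y["PA_TFP"])
      rel_t <- p["lambda_m2"] * y["PA_RTFP"]
      d["RTF"] <- deph_t - phos_t
      d["RTF_P"] <- phos_t - deph_t - bind_t + rel_t
      d["PA_TF"] <- d["PA_TF"] - p["lambda2"] * y["RTF_P"] * y["PA_TF"] + rel_t
      d["PA_TFP"] <- d["PA_TFP"] - p["lambda2"] * y["RTF_P"] * y["PA_TFP"]
      d["PA_RTFP"] <- bind_t - rel_t
    }

    if (has_itf) {
      ## ITF transcription is driven by the phospho-RSK fraction (fast
      ## promoter-equilibration assumption; no explicit ITF promoter state)
      d["mITF"] <- p["k13"] * p["P_itf"] * y["RSK_P"] / p["R0"] -
        p["d4"] * y["mITF"]
      bind_i <- p["k15"] * y["ITF"] * y["PA_TF"]
      rel_i <- p["km15"] * y["PA_ITF"]
      d["ITF"] <- p["k14"] * y["mITF"] - p["d5"] * y["ITF"] - bind_i + rel_i
      d["PA_TF"] <- d["PA_TF"] - bind_i + rel_i
      d["PA_ITF"] <- bind_i - rel_i
    }

    if (has_mirna) {
      mi_on <- p["k16"] * y["RSK_P"] * y["MI_RTF"]
      mi_off <- p["km16"] * y["MI_RTFP"]
      d["MI_RTF"] <- mi_off - mi_on
      d["MI_RTFP"] <- mi_on - mi_off
      d["preMIR"] <- p["k17"] * y["MI_RTFP"] - p["k18"] * y["preMIR"] -
        p["d6"] * y["preMIR"]
      seq_on <- p["k19"] * y["MIR"] * y["mATF3"]
      seq_off <- p["km19"] * y["MIR_mATF3"]
      cplx_deg <- p["d8"] * p["d8_mult"] * y["MIR_mATF3"]
      ## complex decay destroys the mRNA and recycles the miRNA
      d["MIR"] <- p["k18"] * y["preMIR"] - p["d7"] * y["MIR"] -
        seq_on + seq_off + cplx_deg
      d["MIR_mATF3"] <- seq_on - seq_off - cplx_deg
      d["mATF3"] <- d["mATF3"] - seq_on + seq_off
    }

    list(d)
  }
}

## Canonical pre-stimulation state: pools unphosphorylated, promoters
## occupied by their unphosphorylated activator, no transcripts.
.initial_state <- function(variant, params) {
  p <- .param_vector(params)
  y <- setNames(numeric(length(species_names(variant))),
                species_names(variant))
  y["MKK_I"] <- p["M0"]
  y["ERK"] <- p["E0"]
  y["PA_TF"] <- p["P_atf3"]
  y["PE_TF"] <- p["P_egr1"]
  if (.variant_has(variant, "rsk")) y["RSK"] <- p["R0"]
  if (.variant_has(variant, "ext2")) y["RTF"] <- p["RTF0"]
  if (.variant_has(variant, "mirna")) y["MI_RTF"] <- p["P_mi"]
  y
}

#' Unstimulated steady state of a model variant
#'
#' Integrates the model with the stimulus set to zero until the maximum
#' derivative is below \code{tol} relative to the largest state component,
#' and returns the resulting state (used as the initial condition for
#' stimulation runs).
#'
#' @param variant One of [model_variants()].
#' @param params A \code{parameter_set}.
#' @param tol Relative derivative tolerance (default 1e-10).
#' @param max_time Maximum simulated relaxation time in seconds.
#' @return Named state vector at the basal steady state.
#' @export
basal_state <- function(variant, params, tol = 1e-10, max_time = 1e7) {
  params0 <- .set_param(params, "S0", 0)
  rhs <- build_rhs(variant, params0)
  y <- .initial_state(variant, params0)
  elapsed <- 0
  chunk <- 1e5
  repeat {
    dv <- rhs(0, y)[[1]]
    resid <- max(abs(dv))
    if (resid < tol * max(max(abs(y)), 1e-12)) {
      return(y)
    }
    if (elapsed >= max_time) {
      stop("basal_state did not converge within ", max_time,
           " s; residual derivative norm = ", signif(resid, 4),
           call. = FALSE)
    }
    out <- deSolve::lsoda(y, c(0, chunk), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-14)
    y <- setNames(as.numeric(out[2, -1]), colnames(out)[-1])
    elapsed <- elapsed + chunk
  }
}

#' Conservation totals of a model variant
#'
#' Returns the list of conserved pools (species groups whose concentrations
#' must sum to a constant along any trajectory): the MKK pool, the ERK pool,
#' the RSK and RTF pools where present, and each promoter's occupancy states.
#'
#' @param variant One of [model_variants()].
#' @return Named list of character vectors of species names.
#' @export
conserved_pools <- function(variant) {
  .check_variant(variant)
  pools <- list(
    mkk = c("MKK_I", "MKK_A", "MKK_R"),
    erk = c("ERK", "ERK_P"),
    atf3_promoter = intersect(
      c("PA_TF", "PA_TFP", "PA_ATF3", "PA_RTFP", "PA_ITF"),
      species_names(variant)),
    egr1_promoter = c("PE_TF", "PE_TFP", "PE_ATF3")
  )
  if (.variant_has(variant, "rsk")) pools$rsk <- c("RSK", "RSK_P")
  if (.variant_has(variant, "ext2")) pools$rtf <- c("RTF", "RTF_P", "PA_RTFP")
  if (.variant_has(variant, "mirna")) pools$midna <- c("MI_RTF", "MI_RTFP")
  pools
}
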