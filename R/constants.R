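#' Physiological constants and prior means of the microcircuit
#'
#' Central registry of the fixed constants and prior means used throughout the
#' model: reversal potentials (sodium 60 mV carried by AMPA channels, calcium
#' 10 mV by NMDA channels, chloride -70 mV by GABA-A channels), the potassium
#' leak reversal (-70 mV), prior channel time constants (AMPA 12 ms, GABA-A
#' 8 ms, NMDA 100 ms), the magnesium-block sigmoid defaults, the firing
#' non-linearity, intrinsic/extrinsic coupling prior weights and the
#' population contribution weights of the lead field.
#'
#' All free neuronal parameters are log-scaling factors applied to the prior
#' means recorded here.
#'
#' @param ... Named overrides replacing individual defaults (e.g.
#'   `bg = 15`, `w_gaba = c(ss_ii = 1, sp_ii = 2, dp_ii = 1, ii_ii = 1.5)`).
#' @return A named list of constants.
#' @export
cmc_constants <- function(...) {
  defaults <- list(
    populations = c("SS", "SP", "II", "DP"),
    receptors   = c("AMPA", "GABAA", "NMDA"),
    # reversal potentials, mV (Na / Cl / Ca carriers)
    rev  = c(AMPA = 60, GABAA = -70, NMDA = 10),
    VL   = -70,          # potassium leak reversal, mV
    gL   = 1,            # leak conductance, a.u.
    C    = 16,           # membrane capacitance; tau_m = C/gL = 16 ms
    VR   = -40,          # firing threshold, mV
    sigma2 = 64,         # ensemble firing variance prior, mV^2
    tau  = c(AMPA = 12, GABAA = 8, NMDA = 100),  # channel time constants, ms
    mg   = c(alpha = 1.5, beta = 0.33, gamma = 0.06),  # Mg-block sigmoid
    bg   = 18,           # background depolarising current, a.u. * mV
    delay_intra = 2,     # intra-source transmission delay prior, ms
    delay_ext   = 16,    # inter-source delay (fixed), ms
    # intrinsic coupling prior weights (post_pre)
    w_ampa   = c(sp_ss = 1.35, ii_ss = 0.5, dp_sp = 1.35, ii_sp = 2.65,
                 ii_dp = 0.4),
    w_gaba   = c(ss_ii = 1.0, sp_ii = 2.55, dp_ii = 1.1, ii_ii = 1.0),
    w_nmda_e = c(sp_ss = 1.4, dp_sp = 1.4),
    w_nmda_i = c(ii_ss = 0.5, ii_sp = 1.65, ii_dp = 1.0),
    w_spss_nmda = 0.3,   # model-variant SP -> SS NMDA interconnection
    # extrinsic coupling prior weights (AMPA-mediated)
    w_fwd = 0.8, w_bwd = 0.4, w_lat = 0.3,
    # population contributions to the measured signal; II does not reach EEG
    pop_weights = c(SS = 0.1, SP = 0.6, II = 0, DP = 0.3)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown))
      stop("unknown constants: ", paste(unknown, collapse = ", "))
    defaults[names(dots)] <- dots
  }
  defaults
}

#' Channel specifications
#'
#' One row per ionotropic receptor: its reversal potential and prior time
#' constant. Excitatory reversals exceed the leak reversal, which is not
#' exceeded by the GABA-A (chloride) reversal.
#'
#' @return A data frame with columns `receptor`, `reversal_potential` (mV) and
#'   `prior_time_constant` (ms).
#' @export
channel_specs <- function() {
  k <- cmc_constants()
  data.frame(
    receptor = k$receptors,
    reversal_potential = unname(k$rev[k$receptors]),
    prior_time_constant = unname(k$tau[k$receptors]),
    stringsAsFactors = FALSE
  )
}
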