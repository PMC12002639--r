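# Default kinetic parameters and initial state.
#
# The network is a documented reduction (~87 states, ~80 processes) of the
# full NGV metabolic model class: symmetric saturable carriers for all
# facilitated transport, irreversible Michaelis-Menten for committed enzyme
# steps, reversible mass-action-to-Keq for LDH / TPI / MDH / the
# malate-aspartate shuttle, and Hill (n = 4) ATP-inhibition / ADP-activation
# on the committed glycolytic step. Vmax values are design choices calibrated
# so that the control simulation has a stable resting state with
# physiological concentration ranges and a resting neuronal ATP turnover
# dominated by the Na+/K+-ATPase.

#' Construct the default parameter set
#'
#' Returns the complete, validated parameter vector of the reduced NGV
#' model: transporter and enzyme kinetic constants (Vmax mM/s, Km mM,
#' equilibrium constants), conserved-pool totals, compartment volume
#' fractions, membrane/pump constants and blood boundary set points.
#' Construction is deterministic; repeated calls return identical objects.
#'
#' @return A named numeric vector of class `ngv_params`.
#' @export
make_default_parameters <- function() {
  vols <- ngv_volumes()
  p <- c(
    ## --- volumes (dimensionless fractions of the NGV unit) ---
    vol_blood = unname(vols["blood"]), vol_endo = unname(vols["endothelium"]),
    vol_ecsBA = unname(vols["ecsBA"]), vol_ecsAN = unname(vols["ecsAN"]),
    vol_n_cyt = unname(vols["neuron_cyt"]), vol_n_mit = unname(vols["neuron_mito"]),
    vol_n_ims = unname(vols["neuron_ims"]), vol_a_cyt = unname(vols["astro_cyt"]),
    vol_a_mit = unname(vols["astro_mito"]), vol_a_ims = unname(vols["astro_ims"]),

    ## --- blood boundary (arterial set points, mM; relaxation rate 1/s) ---
    glc_b_set = 5.0, lac_b_set = 1.0, bhb_b_set = 0.3,
    blood_relax_k = 0.5, o2_blood = 0.06, o2_supply_k = 40.0,

    ## --- facilitated transport (symmetric saturable carriers) ---
    ## GLUT1 partitions (the four disease-scaled steps), GLUT3 on the neuron
    glut1_be_vmax = 4.0, glut1_ee_vmax = 3.5, glut1_ea_vmax = 3.2,
    glut1_an_vmax = 1.5, glut3_vmax = 1.5,
    km_glut1 = 8.0, km_glut3 = 2.8,
    ## monocarboxylate transporters (lactate)
    mct_be_vmax = 2.0, mct_ee_vmax = 1.6, mct_ea_vmax = 1.2,
    mct_an_vmax = 0.6, mct_n_vmax = 0.15, km_mct = 4.0,
    ## ketone body transport
    bhbt_be_vmax = 0.4, bhbt_ee_vmax = 0.4, bhbt_ea_vmax = 0.35,
    bhbt_an_vmax = 0.3, bhbt_n_vmax = 0.3, km_bhbt = 1.5,

    ## --- glycolysis (per-cell Vmax, shared Km) ---
    hk_vmax_n = 0.06, hk_vmax_a = 0.105,
    km_hk_glc = 1.2, km_hk_atp = 0.15, ki_hk_hkpf = 0.45,
    pfk_vmax_n = 0.2, pfk_vmax_a = 0.5,
    km_pfk_hkpf = 5.0, km_pfk_atp = 0.1,
    ki_pfk_atp = 2.8, ka_pfk_adp = 0.002, hill_pfk = 4,
    ald_vmax_n = 0.25, ald_vmax_a = 0.3, km_ald = 0.1,
    tpi_k = 5.0, keq_tpi = 0.045,
    lgly_vmax_n = 0.8, lgly_vmax_a = 0.9,
    km_lgly_gap = 0.02, km_lgly_nad = 0.03, km_lgly_adp = 0.03,
    ldh_k = 40.0, keq_ldh = 1000,

    ## --- mitochondrial import and TCA cycle ---
    mpc_vmax_n = 2.0, mpc_vmax_a = 1.5, km_mpc = 0.8,
    pdh_vmax_n = 2.0, pdh_vmax_a = 1.5,
    km_pdh_pyr = 0.06, km_pdh_coa = 0.02, km_pdh_nad = 0.06,
    pc_vmax_n = 0.03, pc_vmax_a = 0.06, km_pc = 0.25,
    cs_vmax = 8.0, km_cs_accoa = 0.02, km_cs_oxa = 0.005,
    acn_vmax = 2.0, km_acn = 0.3,
    idh_vmax = 2.5, km_idh_isocit = 0.05, km_idh_nad = 0.06,
    kgdh_vmax = 2.0, km_kgdh_akg = 0.2, km_kgdh_coa = 0.02, km_kgdh_nad = 0.06,
    scs_vmax = 2.0, km_scs_succoa = 0.05, km_scs_adp = 0.3,
    sdh_vmax = 1.5, km_sdh = 0.5,
    fum_vmax = 2.0, km_fum = 0.1,
    mdh_k = 10.0, keq_mdh = 0.05,
    mal_drain_k = 0.005, akg_drain_k = 0.005,

    ## --- oxidative phosphorylation ---
    etc_vmax_n = 2.0, etc_vmax_a = 1.6,
    km_etc_nadh_n = 0.05, km_etc_nadh_a = 1.2, km_etc_o2 = 0.01,
    p_o_ratio = 2.5, km_syn_adp = 0.3,
    ant_k_n = 60.0, ant_k_a = 40.0, km_ant = 0.5, km_ant_adp = 0.01,
    ims_exp_k_n = 500.0, ims_exp_k_a = 350.0, km_ims = 0.6,

    ## --- shuttles, PPP, glutathione, ketones, glycogen ---
    mas_k_n = 10.0, mas_k_a = 10.0, keq_mas = 66,
    ppp_vmax_n = 0.01, ppp_vmax_a = 0.015,
    km_ppp_hkpf = 0.1, km_ppp_nadp = 0.002,
    gr_vmax = 0.1, km_gr_gssg = 0.05, km_gr_nadph = 0.01,
    ros_k = 0.01, km_ros_gsh = 0.5,
    bhb_ut_vmax_n = 0.02, bhb_ut_vmax_a = 0.03,
    km_bhb_ut = 0.25, km_bhb_nad = 0.05,
    glysyn_vmax = 0.05, km_glysyn_hkpf = 0.3, gly_cap = 8.0,
    glyphos_vmax = 0.2, km_glyphos = 1.0, ki_glyphos_glc = 0.4,

    ## --- housekeeping ATP demand (non-pump) ---
    hk_atpase_n = 0.02, hk_atpase_a = 0.06, km_hk_atpase = 0.5,

    ## --- conserved pool totals (mM) ---
    nad_tot_cyt = 0.5, nadp_tot = 0.1, gs_tot = 2.1,
    nad_tot_mit_n = 0.5, nad_tot_mit_a = 1.0, coa_tot = 1.1,

    ## --- Na+/K+-ATPase (neuron) ---
    pump_vmax = 4.67, km_pump_atp = 2.5, hill_pump_atp = 3.0,
    km_pump_glc = 1.0, km_pump_na = 25.0, hill_pump_na = 1.5,
    km_pump_k = 15.0,

    ## --- membrane (Hodgkin-Huxley) ---
    gna = 120, gk = 36, gna_leak = 0.0394, gl = 0.3, el = -70, cm = 1.0,
    na_out = 145, k_in = 140,
    ion_conv = 0.02,        # mM per (uA/cm^2 * s) for intracellular Na
    ecs_k_ratio = 3.0,      # cytosol : effective perineuronal K space
    k_bath = 4.0, k_clear = 2.0, km_clear = 1.0, k_clear_thresh = 1.5,
    k_resupply = 0.5
  )
  class(p) <- "ngv_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks strict positivity of kinetic constants, the intracellular volume
#' partition (cytosol + mitochondria + IMS sum to each cell's volume), and
#' the lower neuronal pyruvate carboxylase expression.
#'
#' @param p A parameter vector from [make_default_parameters()].
#' @return `p` invisibly; stops with a message naming the violated rule.
#' @export
validate_parameters <- function(p) {
  if (any(!is.finite(p))) stop("non-finite parameter: ",
                               paste(names(p)[!is.finite(p)], collapse = ", "))
  kin <- grep("^(km_|ki_|ka_|keq_)|(_vmax|_k)$", names(p), value = TRUE)
  bad <- kin[p[kin] <= 0]
  if (length(bad)) stop("non-positive kinetic constant: ",
                        paste(bad, collapse = ", "))
  if (p[["pc_vmax_n"]] >= p[["pc_vmax_a"]])
    stop("neuronal PC Vmax must be below astrocytic PC Vmax")
  for (cell in c("n", "a")) {
    v <- p[[paste0("vol_", cell, "_cyt")]] + p[[paste0("vol_", cell, "_mit")]] +
      p[[paste0("vol_", cell, "_ims")]]
    tot <- ngv_volumes()[[if (cell == "n") "neuron_cyt" else "astro_cyt"]] /
      0.88
    if (abs(v - tot) > 1e-9)
      stop("cell volume fractions do not sum to the cell volume: ", cell)
  }
  invisible(p)
}

#' Default initial state of the NGV unit
#'
#' The control resting state of the default parameterization (mM; membrane
#' voltage mV, gating variables dimensionless), precomputed by long
#' relaxation plus a Newton solve of the full right-hand side. Using the
#' resting fixed point as the integration starting point keeps pre-run
#' relaxation short; for modified parameters (disease, therapies)
#' [relax_to_rest()] re-equilibrates from here.
#'
#' @param params Parameter vector (unused; kept so callers can thread a
#'   parameter set through).
#' @return Named numeric vector of class `ngv_state`.
#' @export
default_initial_state <- function(params = NULL) {
  s <- c(
    Glc_b = 5,
    Lac_b = 1,
    bHB_b = 0.3,
    Glc_t_t = 3.86131378,
    Lac_t_t = 1.705830955,
    bHB_t_t = 0.2091700027,
    Glc_ecsBA = 2.781990365,
    Lac_ecsBA = 2.928400914,
    bHB_ecsBA = 0.1270664255,
    Glc_ecsAN = 2.099855053,
    Lac_ecsAN = 4.098569672,
    bHB_ecsAN = 0.07938359167,
    Glc_n = 1.807411535,
    HKPF_n = 0.9355804132,
    FBP_n = 0.004428340925,
    GAP_n = 0.01612603201,
    DHAP_n = 0.3604765442,
    PYR_n = 0.3830391933,
    Lac_n = 4.273704305,
    NAD_n = 0.4944624292,
    NADH_n = 0.005537570849,
    NADP_n = 9.019164287e-05,
    NADPH_n = 0.09990980836,
    ATP_n = 2.290341324,
    ADP_n = 0.002016262875,
    GSH_n = 2.099134879,
    GSSG_n = 0.0004325604641,
    bHB_n = 0.0679113656,
    Glc_a = 2.270880178,
    HKPF_a = 0.8016342912,
    FBP_a = 0.008267671545,
    GAP_a = 0.1437487764,
    DHAP_a = 3.198999049,
    PYR_a = 0.02048437896,
    Lac_a = 4.083015291,
    NAD_a = 0.3808619163,
    NADH_a = 0.1191380837,
    NADP_a = 4.161954147e-05,
    NADPH_a = 0.09995838046,
    ATP_a = 2.290398479,
    ADP_a = 0.002002041555,
    GSH_a = 2.099398267,
    GSSG_a = 0.0003008667468,
    bHB_a = 0.08359704492,
    PYRmito_n = 0.3650472926,
    AcCoAmito_n = 0.0004454558904,
    CoAmito_n = 0.002461433743,
    CITmito_n = 0.02847967826,
    ISOCITmito_n = 0.004268480501,
    AKGmito_n = 1.273303378,
    SUCCOAmito_n = 1.09709311,
    SUCmito_n = 0.06265605296,
    FUMmito_n = 0.009112918201,
    MALmito_n = 2.287859733,
    OXAmito_n = 0.966335724,
    NADmito_n = 0.447795865,
    NADHmito_n = 0.05220413498,
    ATPmito_n = 2.971296069,
    ADPmito_n = 0.02870393136,
    O2mito_n = 0.04938087734,
    Qpool_n = 0.85,
    PYRmito_a = 0.01469024309,
    AcCoAmito_a = 0.002040041826,
    CoAmito_a = 0.03375907143,
    CITmito_a = 0.02112158752,
    ISOCITmito_a = 0.00621270415,
    AKGmito_a = 0.05625485098,
    SUCCOAmito_a = 1.064200887,
    SUCmito_a = 0.04795224094,
    FUMmito_a = 0.007024417852,
    MALmito_a = 0.6097421498,
    OXAmito_a = 0.001080151905,
    NADmito_a = 0.05452631158,
    NADHmito_a = 0.9454736884,
    ATPmito_a = 2.977863592,
    ADPmito_a = 0.02213640844,
    O2mito_a = 0.05259439961,
    Qpool_a = 0.85,
    ATPims_n = 2.336266181,
    ATPims_a = 2.334377097,
    GLY_a = 2.362538916,
    V = -69.25122668,
    gate_m = 0.03170358456,
    gate_h = 0.7331083765,
    gate_n = 0.2550074606,
    Na_in = 7.902642965,
    K_out = 3.972297414
  )
  stopifnot(identical(names(s), ngv_state_names()))
  class(s) <- "ngv_state"
  s
}

#' Conserved-moiety pool values
#'
#' Computes the conserved chemical pools of the network: NAD+ + NADH and
#' NADP+ + NADPH per cytosol, NAD+ + NADH per mitochondrion, GSH + 2 GSSG,
#' total CoA-containing species, and the adenine pool volume-weighted across
#' cytosol, mitochondrion and IMS of each cell. These sums are invariant
#' under the network's stoichiometry; trajectory drift measures integration
#' error.
#'
#' @param state State vector.
#' @param params Parameter vector.
#' @return Named numeric vector of pool values (mM in the reference
#'   compartment; adenine in cytosol-equivalent mM).
#' @export
conserved_pools <- function(state, params) {
  s <- as.numeric(state); names(s) <- names(state)
  p <- params
  out <- c()
  for (cell in c("n", "a")) {
    sf <- paste0("_", cell)
    vc <- p[[paste0("vol_", cell, "_cyt")]]
    vm <- p[[paste0("vol_", cell, "_mit")]]
    vi <- p[[paste0("vol_", cell, "_ims")]]
    out[paste0("nad_cyt", sf)] <- s[paste0("NAD", sf)] + s[paste0("NADH", sf)]
    out[paste0("nadp_cyt", sf)] <- s[paste0("NADP", sf)] + s[paste0("NADPH", sf)]
    out[paste0("nad_mit", sf)] <- s[paste0("NADmito", sf)] + s[paste0("NADHmito", sf)]
    out[paste0("glutathione", sf)] <- s[paste0("GSH", sf)] + 2 * s[paste0("GSSG", sf)]
    out[paste0("coa", sf)] <- s[paste0("CoAmito", sf)] + s[paste0("AcCoAmito", sf)] +
      s[paste0("SUCCOAmito", sf)]
    out[paste0("adenine", sf)] <-
      (vc * (s[paste0("ATP", sf)] + s[paste0("ADP", sf)]) +
       vm * (s[paste0("ATPmito", sf)] + s[paste0("ADPmito", sf)]) +
       vi * s[paste0("ATPims", sf)]) / vc
  }
  out
}
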