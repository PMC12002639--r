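# Registered processes of the reduced NGV network and the stoichiometric
# assembly of the metabolic right-hand side.
#
# Every process is an entry {name, reference compartment, stoichiometry,
# rate closure}. Stoichiometric coefficients are molecules per reaction
# event; at assembly each species derivative receives
#   coeff * rate * V(reference) / V(species compartment),
# so conserved moieties (NAD, NADP, adenine, CoA, glutathione) are conserved
# analytically, including across membranes. Blood species are a boundary:
# transport exchanges with blood are recorded as fluxes but do not deplete
# the blood compartment, whose states relax to their (possibly fluctuating)
# arterial set points.

# internal: build the full process list
ngv_process_list <- function() {
  procs <- list()
  add <- function(name, ref, stoich, rate) {
    procs[[name]] <<- list(name = name, ref = ref, stoich = stoich,
                           rate = rate)
  }

  ## ---- extracellular transport chains ----
  tr <- function(name, ref, from, to, vmax_par, km_par, boundary_from = FALSE) {
    st <- if (boundary_from) stats::setNames(1, to)
          else stats::setNames(c(-1, 1), c(from, to))
    add(name, ref, st, local({
      f <- from; t2 <- to; vp <- vmax_par; kp <- km_par
      function(s, p, drv) carrier_flux(s[[f]], s[[t2]], p[[vp]], p[[kp]])
    }))
  }
  tr("glut1_be", "endothelium", "Glc_b", "Glc_t_t", "glut1_be_vmax",
     "km_glut1", boundary_from = TRUE)
  tr("glut1_ee", "endothelium", "Glc_t_t", "Glc_ecsBA", "glut1_ee_vmax", "km_glut1")
  tr("glut1_ea", "ecsBA", "Glc_ecsBA", "Glc_a", "glut1_ea_vmax", "km_glut1")
  tr("glut1_an", "astro_cyt", "Glc_a", "Glc_ecsAN", "glut1_an_vmax", "km_glut1")
  tr("glut3_n", "ecsAN", "Glc_ecsAN", "Glc_n", "glut3_vmax", "km_glut3")
  tr("mct_be", "endothelium", "Lac_b", "Lac_t_t", "mct_be_vmax", "km_mct",
     boundary_from = TRUE)
  tr("mct_ee", "endothelium", "Lac_t_t", "Lac_ecsBA", "mct_ee_vmax", "km_mct")
  tr("mct_ea", "ecsBA", "Lac_ecsBA", "Lac_a", "mct_ea_vmax", "km_mct")
  tr("mct_an", "astro_cyt", "Lac_a", "Lac_ecsAN", "mct_an_vmax", "km_mct")
  tr("mct_n", "ecsAN", "Lac_ecsAN", "Lac_n", "mct_n_vmax", "km_mct")
  tr("bhbt_be", "endothelium", "bHB_b", "bHB_t_t", "bhbt_be_vmax", "km_bhbt",
     boundary_from = TRUE)
  tr("bhbt_ee", "endothelium", "bHB_t_t", "bHB_ecsBA", "bhbt_ee_vmax", "km_bhbt")
  tr("bhbt_ea", "ecsBA", "bHB_ecsBA", "bHB_a", "bhbt_ea_vmax", "km_bhbt")
  tr("bhbt_an", "astro_cyt", "bHB_a", "bHB_ecsAN", "bhbt_an_vmax", "km_bhbt")
  tr("bhbt_n", "ecsAN", "bHB_ecsAN", "bHB_n", "bhbt_n_vmax", "km_bhbt")

  ## ---- blood boundary relaxation (driven by clamped or fluctuating trace) ----
  for (sp in c("Glc", "Lac", "bHB")) {
    local({
      st_name <- paste0(sp, "_b")
      drv_name <- c(Glc = "glc", Lac = "lac", bHB = "bhb")[[sp]]
      add(paste0(tolower(drv_name), "_b_relax"), "blood",
          stats::setNames(1, st_name),
          function(s, p, drv) p[["blood_relax_k"]] * (drv[[drv_name]] - s[[st_name]]))
    })
  }

  ## ---- per-cell metabolism ----
  for (cell in c("n", "a")) local({
    cell <- cell  # freeze the loop variable in this closure environment
    sf <- paste0("_", cell)
    cy <- if (cell == "n") "neuron_cyt" else "astro_cyt"
    mt <- if (cell == "n") "neuron_mito" else "astro_mito"
    im <- if (cell == "n") "neuron_ims" else "astro_ims"
    S <- function(...) paste0(c(...), sf)  # suffixed species names
    nm <- function(base) paste0(base, sf)  # suffixed process name
    vx <- function(base) paste0(base, "_", cell)  # per-cell parameter

    add(nm("hk"), cy,
        stats::setNames(c(-1, -1, 1, 1), S("Glc", "ATP", "ADP", "HKPF")),
        function(s, p, drv)
          p[[vx("hk_vmax")]] * mm(s[[S("Glc")]], p[["km_hk_glc"]]) *
            mm(s[[S("ATP")]], p[["km_hk_atp"]]) *
            p[["ki_hk_hkpf"]] / (p[["ki_hk_hkpf"]] + s[[S("HKPF")]]))

    add(nm("pfk"), cy,
        stats::setNames(c(-1, -1, 1, 1), S("HKPF", "ATP", "ADP", "FBP")),
        function(s, p, drv) {
          h <- p[["hill_pfk"]]
          p[[vx("pfk_vmax")]] * mm(s[[S("HKPF")]], p[["km_pfk_hkpf"]]) *
            mm(s[[S("ATP")]], p[["km_pfk_atp"]]) *
            1 / (1 + (s[[S("ATP")]] / p[["ki_pfk_atp"]])^h) *
            hill(s[[S("ADP")]], p[["ka_pfk_adp"]], h)
        })

    add(nm("ald"), cy,
        stats::setNames(c(-1, 1, 1), S("FBP", "GAP", "DHAP")),
        function(s, p, drv) p[[vx("ald_vmax")]] * mm(s[[S("FBP")]], p[["km_ald"]]))

    add(nm("tpi"), cy,
        stats::setNames(c(-1, 1), S("DHAP", "GAP")),
        function(s, p, drv)
          p[["tpi_k"]] * (s[[S("DHAP")]] - s[[S("GAP")]] / p[["keq_tpi"]]))

    add(nm("lgly"), cy,
        stats::setNames(c(-1, -1, 1, -2, 2, 1),
                        S("GAP", "NAD", "NADH", "ADP", "ATP", "PYR")),
        function(s, p, drv)
          p[[vx("lgly_vmax")]] * mm(s[[S("GAP")]], p[["km_lgly_gap"]]) *
            mm(s[[S("NAD")]], p[["km_lgly_nad"]]) *
            mm(s[[S("ADP")]], p[["km_lgly_adp"]]))

    add(nm("ldh"), cy,
        stats::setNames(c(-1, -1, 1, 1), S("PYR", "NADH", "Lac", "NAD")),
        function(s, p, drv)
          p[["ldh_k"]] * (s[[S("PYR")]] * s[[S("NADH")]] -
                            s[[S("Lac")]] * s[[S("NAD")]] / p[["keq_ldh"]]))

    add(nm("mpc"), cy,
        stats::setNames(c(-1, 1), S("PYR", "PYRmito")),
        function(s, p, drv)
          carrier_flux(s[[S("PYR")]], s[[S("PYRmito")]],
                       p[[vx("mpc_vmax")]], p[["km_mpc"]]))

    add(nm("pdh"), mt,
        stats::setNames(c(-1, -1, -1, 1, 1),
                        S("PYRmito", "CoAmito", "NADmito", "AcCoAmito", "NADHmito")),
        function(s, p, drv)
          p[[vx("pdh_vmax")]] * mm(s[[S("PYRmito")]], p[["km_pdh_pyr"]]) *
            mm(s[[S("CoAmito")]], p[["km_pdh_coa"]]) *
            mm(s[[S("NADmito")]], p[["km_pdh_nad"]]))

    add(nm("pc"), mt,
        stats::setNames(c(-1, 1), S("PYRmito", "OXAmito")),
        function(s, p, drv)
          p[[vx("pc_vmax")]] * mm(s[[S("PYRmito")]], p[["km_pc"]]))

    add(nm("cs"), mt,
        stats::setNames(c(-1, -1, 1, 1),
                        S("AcCoAmito", "OXAmito", "CITmito", "CoAmito")),
        function(s, p, drv)
          p[["cs_vmax"]] * mm(s[[S("AcCoAmito")]], p[["km_cs_accoa"]]) *
            mm(s[[S("OXAmito")]], p[["km_cs_oxa"]]))

    add(nm("acn"), mt,
        stats::setNames(c(-1, 1), S("CITmito", "ISOCITmito")),
        function(s, p, drv)
          p[["acn_vmax"]] * mm(s[[S("CITmito")]], p[["km_acn"]]))

    add(nm("idh"), mt,
        stats::setNames(c(-1, 1, -1, 1),
                        S("ISOCITmito", "AKGmito", "NADmito", "NADHmito")),
        function(s, p, drv)
          p[["idh_vmax"]] * mm(s[[S("ISOCITmito")]], p[["km_idh_isocit"]]) *
            mm(s[[S("NADmito")]], p[["km_idh_nad"]]))

    add(nm("kgdh"), mt,
        stats::setNames(c(-1, -1, 1, -1, 1),
                        S("AKGmito", "CoAmito", "SUCCOAmito", "NADmito", "NADHmito")),
        function(s, p, drv)
          p[["kgdh_vmax"]] * mm(s[[S("AKGmito")]], p[["km_kgdh_akg"]]) *
            mm(s[[S("CoAmito")]], p[["km_kgdh_coa"]]) *
            mm(s[[S("NADmito")]], p[["km_kgdh_nad"]]))

    add(nm("scs"), mt,
        stats::setNames(c(-1, 1, 1, -1, 1),
                        S("SUCCOAmito", "SUCmito", "CoAmito", "ADPmito", "ATPmito")),
        function(s, p, drv)
          p[["scs_vmax"]] * mm(s[[S("SUCCOAmito")]], p[["km_scs_succoa"]]) *
            mm(s[[S("ADPmito")]], p[["km_scs_adp"]]))

    add(nm("sdh"), mt,
        stats::setNames(c(-1, 1), S("SUCmito", "FUMmito")),
        function(s, p, drv)
          p[["sdh_vmax"]] * mm(s[[S("SUCmito")]], p[["km_sdh"]]))

    add(nm("fum"), mt,
        stats::setNames(c(-1, 1), S("FUMmito", "MALmito")),
        function(s, p, drv)
          p[["fum_vmax"]] * mm(s[[S("FUMmito")]], p[["km_fum"]]))

    add(nm("mdh"), mt,
        stats::setNames(c(-1, -1, 1, 1),
                        S("MALmito", "NADmito", "OXAmito", "NADHmito")),
        function(s, p, drv)
          p[["mdh_k"]] * (s[[S("MALmito")]] * s[[S("NADmito")]] -
                            s[[S("OXAmito")]] * s[[S("NADHmito")]] / p[["keq_mdh"]]))

    # cataplerotic drains balancing anaplerotic (PC) input; the AKG outlet
    # stands for glutamate/glutamine synthesis from alpha-ketoglutarate
    add(nm("mal_drain"), mt,
        stats::setNames(-1, S("MALmito")),
        function(s, p, drv) p[["mal_drain_k"]] * s[[S("MALmito")]])

    add(nm("akg_drain"), mt,
        stats::setNames(-1, S("AKGmito")),
        function(s, p, drv) p[["akg_drain_k"]] * s[[S("AKGmito")]])

    etc_rate <- function(s, p)
      p[[vx("etc_vmax")]] * mm(s[[S("NADHmito")]], p[[vx("km_etc_nadh")]]) *
        mm(s[[S("O2mito")]], p[["km_etc_o2"]])

    add(nm("etc"), mt,
        stats::setNames(c(-1, 1, -0.5), S("NADHmito", "NADmito", "O2mito")),
        function(s, p, drv) etc_rate(s, p))

    add(nm("atpsyn"), mt,
        stats::setNames(c(-1, 1), S("ADPmito", "ATPmito")),
        function(s, p, drv)
          p[["p_o_ratio"]] * etc_rate(s, p) * s[[S("Qpool")]] *
            mm(s[[S("ADPmito")]], p[["km_syn_adp"]]))

    # adenine nucleotide translocase: ATP(mito) out to IMS, ADP(cyt) in
    add(nm("ant"), mt,
        stats::setNames(c(-1, 1, 1, -1),
                        S("ATPmito", "ADPmito", "ATPims", "ADP")),
        function(s, p, drv) {
          r <- p[[vx("ant_k")]] *
            (mm(s[[S("ATPmito")]], p[["km_ant"]]) -
               mm(s[[S("ATPims")]], p[["km_ant"]])) *
            mm(s[[S("ADP")]], p[["km_ant_adp"]])
          # reverse exchange needs matrix ADP as substrate
          if (r < 0) r <- r * mm(s[[S("ADPmito")]], p[["km_ant_adp"]])
          r
        })

    add(nm("ims_exp"), im,
        stats::setNames(c(-1, 1), S("ATPims", "ATP")),
        function(s, p, drv)
          p[[vx("ims_exp_k")]] * (mm(s[[S("ATPims")]], p[["km_ims"]]) -
                                    mm(s[[S("ATP")]], p[["km_ims"]])))

    add(nm("o2sup"), mt,
        stats::setNames(1, S("O2mito")),
        function(s, p, drv)
          p[["o2_supply_k"]] * (p[["o2_blood"]] - s[[S("O2mito")]]))

    add(nm("ppp"), cy,
        stats::setNames(c(-1, -2, 2), S("HKPF", "NADP", "NADPH")),
        function(s, p, drv)
          p[[vx("ppp_vmax")]] * mm(s[[S("HKPF")]], p[["km_ppp_hkpf"]]) *
            mm(s[[S("NADP")]], p[["km_ppp_nadp"]]))

    add(nm("gr"), cy,
        stats::setNames(c(-1, -1, 1, 2), S("GSSG", "NADPH", "NADP", "GSH")),
        function(s, p, drv)
          p[["gr_vmax"]] * mm(s[[S("GSSG")]], p[["km_gr_gssg"]]) *
            mm(s[[S("NADPH")]], p[["km_gr_nadph"]]))

    # ROS scavenging drain proportional to respiratory (ETC) activity
    add(nm("ros"), cy,
        stats::setNames(c(-2, 1), S("GSH", "GSSG")),
        function(s, p, drv)
          p[["ros_k"]] * etc_rate(s, p) *
            p[[paste0("vol_", cell, "_mit")]] / p[[paste0("vol_", cell, "_cyt")]] *
            mm(s[[S("GSH")]], p[["km_ros_gsh"]]))

    # ketone body utilization: bHB -> 2 AcCoA, one mitochondrial NADH
    add(nm("bhb_ut"), cy,
        stats::setNames(c(-1, 2, -2, -1, 1),
                        S("bHB", "AcCoAmito", "CoAmito", "NADmito", "NADHmito")),
        function(s, p, drv)
          p[[vx("bhb_ut_vmax")]] * mm(s[[S("bHB")]], p[["km_bhb_ut"]]) *
            mm(s[[S("NADmito")]], p[["km_bhb_nad"]]) *
            mm(s[[S("CoAmito")]], p[["km_pdh_coa"]]))

    # malate-aspartate shuttle: transfers cytosolic NADH to the matrix
    add(nm("mas"), cy,
        stats::setNames(c(-1, 1, -1, 1),
                        S("NADH", "NAD", "NADmito", "NADHmito")),
        function(s, p, drv)
          p[[vx("mas_k")]] * (s[[S("NADH")]] * s[[S("NADmito")]] -
                            s[[S("NAD")]] * s[[S("NADHmito")]] / p[["keq_mas"]]))

    add(nm("hk_atpase"), cy,
        stats::setNames(c(-1, 1), S("ATP", "ADP")),
        function(s, p, drv)
          p[[vx("hk_atpase")]] * mm(s[[S("ATP")]], p[["km_hk_atpase"]]))
  })

  ## ---- astrocyte glycogen ----
  add("glysyn_a", "astro_cyt",
      c(HKPF_a = -1, ATP_a = -1, ADP_a = 1, GLY_a = 1),
      function(s, p, drv)
        p[["glysyn_vmax"]] * mm(s[["HKPF_a"]], p[["km_glysyn_hkpf"]]) *
          mm(s[["ATP_a"]], p[["km_hk_atpase"]]) *
          max(0, 1 - s[["GLY_a"]] / p[["gly_cap"]]))

  add("glyphos_a", "astro_cyt",
      c(GLY_a = -1, HKPF_a = 1),
      function(s, p, drv)
        p[["glyphos_vmax"]] * mm(s[["GLY_a"]], p[["km_glyphos"]]) *
          p[["ki_glyphos_glc"]] / (p[["ki_glyphos_glc"]] + s[["Glc_a"]]))

  ## ---- neuronal Na+/K+-ATPase (metabolic debit; ion fluxes in membrane) ----
  add("nka", "neuron_cyt",
      c(ATP_n = -1, ADP_n = 1),
      function(s, p, drv)
        nka_rate(s[["ATP_n"]], s[["Glc_n"]], s[["Na_in"]], s[["K_out"]], p))

  procs
}

# cache (structure is parameter-independent)
.ngv_env <- new.env(parent = emptyenv())

ngv_processes <- function() {
  if (is.null(.ngv_env$procs)) .ngv_env$procs <- ngv_process_list()
  .ngv_env$procs
}

#' Registered process names
#' @return Character vector of all process identifiers.
#' @export
list_processes <- function() names(ngv_processes())

#' Instantaneous rate of a registered process
#'
#' @param process_id Process name (see [list_processes()]).
#' @param state State vector.
#' @param params Parameter vector.
#' @param drivers Optional list of blood targets `glc`, `lac`, `bhb` (mM);
#'   defaults to the parameter set points.
#' @return Rate (mM/s) in the process's reference compartment.
#' @export
reaction_rate <- function(process_id, state, params, drivers = NULL) {
  procs <- ngv_processes()
  if (!process_id %in% names(procs))
    stop("unknown process: ", process_id)
  if (any(!is.finite(state))) stop("invalid state: non-finite value")
  if (is.null(drivers))
    drivers <- list(glc = params[["glc_b_set"]], lac = params[["lac_b_set"]],
                    bhb = params[["bhb_b_set"]])
  s <- as.list(state)
  procs[[process_id]]$rate(s, params, drivers)
}

#' All process rates at a state
#'
#' @inheritParams reaction_rate
#' @return Named numeric vector of rates (mM/s) for every registered process.
#' @export
all_rates <- function(state, params, drivers = NULL) {
  procs <- ngv_processes()
  if (is.null(drivers))
    drivers <- list(glc = params[["glc_b_set"]], lac = params[["lac_b_set"]],
                    bhb = params[["bhb_b_set"]])
  s <- as.list(state)
  vapply(procs, function(pr) pr$rate(s, params, drivers), numeric(1))
}

#' Assemble the metabolic right-hand side
#'
#' Stoichiometry-weighted sum of all registered process rates with exact
#' volume-ratio corrections at every membrane. Membrane-block states (V,
#' gating, Na_in, K_out) get zero derivatives here; [membrane_rhs()]
#' contributes those. Conserved-moiety derivatives cancel analytically.
#'
#' @param t Time (s).
#' @param state State vector.
#' @param params Parameter vector.
#' @param drivers Optional blood-target list (`glc`, `lac`, `bhb`).
#' @return Named numeric derivative vector (same layout as the state).
#' @export
assemble_metabolic_rhs <- function(t, state, params, drivers = NULL) {
  procs <- ngv_processes()
  rates <- all_rates(state, params, drivers)
  if (any(!is.finite(rates)))
    stop("numerical failure in process: ",
         paste(names(rates)[!is.finite(rates)], collapse = ", "))
  vols <- ngv_volumes()
  comp <- ngv_state_compartments()
  ds <- stats::setNames(numeric(length(state)), names(state))
  for (pr in procs) {
    r <- rates[[pr$name]]
    v_ref <- vols[[pr$ref]]
    sp <- names(pr$stoich)
    ds[sp] <- ds[sp] + pr$stoich * r * v_ref / vols[comp[sp]]
  }
  ds
}

#' Full model right-hand side (reference R implementation)
#'
#' Metabolic assembly plus the membrane block. Used for validation and small
#' problems; the simulator uses the compiled equivalent.
#'
#' @param t Time (s).
#' @param state State vector.
#' @param params Parameter vector.
#' @param protocol Protocol list (stimulus definition); `NULL` means no
#'   stimulus.
#' @param drivers Optional blood-target list.
#' @return Named derivative vector.
#' @export
ngv_rhs <- function(t, state, params, protocol = NULL, drivers = NULL) {
  ds <- assemble_metabolic_rhs(t, state, params, drivers)
  stim <- if (is.null(protocol)) 0 else stimulus_current(t, protocol)
  mem <- membrane_rhs(t, state[["V"]],
                      c(state[["gate_m"]], state[["gate_h"]], state[["gate_n"]]),
                      state[["Na_in"]], state[["K_out"]],
                      state[["ATP_n"]], state[["Glc_n"]], stim, params)
  ds[c("V", "gate_m", "gate_h", "gate_n", "Na_in", "K_out")] <-
    ds[c("V", "gate_m", "gate_h", "gate_n", "Na_in", "K_out")] +
    mem$derivatives
  ds
}
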