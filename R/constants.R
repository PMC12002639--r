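# Compartment layout, state-vector naming, and functional-group labels.
#
# Naming follows the field's conventions for NGV models: five glucose
# "stations" along the blood -> endothelium -> basal lamina ECS -> astrocyte
# -> interstitial ECS -> neuron transport chain, with _n / _a suffixes for
# neuron and astrocyte species and *mito for matrix species.

#' Compartment identifiers of the NGV unit
#'
#' @return Character vector of compartment names.
#' @export
ngv_compartments <- function() {
  c("blood", "endothelium", "ecsBA", "ecsAN",
    "neuron_cyt", "neuron_mito", "neuron_ims",
    "astro_cyt", "astro_mito", "astro_ims")
}

#' Effective compartment volume fractions
#'
#' Volume fractions of the NGV unit (dimensionless, summing to 1 over blood,
#' endothelium, the two extracellular spaces and the two cells). The
#' mitochondrial fraction is 0.10 of each cell and the intermembrane space
#' 0.02; the remainder is cytosol. These are order-of-magnitude literature
#' values for neuropil composition, exposed here so transport fluxes can be
#' volume-corrected exactly.
#'
#' @return Named numeric vector of volume fractions, one per compartment.
#' @export
ngv_volumes <- function() {
  v_n <- 0.45
  v_a <- 0.25
  c(blood       = 0.10,
    endothelium = 0.04,
    ecsBA       = 0.08,
    ecsAN       = 0.08,
    neuron_cyt  = v_n * 0.88,
    neuron_mito = v_n * 0.10,
    neuron_ims  = v_n * 0.02,
    astro_cyt   = v_a * 0.88,
    astro_mito  = v_a * 0.10,
    astro_ims   = v_a * 0.02)
}

# cytosolic species per cell (suffix added later)
.CYT_SPECIES <- c("Glc", "HKPF", "FBP", "GAP", "DHAP", "PYR", "Lac",
                  "NAD", "NADH", "NADP", "NADPH", "ATP", "ADP",
                  "GSH", "GSSG", "bHB")

# mitochondrial species per cell
.MITO_SPECIES <- c("PYRmito", "AcCoAmito", "CoAmito", "CITmito", "ISOCITmito",
                   "AKGmito", "SUCCOAmito", "SUCmito", "FUMmito", "MALmito",
                   "OXAmito", "NADmito", "NADHmito", "ATPmito", "ADPmito",
                   "O2mito", "Qpool")

#' State-variable names of the reduced NGV model
#'
#' Extracellular glucose, lactate and beta-hydroxybutyrate occupy four
#' compartments (blood, endothelium `_t_t`, `_ecsBA`, `_ecsAN`); each cell
#' carries a cytosolic block, a mitochondrial block and an IMS ATP pool;
#' the astrocyte additionally carries glycogen (`GLY_a`, glucosyl units) and
#' the neuron a membrane block (V, gating m/h/n, intracellular Na+,
#' perineuronal K+).
#'
#' @return Character vector of state names (length 87).
#' @export
ngv_state_names <- function() {
  extracell <- as.vector(outer(c("Glc", "Lac", "bHB"),
                               c("_b", "_t_t", "_ecsBA", "_ecsAN"),
                               paste0))
  cyt_n <- paste0(.CYT_SPECIES, "_n")
  cyt_a <- paste0(.CYT_SPECIES, "_a")
  mit_n <- paste0(.MITO_SPECIES, "_n")
  mit_a <- paste0(.MITO_SPECIES, "_a")
  c(extracell, cyt_n, cyt_a, mit_n, mit_a,
    "ATPims_n", "ATPims_a", "GLY_a",
    "V", "gate_m", "gate_h", "gate_n", "Na_in", "K_out")
}

#' Compartment of each state variable
#'
#' @return Named character vector mapping every state name to its compartment.
#' @export
ngv_state_compartments <- function() {
  nm <- ngv_state_names()
  comp <- character(length(nm))
  names(comp) <- nm
  comp[grepl("_b$", nm)] <- "blood"
  comp[grepl("_t_t$", nm)] <- "endothelium"
  comp[grepl("_ecsBA$", nm)] <- "ecsBA"
  comp[grepl("_ecsAN$", nm)] <- "ecsAN"
  cyt_n <- paste0(.CYT_SPECIES, "_n")
  cyt_a <- paste0(.CYT_SPECIES, "_a")
  comp[cyt_n] <- "neuron_cyt"
  comp[cyt_a] <- "astro_cyt"
  comp[paste0(.MITO_SPECIES, "_n")] <- "neuron_mito"
  comp[paste0(.MITO_SPECIES, "_a")] <- "astro_mito"
  comp["ATPims_n"] <- "neuron_ims"
  comp["ATPims_a"] <- "astro_ims"
  comp["GLY_a"] <- "astro_cyt"
  # membrane block lives on the neuron; K_out in the perineuronal ECS
  comp[c("V", "gate_m", "gate_h", "gate_n", "Na_in")] <- "neuron_cyt"
  comp["K_out"] <- "ecsAN"
  comp
}

#' The five glucose stations of the transport chain
#'
#' Maps the conventional station labels (endothelial `Glc_t_t`, basal-lamina
#' `Glc_ecsBA`, astrocytic `Glc_a`, interstitial `Glc_ecsAN`, neuronal
#' `Glc_n`) to state-vector names.
#'
#' @return Named character vector (station label -> state name).
#' @export
glucose_stations <- function() {
  c(Glc_t_t   = "Glc_t_t",
    Glc_ecsBA = "Glc_ecsBA",
    Glc_a     = "Glc_a",
    Glc_ecsAN = "Glc_ecsAN",
    Glc_n     = "Glc_n")
}

#' Default metabolite-to-functional-group mapping
#'
#' Functional subgroups used in the variability analysis: ketone-body fuel
#' (keto), redox carriers (redox), respiration upstream of the electron
#' transport chain (resp), the ETC itself (ETC), adenosine phosphates
#' (ATDMP), glycolysis (GLCLS), TCA cycle (TCA), glutamate-glutamine cycle
#' (GLTGLN, present only as a label in this reduced network) and the pentose
#' phosphate shunt with its glutathione consumers (PPP).
#'
#' @return Named character vector mapping base metabolite names (no cell
#'   suffix) to group labels.
#' @export
metabolite_groups <- function() {
  c(Glc = "GLCLS", HKPF = "GLCLS", FBP = "GLCLS", GAP = "GLCLS",
    DHAP = "GLCLS", PYR = "GLCLS", Lac = "GLCLS", GLY = "GLCLS",
    PYRmito = "TCA", AcCoAmito = "resp", CoAmito = "resp",
    CITmito = "TCA", ISOCITmito = "TCA", AKGmito = "TCA",
    SUCCOAmito = "TCA", SUCmito = "TCA", FUMmito = "TCA",
    MALmito = "TCA", OXAmito = "TCA",
    NAD = "redox", NADH = "redox", NADP = "redox", NADPH = "redox",
    NADmito = "ETC", NADHmito = "ETC", O2mito = "ETC",
    ATP = "ATDMP", ADP = "ATDMP", ATPmito = "ATDMP", ADPmito = "ATDMP",
    ATPims = "ATDMP",
    GSH = "PPP", GSSG = "PPP",
    bHB = "keto")
}
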