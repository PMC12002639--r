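# Disease induction (GLUT1 deficiency as transporter-parameter scaling) and
# therapy protocols (blood supplements, intracellular injections, ubiquinone
# boost, ATP dose ladders).

#' GLUT1 deficiency coefficients
#'
#' Multiplicative coefficients for the four GLUT1 membrane partitions
#' (blood to endothelium, endothelium to basal-lamina ECS, basal-lamina ECS
#' to astrocyte, astrocyte to interstitium). GLUT3 on the neuron is left
#' untouched. The default deficiency factor 0.4 is a calibration choice: it
#' reduces glucose at every station while keeping a viable resting state and
#' crossing the after-discharge threshold.
#'
#' @param factor Deficiency factor in [0, 1]; 1 reproduces control.
#' @return Named numeric vector of parameter coefficients.
#' @export
glut1_coefficients <- function(factor = 0.4) {
  if (factor < 0) stop("deficiency factor must be >= 0")
  c(glut1_be_vmax = factor, glut1_ee_vmax = factor,
    glut1_ea_vmax = factor, glut1_an_vmax = factor)
}

#' Apply multiplicative deficiency coefficients to a parameter set
#'
#' @param params Parameter vector.
#' @param coeffs Named numeric vector: parameter name -> multiplicative
#'   coefficient (>= 0). Coefficient 1 for every parameter reproduces the
#'   input exactly.
#' @return A new parameter vector; the input is untouched.
#' @export
apply_glut1_deficiency <- function(params, coeffs) {
  unknown <- setdiff(names(coeffs), names(params))
  if (length(unknown))
    stop("unknown parameter: ", paste(unknown, collapse = ", "))
  if (any(coeffs < 0)) stop("negative deficiency coefficient")
  out <- params
  out[names(coeffs)] <- out[names(coeffs)] * coeffs
  out
}

#' Construct a therapy specification
#'
#' @param name Therapy label.
#' @param blood Named additions to arterial set points (mM), names from
#'   `GLC`, `LAC`, `bHB`.
#' @param inject Named additions to initial intracellular concentrations
#'   (mM), names from `NAD`, `ATP`, `OXA`, `SUCCOA`, `AKG`, `FUM`. `ATP`
#'   raises cytosolic and IMS ATP and therefore the adenine pool; `NAD`
#'   raises NAD+ and the NAD pool.
#' @param q_boost Addition to the Qpool efficiency factor (dimensionless).
#' @return A `therapy_spec` list.
#' @export
therapy_spec <- function(name, blood = c(), inject = c(), q_boost = 0) {
  blood_ok <- c("GLC", "LAC", "bHB")
  inj_ok <- c("NAD", "ATP", "OXA", "SUCCOA", "AKG", "FUM")
  if (length(blood) && !all(names(blood) %in% blood_ok))
    stop("unknown blood supplement: ",
         paste(setdiff(names(blood), blood_ok), collapse = ", "))
  if (length(inject) && !all(names(inject) %in% inj_ok))
    stop("unknown injection species: ",
         paste(setdiff(names(inject), inj_ok), collapse = ", "))
  if (any(c(blood, inject, q_boost) < 0))
    stop("therapy additions must be non-negative")
  structure(list(name = name, blood = blood, inject = inject,
                 q_boost = q_boost),
            class = "therapy_spec")
}

#' Standard therapy list
#'
#' The panel of candidate therapies ranked by the redox-restoration
#' analysis: single blood supplements (GLC, LAC, bHB), cofactor injections
#' (NAD), ubiquinone boost (Q), high-dose ATP, the combination therapies
#' GLC-LAC-bHB, bHB-LAC-NAD-Q and LAC-bHB, and four single anaplerotic TCA
#' injections (OXA, SUCCOA, AKG, FUM). Default magnitudes are calibrated so
#' single blood supplements produce an intracellular rise of roughly half
#' the control level of the targeted species.
#'
#' @param glc_dose,lac_dose,bhb_dose Arterial supplement magnitudes (mM).
#' @param nad_dose,atp_dose,ana_dose Injection magnitudes (mM).
#' @param q_boost Qpool efficiency addition.
#' @return Named list of `therapy_spec` objects.
#' @export
make_standard_therapies <- function(glc_dose = 1.5, lac_dose = 0.08,
                                    bhb_dose = 0.08, nad_dose = 0.02,
                                    atp_dose = 1.0, ana_dose = 0.5,
                                    q_boost = 0.1) {
  sp <- list(
    "GLC" = therapy_spec("GLC", blood = c(GLC = glc_dose)),
    "LAC" = therapy_spec("LAC", blood = c(LAC = lac_dose)),
    "bHB" = therapy_spec("bHB", blood = c(bHB = bhb_dose)),
    "NAD" = therapy_spec("NAD", inject = c(NAD = nad_dose)),
    "Q" = therapy_spec("Q", q_boost = q_boost),
    "ATP" = therapy_spec("ATP", inject = c(ATP = atp_dose)),
    "GLC-LAC-bHB" = therapy_spec("GLC-LAC-bHB",
      blood = c(GLC = glc_dose, LAC = lac_dose, bHB = bhb_dose)),
    "bHB-LAC-NAD-Q" = therapy_spec("bHB-LAC-NAD-Q",
      blood = c(LAC = lac_dose, bHB = bhb_dose),
      inject = c(NAD = nad_dose), q_boost = q_boost),
    "LAC-bHB" = therapy_spec("LAC-bHB",
      blood = c(LAC = lac_dose, bHB = bhb_dose)),
    "OXA" = therapy_spec("OXA", inject = c(OXA = ana_dose)),
    "SUCCOA" = therapy_spec("SUCCOA", inject = c(SUCCOA = ana_dose)),
    "AKG" = therapy_spec("AKG", inject = c(AKG = ana_dose)),
    "FUM" = therapy_spec("FUM", inject = c(FUM = ana_dose)))
  sp
}

#' Apply a therapy to a state and parameter set
#'
#' Blood supplements raise arterial set points (a parameter change, in
#' force during pre-run relaxation); injections raise initial concentrations
#' (and, through the state, the corresponding conserved pools); `q_boost`
#' raises the Qpool efficiency factor of both cells, capped at 1.
#'
#' @param state0 Initial state vector.
#' @param params Parameter vector.
#' @param spec A `therapy_spec`.
#' @return List with modified `state` and `params` (inputs untouched).
#' @export
apply_therapy <- function(state0, params, spec) {
  s <- state0; p <- params
  bl <- spec$blood
  if (length(bl)) {
    map <- c(GLC = "glc_b_set", LAC = "lac_b_set", bHB = "bhb_b_set")
    p[map[names(bl)]] <- p[map[names(bl)]] + bl
  }
  inj <- spec$inject
  for (sp_name in names(inj)) {
    d <- inj[[sp_name]]
    targets <- switch(sp_name,
      NAD = c("NAD_n", "NAD_a"),
      ATP = c("ATP_n", "ATP_a", "ATPims_n", "ATPims_a"),
      OXA = c("OXAmito_n", "OXAmito_a"),
      SUCCOA = c("SUCCOAmito_n", "SUCCOAmito_a"),
      AKG = c("AKGmito_n", "AKGmito_a"),
      FUM = c("FUMmito_n", "FUMmito_a"))
    s[targets] <- s[targets] + d
    if (sp_name == "NAD") p["nad_tot_cyt"] <- p[["nad_tot_cyt"]] + d
  }
  if (spec$q_boost > 0) {
    q <- c("Qpool_n", "Qpool_a")
    s[q] <- pmin(1.0, s[q] + spec$q_boost)
  }
  conc <- setdiff(names(s), "V")  # membrane voltage is legitimately negative
  if (any(s[conc] < 0)) stop("invalid therapy: negative state")
  list(state = s, params = p)
}

#' ATP dose ladder
#'
#' `n` equally spaced exogenous ATP doses from `d_max/n` to `d_max`, one
#' therapy specification per dose (each dose is a separate simulation).
#'
#' @param n Number of doses (default 5).
#' @param d_max Largest dose (mM).
#' @return List of `therapy_spec` objects named `ATP_dose<i>`.
#' @export
atp_dose_ladder <- function(n = 5, d_max = 1.0) {
  if (n < 1) stop("n must be >= 1")
  if (d_max <= 0) stop("d_max must be > 0")
  doses <- d_max * seq_len(n) / n
  out <- lapply(seq_len(n), function(i)
    therapy_spec(paste0("ATP_dose", i), inject = c(ATP = doses[i])))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
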