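# Rate laws: facilitated transport, enzyme kinetics, the Na+/K+-ATPase and
# the Hodgkin-Huxley membrane. Every registered process is an explicit named
# closure so each law can be checked against an independent hand evaluation.

# saturating terms clamp at zero so transient solver undershoots below zero
# cannot create singularities
mm <- function(x, km) { x <- pmax(x, 0); x / (x + km) }
hill <- function(x, km, n) { x <- pmax(x, 0); x^n / (x^n + km^n) }

#' Symmetric saturable carrier flux
#'
#' Facilitated-diffusion rate law used for every GLUT1 partition, GLUT3,
#' the monocarboxylate (lactate) transporters and ketone-body transport:
#' \deqn{v = V_{max}\left(\frac{s_a}{s_a + K_m} - \frac{s_b}{s_b + K_m}\right)}
#' The carrier is symmetric: equal concentrations give zero net flux and
#' reversing the sides flips the sign.
#'
#' @param s_a,s_b Substrate concentrations on the two faces (mM, >= 0).
#' @param vmax Carrier capacity (mM/s, > 0).
#' @param km Half-saturation constant (mM, > 0).
#' @return Net flux from side a to side b (mM/s, signed).
#' @export
carrier_flux <- function(s_a, s_b, vmax, km) {
  if (any(s_a < 0) || any(s_b < 0))
    stop("carrier_flux: negative substrate concentration")
  if (any(vmax <= 0) || any(km <= 0))
    stop("carrier_flux: vmax and km must be positive")
  vmax * (s_a / (s_a + km) - s_b / (s_b + km))
}

#' Na+/K+-ATPase rate
#'
#' ATP consumption rate of the neuronal sodium pump. The pump saturates in
#' ATP, intracellular Na+ (Hill coefficient 1.5) and perineuronal K+, and is
#' additionally gated by neuronal glucose, which couples glucose availability
#' to pump capacity. Fixed stoichiometry: 3 Na+ out, 2 K+ in per ATP.
#'
#' @param atp Cytosolic ATP (mM).
#' @param glc Cytosolic glucose (mM).
#' @param na_in Intracellular Na+ (mM).
#' @param k_out Perineuronal K+ (mM).
#' @param p Parameter vector (uses `pump_vmax`, `km_pump_*`, `hill_pump_na`).
#' @return ATP consumption rate (mM/s), monotone non-decreasing in every
#'   argument.
#' @export
nka_rate <- function(atp, glc, na_in, k_out, p) {
  if (any(c(atp, glc, na_in, k_out) < 0))
    stop("nka_rate: negative input")
  p[["pump_vmax"]] *
    hill(atp, p[["km_pump_atp"]], p[["hill_pump_atp"]]) *
    mm(glc, p[["km_pump_glc"]]) *
    hill(na_in, p[["km_pump_na"]], p[["hill_pump_na"]]) *
    mm(k_out, p[["km_pump_k"]])
}

# --- Hodgkin-Huxley gating kinetics (voltage in absolute mV) ---

hh_alpha <- function(gate, v) {
  switch(gate,
    m = {
      x <- v + 40
      ifelse(abs(x) < 1e-7, 1.0, 0.1 * x / (1 - exp(-x / 10)))
    },
    h = 0.07 * exp(-(v + 65) / 20),
    n = {
      x <- v + 55
      ifelse(abs(x) < 1e-7, 0.1, 0.01 * x / (1 - exp(-x / 10)))
    },
    stop("unknown gate"))
}

hh_beta <- function(gate, v) {
  switch(gate,
    m = 4 * exp(-(v + 65) / 18),
    h = 1 / (1 + exp(-(v + 35) / 10)),
    n = 0.125 * exp(-(v + 65) / 80),
    stop("unknown gate"))
}

#' Steady-state value of a Hodgkin-Huxley gate
#' @param gate One of "m", "h", "n".
#' @param v Membrane voltage (mV).
#' @return Gate open probability at steady state.
#' @export
hh_gate_inf <- function(gate, v) {
  a <- hh_alpha(gate, v); b <- hh_beta(gate, v)
  a / (a + b)
}

#' Stimulus current
#'
#' Rectangular depolarizing pulse: the configured amplitude within
#' `[stim_start, stim_end)` and zero outside.
#'
#' @param t Time (s).
#' @param protocol A protocol list with `stim_start`, `stim_end`,
#'   `stim_amplitude` (uA/cm^2).
#' @return Stimulus current (uA/cm^2).
#' @export
stimulus_current <- function(t, protocol) {
  if (protocol$stim_end <= protocol$stim_start)
    stop("invalid protocol: stim_end <= stim_start")
  ifelse(t >= protocol$stim_start & t < protocol$stim_end,
         protocol$stim_amplitude, 0)
}

#' Membrane right-hand side
#'
#' Hodgkin-Huxley voltage and gating dynamics with Nernst reversal
#' potentials recomputed from the tracked ion pools, activity-dependent ion
#' accumulation, and the Na+/K+-ATPase (3 Na+ out : 2 K+ in : 1 ATP). The
#' sodium leak conductance is sized so that resting channel fluxes match the
#' pump's 3:2 stoichiometry, which gives the membrane a genuine resting
#' fixed point. K+ accumulates in a small effective perineuronal space
#' (`ecs_k_ratio` cytosol:ECS) and is cleared toward the bath.
#'
#' @param t Time (s).
#' @param v Membrane voltage (mV).
#' @param gates Numeric vector `c(m, h, n)`.
#' @param na_in Intracellular Na+ (mM).
#' @param k_out Perineuronal K+ (mM).
#' @param atp,glc Neuronal cytosolic ATP and glucose (mM), which set pump
#'   capacity.
#' @param stim Stimulus current (uA/cm^2).
#' @param p Parameter vector.
#' @return List with `derivatives` (dV, dm, dh, dn, dNa_in, dK_out; per
#'   second) and `atp_rate`, the pump's ATP consumption (mM/s) to be debited
#'   from neuronal ATP.
#' @export
membrane_rhs <- function(t, v, gates, na_in, k_out, atp, glc, stim, p) {
  m <- gates[[1]]; h <- gates[[2]]; n <- gates[[3]]
  if (any(c(m, h, n) < -1e-9) || any(c(m, h, n) > 1 + 1e-9))
    stop("invalid state: gating variable outside [0,1]")
  rt_f <- 26.64  # RT/F at 37C, mV
  e_na <- rt_f * log(p[["na_out"]] / max(na_in, 1e-6))
  e_k <- rt_f * log(max(k_out, 1e-6) / p[["k_in"]])
  i_na <- (p[["gna"]] * m^3 * h + p[["gna_leak"]]) * (v - e_na)
  i_k <- p[["gk"]] * n^4 * (v - e_k)
  i_l <- p[["gl"]] * (v - p[["el"]])  # untracked (Cl-dominated) leak
  j_pump <- nka_rate(atp, glc, na_in, k_out, p)
  i_pump <- j_pump / p[["ion_conv"]]  # net 1 charge out per ATP
  # gating rates are the classic per-ms forms; convert to per-second
  phi <- 1000
  dv <- 1000 * (-(i_na + i_k + i_l + i_pump) + stim) / p[["cm"]]
  dm <- phi * (hh_alpha("m", v) * (1 - m) - hh_beta("m", v) * m)
  dh <- phi * (hh_alpha("h", v) * (1 - h) - hh_beta("h", v) * h)
  dn <- phi * (hh_alpha("n", v) * (1 - n) - hh_beta("n", v) * n)
  dna <- -p[["ion_conv"]] * i_na - 3 * j_pump
  # astrocytic K+ clearance: engages only above a threshold over bath
  # (dead zone lets the pump govern baseline K+), and saturates, so
  # sustained firing can outrun it and accumulate perineuronal K+
  kx <- k_out - p[["k_bath"]]
  th <- p[["k_clear_thresh"]]
  clear <- if (kx >= th) {
    p[["k_clear"]] * (kx - th) / ((kx - th) + p[["km_clear"]])
  } else if (kx <= 0) {
    # weak re-supply from the bath below baseline
    p[["k_resupply"]] * kx / (abs(kx) + p[["km_clear"]])
  } else 0
  dk <- p[["ecs_k_ratio"]] * (p[["ion_conv"]] * i_k - 2 * j_pump) - clear
  list(derivatives = c(dV = dv, dm = dm, dh = dh, dn = dn,
                       dNa_in = dna, dK_out = dk),
       atp_rate = j_pump)
}
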