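# Pump rate law, membrane dynamics, stimulus definition.

test_that("pump rate follows the documented product form and gates on fuel", {
  p <- ctrl_params()
  expect_equal(nka_rate(0, 1, 10, 4, p), 0)
  expect_equal(nka_rate(2, 0, 10, 4, p), 0)
  hill <- function(x, km, n) x^n / (x^n + km^n)
  hand <- p[["pump_vmax"]] *
    hill(2, p[["km_pump_atp"]], p[["hill_pump_atp"]]) *
    2 / (2 + p[["km_pump_glc"]]) *
    hill(15, p[["km_pump_na"]], p[["hill_pump_na"]]) *
    4 / (4 + p[["km_pump_k"]])
  expect_equal(nka_rate(2, 2, 15, 4, p), hand, tolerance = 1e-12)
  # monotone non-decreasing in every argument
  base <- nka_rate(2, 2, 15, 4, p)
  expect_gte(nka_rate(3, 2, 15, 4, p), base)
  expect_gte(nka_rate(2, 3, 15, 4, p), base)
  expect_gte(nka_rate(2, 2, 20, 4, p), base)
  expect_gte(nka_rate(2, 2, 15, 6, p), base)
  expect_error(nka_rate(-1, 2, 15, 4, p), "negative")
})

test_that("pump ion stoichiometry is exactly 3 Na out : 2 K in : 1 ATP", {
  p <- ctrl_params()
  s <- state_vec(ctrl_rest())
  out <- membrane_rhs(0, s[["V"]], s[c("gate_m", "gate_h", "gate_n")],
                      s[["Na_in"]], s[["K_out"]], s[["ATP_n"]], s[["Glc_n"]],
                      0, p)
  d <- out$derivatives; jp <- out$atp_rate
  # subtract the channel/leak contributions to isolate the pump terms
  rt_f <- 26.64
  e_na <- rt_f * log(p[["na_out"]] / s[["Na_in"]])
  i_na <- (p[["gna"]] * s[["gate_m"]]^3 * s[["gate_h"]] + p[["gna_leak"]]) *
    (s[["V"]] - e_na)
  na_pump <- d[["dNa_in"]] + p[["ion_conv"]] * i_na
  expect_equal(na_pump / jp, -3, tolerance = 1e-6)
  e_k <- rt_f * log(s[["K_out"]] / p[["k_in"]])
  i_k <- p[["gk"]] * s[["gate_n"]]^4 * (s[["V"]] - e_k)
  kx <- s[["K_out"]] - p[["k_bath"]]
  clear <- if (kx >= p[["k_clear_thresh"]]) {
    p[["k_clear"]] * (kx - p[["k_clear_thresh"]]) /
      ((kx - p[["k_clear_thresh"]]) + p[["km_clear"]])
  } else if (kx <= 0) p[["k_resupply"]] * kx / (abs(kx) + p[["km_clear"]]) else 0
  k_pump <- d[["dK_out"]] - p[["ecs_k_ratio"]] * p[["ion_conv"]] * i_k + clear
  expect_equal(k_pump / (p[["ecs_k_ratio"]] * jp), -2, tolerance = 1e-6)
})

test_that("membrane is at rest at the shipped resting state", {
  p <- ctrl_params()
  s <- state_vec(ctrl_rest())
  out <- membrane_rhs(0, s[["V"]], s[c("gate_m", "gate_h", "gate_n")],
                      s[["Na_in"]], s[["K_out"]], s[["ATP_n"]], s[["Glc_n"]],
                      0, p)
  expect_lt(max(abs(out$derivatives[c("dV", "dm", "dh", "dn")])), 1e-3)
  expect_error(membrane_rhs(0, -65, c(1.2, 0.5, 0.3), 10, 4, 2, 1, 0, p),
               "gating")
})

test_that("Nernst reversals move with ion accumulation in the physical direction", {
  # E_K rises as perineuronal K+ rises: the K current driving force shrinks
  p <- ctrl_params()
  s <- state_vec(ctrl_rest())
  g <- s[c("gate_m", "gate_h", "gate_n")]
  d_lo <- membrane_rhs(0, s[["V"]], g, s[["Na_in"]], 4, s[["ATP_n"]],
                       s[["Glc_n"]], 0, p)$derivatives
  d_hi <- membrane_rhs(0, s[["V"]], g, s[["Na_in"]], 12, s[["ATP_n"]],
                       s[["Glc_n"]], 0, p)$derivatives
  expect_gt(d_hi[["dV"]], d_lo[["dV"]])  # higher K_out depolarizes
})

test_that("stimulus is a rectangular pulse on the configured window", {
  pr <- make_protocol(stim_start = 50, stim_dur = 0.03, stim_amplitude = 15)
  expect_equal(stimulus_current(49.99, pr), 0)
  expect_equal(stimulus_current(50.0, pr), 15)
  expect_equal(stimulus_current(50.0299, pr), 15)
  expect_equal(stimulus_current(50.03, pr), 0)
  expect_equal(pr$stim_end - pr$stim_start, 0.03)
  bad <- pr; bad$stim_end <- bad$stim_start
  expect_error(stimulus_current(1, bad), "invalid protocol")
})

test_that("a weakened pump lets perineuronal K+ rise during identical stimulation", {
  p <- ctrl_params()
  ctx_strong <- ngvmet:::ngv_ctx(p)
  p_weak <- p; p_weak["pump_vmax"] <- p[["pump_vmax"]] * 0.5
  ctx_weak <- ngvmet:::ngv_ctx(p_weak)
  y0 <- state_vec(ctrl_rest())
  run1 <- function(ctx) {
    f <- function(t, y, parms) list(ngvmet:::ngv_rhs_cpp(ctx, t, y, 20))
    o <- deSolve::lsoda(y0, seq(0, 1, by = 1e-3), f, NULL,
                        rtol = 1e-6, atol = 1e-9)
    max(o[, "K_out"])
  }
  expect_gt(run1(ctx_weak), run1(ctx_strong))
})
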