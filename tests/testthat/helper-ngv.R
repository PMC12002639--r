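# Shared fixtures: parameters, resting states and heavyweight simulation
# results are computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ctrl_params <- function() cached("params", make_default_parameters())
ctrl_rest <- function() cached("rest", default_initial_state())

disease_params <- function()
  cached("dparams", apply_glut1_deficiency(ctrl_params(),
                                           glut1_coefficients(0.4)))
disease_rest <- function()
  cached("drest", suppressWarnings(relax_to_rest(disease_params(), 400)))

# seizure-study runs (control, disease) shared by several tests
seizure_control <- function()
  cached("seiz_c", suppressWarnings(run_protocol(seizure_protocol("control"),
                                                 ctrl_params())))
seizure_disease <- function()
  cached("seiz_d", suppressWarnings(
    run_protocol(seizure_protocol("glut1_ds",
                                  deficiency = glut1_coefficients(0.4)),
                 ctrl_params())))

# baseline (no-stimulus) runs for redox/therapy readouts
redox_protocol <- function(label, therapy = NULL, deficiency = NULL)
  make_protocol(label, t_end = 120, stim_start = 100, stim_dur = 0.03,
                stim_amplitude = 0, deficiency = deficiency,
                therapy = therapy, output_dt = 0.2, spike_window = 1)
redox_control <- function()
  cached("redox_c", suppressWarnings(run_protocol(redox_protocol("control"),
                                                  ctrl_params())))
redox_disease <- function()
  cached("redox_d", suppressWarnings(
    run_protocol(redox_protocol("glut1_ds",
                                deficiency = glut1_coefficients(0.4)),
                 ctrl_params())))

state_vec <- function(s) stats::setNames(as.numeric(s), names(s))

# random strictly-positive perturbations of the resting state
random_states <- function(n, seed = 42) {
  set.seed(seed)
  s0 <- state_vec(ctrl_rest())
  lapply(seq_len(n), function(i) {
    s <- s0 * exp(stats::runif(length(s0), -0.3, 0.3))
    s["V"] <- -60; s[c("gate_m", "gate_h", "gate_n")] <-
      pmin(pmax(s0[c("gate_m", "gate_h", "gate_n")], 0.01), 0.99)
    s
  })
}
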