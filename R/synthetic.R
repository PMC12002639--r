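# Synthetic data: mean-reverting blood nutrient traces and analytic
# fixtures with embedded ground truth for testing the analysis layer.

#' Blood-trace specification
#'
#' Mean-reverting (Ornstein-Uhlenbeck) fluctuation parameters for arterial
#' glucose, lactate and beta-hydroxybutyrate. Defaults emulate slow
#' physiological variation of arterial nutrient levels around their set
#' points: relative fluctuations of ~5-10% with a 30 s reversion time.
#'
#' @param mean Named means (mM) for `GLC`, `LAC`, `bHB`.
#' @param sd Named stationary standard deviations (mM); each must be below
#'   `mean/3` so negative excursions are rare (they are clipped at 0 and
#'   counted).
#' @param tau Mean-reversion time constant (s); the default 120 s reflects
#'   the minutes-scale variation of arterial nutrient levels.
#' @param dt Trace time step (s).
#' @param duration Trace length (s).
#' @param seed Integer seed.
#' @return A `blood_trace_spec` list.
#' @export
blood_trace_spec <- function(mean = c(GLC = 5.0, LAC = 1.0, bHB = 0.3),
                             sd = c(GLC = 0.5, LAC = 0.12, bHB = 0.04),
                             tau = 120, dt = 0.5, duration = 600,
                             seed = 1L) {
  if (any(sd < 0) || tau <= 0 || dt <= 0 || duration <= 0)
    stop("invalid blood trace spec")
  if (any(sd >= mean / 3))
    stop("invalid blood trace spec: sd must be < mean/3")
  structure(list(mean = mean, sd = sd, tau = tau, dt = dt,
                 duration = duration, seed = as.integer(seed)),
            class = "blood_trace_spec")
}

#' Generate mean-reverting blood nutrient traces
#'
#' Exact discretization of the Ornstein-Uhlenbeck process,
#' \deqn{x_{t+dt} = \mu + (x_t - \mu) e^{-dt/\tau} +
#'   \sigma\sqrt{1 - e^{-2dt/\tau}}\, z,}
#' started at the mean, seeded and reproducible. Negative excursions are
#' clipped at zero and counted in the `clipped` attribute.
#'
#' @param spec A [blood_trace_spec()].
#' @return Data frame with columns `t`, `GLC`, `LAC`, `bHB`; attribute
#'   `clipped` gives the number of clipped samples per species.
#' @export
ou_blood_trace <- function(spec) {
  stopifnot(inherits(spec, "blood_trace_spec"))
  n <- floor(spec$duration / spec$dt) + 1
  t <- (seq_len(n) - 1) * spec$dt
  a <- exp(-spec$dt / spec$tau)
  b <- sqrt(1 - a^2)
  out <- data.frame(t = t)
  clipped <- c()
  set.seed(spec$seed)
  for (spn in c("GLC", "LAC", "bHB")) {
    mu <- spec$mean[[spn]]; sd <- spec$sd[[spn]]
    x <- numeric(n); x[1] <- mu
    z <- stats::rnorm(n - 1)
    for (i in seq_len(n - 1)) x[i + 1] <- mu + (x[i] - mu) * a + sd * b * z[i]
    clipped[spn] <- sum(x < 0)
    out[[spn]] <- pmax(x, 0)
  }
  attr(out, "clipped") <- clipped
  out
}

#' Synthetic voltage trace with known spike times
#'
#' Stitches template action potentials (2 ms wide, peak +30 mV, resting
#' level -65 mV) onto a flat trace at deterministic times: `n_spikes -
#' n_after` uniformly inside the stimulus window, `n_after` after its end.
#' Returns both the trace and the embedded ground truth.
#'
#' @param n_spikes Total spike count.
#' @param stim_window Numeric `c(start, end)` (s).
#' @param n_after Number of spikes placed after `stim_window[2]`.
#' @param dt Sample interval (s).
#' @param t_end Trace end (s); default extends 1 s past the window.
#' @return List with `trace` (data frame `t_s`, `V_mV`) and `spike_times`.
#' @export
fixture_voltage <- function(n_spikes, stim_window, n_after = 0, dt = 1e-4,
                            t_end = stim_window[2] + 1) {
  if (n_after > n_spikes) stop("n_after must be <= n_spikes")
  t <- seq(0, t_end, by = dt)
  v <- rep(-65, length(t))
  n_in <- n_spikes - n_after
  times_in <- if (n_in > 0)
    stim_window[1] + (seq_len(n_in)) *
      diff(stim_window) / (n_in + 1) else numeric()
  after_span <- t_end - stim_window[2]
  times_after <- if (n_after > 0)
    stim_window[2] + seq_len(n_after) * after_span / (n_after + 1)
    else numeric()
  spike_times <- c(times_in, times_after)
  if (length(spike_times) > 1 && min(diff(sort(spike_times))) < 2e-3)
    stop("overlapping action potential templates")
  width <- 2e-3
  for (ts in spike_times) {
    idx <- which(t >= ts & t < ts + width)
    ph <- (t[idx] - ts) / width            # 0..1 through the template
    v[idx] <- -65 + 95 * sin(pi * ph)^2    # peak +30 mV mid-template
  }
  list(trace = data.frame(t_s = t, V_mV = v), spike_times = spike_times)
}

#' Sinusoidal concentration series with known coefficient of variation
#'
#' Generates `m (1 + a sin(2 pi t / T))`; over whole periods the population
#' CV tends to `a / sqrt(2)`.
#'
#' @param mean Mean level `m` (mM).
#' @param rel_amp Relative amplitude `a` (< 1).
#' @param period Period `T` (s).
#' @param duration Series length (s).
#' @param dt Sample interval (s).
#' @return Data frame with columns `t`, `x`; attribute `cv_expected`.
#' @export
fixture_timeseries <- function(mean = 1, rel_amp = 0.2, period = 10,
                               duration = 100, dt = 0.01) {
  if (rel_amp >= 1) stop("rel_amp must be < 1")
  t <- seq(0, duration, by = dt)
  x <- mean * (1 + rel_amp * sin(2 * pi * t / period))
  out <- data.frame(t = t, x = x)
  attr(out, "cv_expected") <- rel_amp / sqrt(2)
  out
}
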