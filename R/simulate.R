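# Protocol construction and the stiff-ODE simulator.
#
# Integration uses deSolve::lsoda on the compiled right-hand side, with the
# integration restarted at stimulus edges so the rectangular pulse is never
# stepped over. Output is sampled on a coarse grid for metabolic readouts
# plus a dense grid around and after the stimulus so action potentials are
# resolved for spike detection.

ngv_ctx <- function(params) {
  ngv_make_ctx(as.numeric(params) |> stats::setNames(names(params)),
               ngv_state_names())
}

#' Construct a simulation protocol
#'
#' @param label Protocol label.
#' @param t_end Total simulated time (s).
#' @param stim_start,stim_dur Stimulus onset (s) and duration (s; default
#'   the 30 ms pulse).
#' @param stim_amplitude Stimulus current (uA/cm^2).
#' @param deficiency Named coefficient vector (see [glut1_coefficients()])
#'   or `NULL` for control.
#' @param therapy A `therapy_spec` or `NULL`.
#' @param blood_mode `"clamped"` (arterial set points) or `"fluctuating"`
#'   (mean-reverting noisy traces; see [ou_blood_trace()]).
#' @param blood_spec Optional [blood_trace_spec()] for fluctuating mode.
#' @param seed Integer seed for the blood trace.
#' @param output_dt Coarse output interval (s).
#' @param spike_window Length (s) of the densely sampled window starting
#'   just before the stimulus, used for spike detection.
#' @param dense_dt Dense output interval (s).
#' @param rtol,atol Solver tolerances.
#' @param t_relax Pre-run relaxation horizon (s).
#' @return A `ngv_protocol` list.
#' @export
make_protocol <- function(label = "control", t_end = 200, stim_start = 50,
                          stim_dur = 0.03, stim_amplitude = 15,
                          deficiency = NULL, therapy = NULL,
                          blood_mode = c("clamped", "fluctuating"),
                          blood_spec = NULL, seed = 1L,
                          output_dt = 0.05, spike_window = 40,
                          dense_dt = 5e-4, rtol = 1e-6, atol = 1e-9,
                          t_relax = 400) {
  blood_mode <- match.arg(blood_mode)
  stim_end <- stim_start + stim_dur
  if (!(0 <= stim_start && stim_start < stim_end && stim_end <= t_end))
    stop("invalid protocol: need 0 <= stim_start < stim_end <= t_end")
  if (output_dt <= 0) stop("invalid protocol: output_dt must be > 0")
  structure(list(label = label, t_end = t_end, stim_start = stim_start,
                 stim_end = stim_end, stim_amplitude = stim_amplitude,
                 deficiency = deficiency, therapy = therapy,
                 blood_mode = blood_mode, blood_spec = blood_spec,
                 seed = as.integer(seed), output_dt = output_dt,
                 spike_window = spike_window, dense_dt = dense_dt,
                 rtol = rtol, atol = atol, t_relax = t_relax),
            class = "ngv_protocol")
}

# integrate [t0, t1] with constant stimulus, returning deSolve matrix
.integrate_segment <- function(ctx, y0, times, stim, rtol, atol) {
  f <- function(t, y, parms) list(ngv_rhs_cpp(ctx, t, y, stim))
  out <- deSolve::lsoda(y = y0, times = times, func = f, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("solver failure (istate = ", attr(out, "istate")[1], ")")
  out
}

#' Relax the model to its resting state
#'
#' Integrates without stimulus from the given (default) initial conditions
#' under clamped blood and returns the final state. Warns when the relative
#' residual derivative exceeds 1e-6.
#'
#' @param params Parameter vector.
#' @param t_relax Relaxation horizon (s).
#' @param y0 Starting state (default [default_initial_state()]).
#' @param rtol,atol Solver tolerances.
#' @return Resting state vector.
#' @export
relax_to_rest <- function(params, t_relax = 400,
                          y0 = default_initial_state(params),
                          rtol = 1e-6, atol = 1e-9) {
  if (t_relax <= 0) stop("t_relax must be > 0")
  ctx <- ngv_ctx(params)
  y <- as.numeric(y0) |> stats::setNames(names(y0))
  # alternate integration and Newton polishing: integration brings the
  # state onto the slow manifold, Newton lands it on the fixed point; slow
  # pools (glycogen) need a few rounds
  for (round in 1:6) {
    out <- .integrate_segment(ctx, y, seq(0, t_relax, length.out = 201),
                              0, rtol, atol)
    y <- out[nrow(out), -1]
    y <- .newton_polish(ctx, y, params)
    if (max(abs(ngv_rhs_cpp(ctx, 0, y, 0))) < 1e-8) break
  }
  ds <- ngv_rhs_cpp(ctx, t_relax, y, 0)
  rel <- abs(ds) / pmax(abs(y), 1e-3)
  if (max(rel) > 1e-6)
    warning("relaxation residual ", signif(max(rel), 3), " in ",
            names(y)[which.max(rel)])
  class(y) <- "ngv_state"
  y
}

# Conserved-moiety co-vectors (rows: one per pool, columns: states).
# Newton steps are projected onto the kernel of this matrix so polishing
# never moves mass between or out of conserved pools.
.conservation_matrix <- function(params, sn) {
  C <- NULL
  for (cell in c("n", "a")) {
    sf <- paste0("_", cell)
    vc <- params[[paste0("vol_", cell, "_cyt")]]
    vm <- params[[paste0("vol_", cell, "_mit")]]
    vi <- params[[paste0("vol_", cell, "_ims")]]
    row <- function(spec) {
      r <- stats::setNames(numeric(length(sn)), sn)
      r[names(spec)] <- spec
      r
    }
    C <- rbind(C,
      row(stats::setNames(c(1, 1), paste0(c("NAD", "NADH"), sf))),
      row(stats::setNames(c(1, 1), paste0(c("NADP", "NADPH"), sf))),
      row(stats::setNames(c(1, 1), paste0(c("NADmito", "NADHmito"), sf))),
      row(stats::setNames(c(1, 2), paste0(c("GSH", "GSSG"), sf))),
      row(stats::setNames(c(1, 1, 1),
            paste0(c("CoAmito", "AcCoAmito", "SUCCOAmito"), sf))),
      row(stats::setNames(c(vc, vc, vm, vm, vi),
            paste0(c("ATP", "ADP", "ATPmito", "ADPmito", "ATPims"), sf))))
  }
  C
}

# Scaled damped Newton on the full right-hand side; the pseudoinverse
# projects out the zero modes (Qpool constants) and every step is projected
# onto the conserved-pool manifold. Polishes the integrated end state to the
# exact resting fixed point; falls back to the integrated state when no
# descent is possible.
.newton_polish <- function(ctx, y, params, max_iter = 30, tol = 1e-10) {
  sn <- names(y)
  msk <- which(!sn %in% c("Qpool_n", "Qpool_a"))
  Cm <- .conservation_matrix(params, sn)
  # orthonormal basis of the pool co-vector span
  Q <- qr.Q(qr(t(Cm)))
  rhs <- function(yy) ngv_rhs_cpp(ctx, 0, yy, 0)
  nrm <- function(f) sqrt(sum(f[msk]^2))
  conc <- seq_len(length(y) - 6)  # all but the membrane block stay >= 0
  for (it in seq_len(max_iter)) {
    fy <- rhs(y)
    if (max(abs(fy)) < tol) break
    J <- matrix(0, length(msk), length(msk))
    for (jj in seq_along(msk)) {
      j <- msk[jj]
      h <- max(1e-9, 1e-6 * abs(y[j]))
      yp <- y; yp[j] <- yp[j] + h
      J[, jj] <- ((rhs(yp) - fy) / h)[msk]
    }
    cs <- pmax(abs(y[msk]), 1e-3)
    sv <- svd(sweep(J, 2, cs, `*`))
    # cutoff well above finite-difference Jacobian noise
    dinv <- ifelse(sv$d > max(sv$d) * 1e-8, 1 / sv$d, 0)
    dx <- numeric(length(y))
    dx[msk] <- cs * as.numeric(sv$v %*% (dinv * (t(sv$u) %*% (-fy[msk]))))
    dx <- dx - as.numeric(Q %*% (t(Q) %*% dx))  # keep pools exact
    f0 <- nrm(fy); lam <- 1; improved <- FALSE
    while (lam >= 1e-9) {
      yn <- y + lam * dx
      if (all(yn[conc] >= 0) && nrm(rhs(yn)) < (1 - 0.25 * lam) * f0) {
        improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
    y <- yn
  }
  y
}

#' Run a simulation protocol
#'
#' Applies the deficiency coefficients, then the therapy's parameter changes
#' (arterial supplements), relaxes to rest, applies the therapy's
#' initial-condition changes (injections, Qpool boost), and integrates
#' `[0, t_end]` with the stimulus, restarting at the pulse edges. States are
#' sampled on the coarse grid everywhere plus a dense grid from just before
#' the stimulus through the spike-observation window; per-process fluxes are
#' recorded at every sample.
#'
#' @param protocol A `ngv_protocol`.
#' @param params Parameter vector (control baseline).
#' @return A `ngv_result` list: `times`, `state` (time x variable matrix),
#'   `flux` (time x process matrix), `protocol`, `rest` (pre-run resting
#'   state), `diagnostics`.
#' @export
run_protocol <- function(protocol, params = make_default_parameters()) {
  stopifnot(inherits(protocol, "ngv_protocol"))
  p <- params
  if (!is.null(protocol$deficiency))
    p <- apply_glut1_deficiency(p, protocol$deficiency)
  if (!is.null(protocol$therapy)) {
    # parameter part first (blood set points in force during relaxation)
    tmp <- apply_therapy(default_initial_state(p), p, protocol$therapy)
    p <- tmp$params
  }
  rest <- relax_to_rest(p, protocol$t_relax, rtol = protocol$rtol,
                        atol = protocol$atol)
  y0 <- rest
  if (!is.null(protocol$therapy)) {
    tmp <- apply_therapy(rest, p, protocol$therapy)
    y0 <- tmp$state  # injections on top of the relaxed state
  }

  ctx <- ngv_ctx(p)
  if (protocol$blood_mode == "fluctuating") {
    spec <- protocol$blood_spec
    if (is.null(spec)) spec <- blood_trace_spec(duration = protocol$t_end,
                                                seed = protocol$seed)
    tr <- ou_blood_trace(spec)
    ngv_set_blood_trace(ctx, tr$t, tr$GLC, tr$LAC, tr$bHB)
  }

  ## output grid: coarse everywhere + dense through the spike window
  t_end <- protocol$t_end
  coarse <- seq(0, t_end, by = protocol$output_dt)
  dense <- seq(max(0, protocol$stim_start - 0.5),
               min(t_end, protocol$stim_end + protocol$spike_window),
               by = protocol$dense_dt)
  times <- sort(unique(signif(c(coarse, dense, protocol$stim_start,
                                protocol$stim_end, t_end), 12)))

  edges <- c(0, protocol$stim_start, protocol$stim_end, t_end)
  edges <- sort(unique(edges[edges >= 0 & edges <= t_end]))
  segs <- cbind(utils::head(edges, -1), utils::tail(edges, -1))
  y <- as.numeric(y0) |> stats::setNames(names(y0))
  rows <- list()
  for (i in seq_len(nrow(segs))) {
    t0 <- segs[i, 1]; t1 <- segs[i, 2]
    stim <- if (t0 >= protocol$stim_start && t1 <= protocol$stim_end)
      protocol$stim_amplitude else 0
    tt <- times[times >= t0 & times <= t1]
    if (length(tt) < 2 || tt[1] > t0) tt <- unique(c(t0, tt))
    if (tt[length(tt)] < t1) tt <- c(tt, t1)
    out <- .integrate_segment(ctx, y, tt, stim, protocol$rtol, protocol$atol)
    y <- out[nrow(out), -1]
    rows[[i]] <- out[if (i == 1) TRUE else -1, , drop = FALSE]
  }
  traj <- do.call(rbind, rows)
  tgrid <- traj[, 1]
  state <- traj[, -1, drop = FALSE]
  if (any(!is.finite(state))) stop("numerical failure: non-finite state")
  if (min(state[, setdiff(colnames(state), "V")]) < -1e-9)
    warning("negative concentration in output: ",
            min(state[, setdiff(colnames(state), "V")]))

  flux <- ngv_flux_matrix(ctx, tgrid, state)
  ngv_clear_blood_trace(ctx)
  structure(list(times = tgrid, state = state, flux = flux,
                 protocol = protocol, rest = rest,
                 diagnostics = list(n_samples = length(tgrid))),
            class = "ngv_result")
}

#' @export
print.ngv_result <- function(x, ...) {
  cat("<ngv_result>", x$protocol$label, "\n")
  cat("  ", length(x$times), "samples over", max(x$times), "s;",
      ncol(x$state), "states,", ncol(x$flux), "process fluxes\n")
  invisible(x)
}

#' Extract the voltage trace of a result
#'
#' @param result A `ngv_result`.
#' @param dense_only Keep only the densely sampled spike window (default),
#'   which is the part suitable for spike detection.
#' @return Data frame with columns `t_s`, `V_mV`.
#' @export
voltage_trace <- function(result, dense_only = TRUE) {
  pr <- result$protocol
  t <- result$times; v <- result$state[, "V"]
  if (dense_only) {
    keep <- t >= max(0, pr$stim_start - 0.5) &
      t <= min(pr$t_end, pr$stim_end + pr$spike_window)
    t <- t[keep]; v <- v[keep]
  }
  data.frame(t_s = t, V_mV = unname(v))
}

#' Tetanic seizure-study protocol
#'
#' The protocol used for the after-discharge experiments: a 2.2 s, 20
#' uA/cm^2 tetanic stimulus. A brief 30 ms pulse leaves the 3-4 evoked
#' action potentials metabolically invisible in this reduced model, so the
#' seizure study uses a sustained tetanus whose ionic load engages the
#' Na+/K+-ATPase and the perineuronal K+ balance; see the methods vignette.
#'
#' @param label Protocol label.
#' @param deficiency,therapy Passed to [make_protocol()].
#' @param ... Further arguments to [make_protocol()].
#' @return A `ngv_protocol`.
#' @export
seizure_protocol <- function(label = "seizure", deficiency = NULL,
                             therapy = NULL, ...) {
  make_protocol(label = label, t_end = 150, stim_start = 50,
                stim_dur = 2.2, stim_amplitude = 20,
                deficiency = deficiency, therapy = therapy,
                spike_window = 60, dense_dt = 1e-3, ...)
}
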