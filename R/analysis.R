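# Quantitative readouts: spike and after-discharge detection, metabolite
# variability (CV) by functional group, redox and flux ratios, lactate flux
# summaries, therapy scoring/ranking, and metabolite-change clustering.

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of the threshold separated from the
#' previous spike by at least the refractory period.
#'
#' @param trace Data frame with columns `t_s`, `V_mV` (uniformly sampled).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum inter-spike interval (s); must be at least two
#'   sample intervals.
#' @param stim_window Optional numeric `c(start, end)` (s) recorded in the
#'   result and used for the after-discharge count.
#' @return A `spike_train` list: `times`, `threshold`, `refractory`,
#'   `stim_window`, `afterdischarge_count`.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2e-3,
                          stim_window = NULL) {
  t <- trace$t_s; v <- trace$V_mV
  if (any(diff(t) <= 0)) stop("invalid input: non-monotone time grid")
  dt <- stats::median(diff(t))
  if (refractory < 2 * dt * (1 - 1e-9))
    stop("refractory must be >= 2 sample intervals")
  up <- which(diff(v > threshold) == 1) + 1
  times <- t[up]
  if (length(times) > 1) {
    keep <- c(TRUE, rep(FALSE, length(times) - 1))
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  st <- structure(list(times = times, threshold = threshold,
                       refractory = refractory, stim_window = stim_window,
                       afterdischarge_count = NA_integer_),
                  class = "spike_train")
  if (!is.null(stim_window))
    st$afterdischarge_count <- count_afterdischarges(st, stim_window)
  st
}

#' Count after-discharge spikes
#'
#' After-discharges are spikes occurring after the stimulus has ended —
#' the model's seizure proxy.
#'
#' @param spikes A `spike_train`.
#' @param stim_window Numeric `c(start, end)` (s).
#' @return Integer count of spikes with time > `stim_window[2]`.
#' @export
count_afterdischarges <- function(spikes, stim_window) {
  sum(spikes$times > stim_window[2])
}

#' Coefficient of variation of a concentration series
#'
#' @param series Data frame with columns `t`, `x`, or a numeric vector.
#' @param window Optional numeric `c(start, end)` (s) restricting the
#'   samples (requires the data-frame form).
#' @return List with `mean`, `sd`, `cv` (sample sd / mean) and `defined`
#'   (`FALSE`, with `cv = NA`, when the mean is not positive).
#' @export
compute_cv <- function(series, window = NULL) {
  if (is.data.frame(series)) {
    x <- series$x
    if (!is.null(window)) x <- x[series$t >= window[1] & series$t <= window[2]]
  } else x <- as.numeric(series)
  if (length(x) < 3) stop("need at least 3 samples")
  m <- mean(x); s <- stats::sd(x)
  if (m <= 0) return(list(mean = m, sd = s, cv = NA_real_, defined = FALSE))
  list(mean = m, sd = s, cv = s / m, defined = TRUE)
}

#' Per-metabolite CV report with functional groups
#'
#' Computes the coefficient of variation of every reported metabolite over
#' the analysis window, labels it with its functional group and cell, and
#' summarizes per group and per cell (mean and median log10 CV). Metabolites
#' shared between neuron and astrocyte are paired for the astro-vs-neuron
#' comparison.
#'
#' @param result A `ngv_result`.
#' @param grouping Named map base-metabolite -> group label (default
#'   [metabolite_groups()]). Every reported metabolite must be covered.
#' @param window Analysis window `c(start, end)` (s); default the whole
#'   trajectory.
#' @return List of class `cv_report`: `table` (per metabolite), `groups`
#'   (per group x cell summary), `cells` (per cell summary), `paired`
#'   (astro vs neuron CV for shared metabolites).
#' @export
cv_report <- function(result, grouping = metabolite_groups(), window = NULL) {
  t <- result$times
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  st <- result$state[keep, , drop = FALSE]
  # cell metabolites only (exclude gating/membrane and extracellular chain)
  rows <- list()
  membrane <- c("V", "gate_m", "gate_h", "gate_n", "Na_in", "K_out")
  for (nm in setdiff(colnames(st), membrane)) {
    cell <- if (grepl("_n$", nm)) "neuron" else if (grepl("_a$", nm))
      "astrocyte" else next
    base <- sub("_[na]$", "", nm)
    if (base %in% c("Qpool")) next
    if (!base %in% names(grouping))
      stop("unmapped metabolite: ", base)
    cv <- compute_cv(st[, nm])
    rows[[nm]] <- data.frame(metabolite = base, state = nm, cell = cell,
                             group = unname(grouping[base]), mean = cv$mean,
                             sd = cv$sd, cv = cv$cv,
                             log10_cv = ifelse(is.na(cv$cv) | cv$cv <= 0,
                                               NA, log10(cv$cv)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  groups <- stats::aggregate(log10_cv ~ group + cell, tab,
                             function(z) mean(z, na.rm = TRUE))
  cells <- do.call(rbind, lapply(split(tab, tab$cell), function(d)
    data.frame(cell = d$cell[1],
               mean_log10_cv = mean(d$log10_cv, na.rm = TRUE),
               median_log10_cv = stats::median(d$log10_cv, na.rm = TRUE))))
  rownames(cells) <- NULL
  shared <- intersect(tab$metabolite[tab$cell == "neuron"],
                      tab$metabolite[tab$cell == "astrocyte"])
  paired <- data.frame(
    metabolite = shared,
    group = unname(grouping[shared]),
    cv_neuron = tab$cv[match(paste0(shared, "_n"), tab$state)],
    cv_astro = tab$cv[match(paste0(shared, "_a"), tab$state)])
  paired$astro_higher <- paired$cv_astro > paired$cv_neuron
  structure(list(table = tab, groups = groups, cells = cells,
                 paired = paired, window = window), class = "cv_report")
}

.ratio_series <- function(st, num, den) {
  # denominator floor keeps ratios finite when a nucleotide pool empties
  d <- pmax(st[, den], 1e-4)
  st[, num] / d
}

#' Redox-ratio report
#'
#' Computes the redox and adenylate ratio families per cell: NAD+/NADH
#' (cytosol and mitochondrion), NADP+/NADPH (cytosol), and ATP/ADP
#' (cytosol, matrix, and IMS; the IMS, which carries only ATP, is reported
#' relative to cytosolic ADP). Baseline is the mean over the pre-stimulus
#' window, post the mean over the post-stimulus window.
#'
#' @param result A `ngv_result`.
#' @return A `redox_report`: data frame `ratios` (cell, compartment, family,
#'   baseline, post) plus the underlying `series`.
#' @export
redox_ratios <- function(result) {
  st <- result$state; t <- result$times
  pr <- result$protocol
  pre <- t < pr$stim_start
  post <- t > pr$stim_end
  series <- list()
  rows <- list()
  for (cell in c("n", "a")) {
    sf <- paste0("_", cell)
    cn <- if (cell == "n") "neuron" else "astrocyte"
    fams <- list(
      c("nad_cyt", "cytosol", paste0("NAD", sf), paste0("NADH", sf)),
      c("nad_mito", "mitochondrion", paste0("NADmito", sf), paste0("NADHmito", sf)),
      c("nadp_cyt", "cytosol", paste0("NADP", sf), paste0("NADPH", sf)),
      c("atp_adp_cyt", "cytosol", paste0("ATP", sf), paste0("ADP", sf)),
      c("atp_adp_mito", "mitochondrion", paste0("ATPmito", sf), paste0("ADPmito", sf)),
      c("atp_adp_ims", "ims", paste0("ATPims", sf), paste0("ADP", sf)))
    for (f in fams) {
      r <- .ratio_series(st, f[3], f[4])
      key <- paste0(f[1], sf)
      series[[key]] <- r
      rows[[key]] <- data.frame(cell = cn, compartment = f[2], family = f[1],
                                baseline = mean(r[pre], na.rm = TRUE),
                                post = mean(r[post], na.rm = TRUE))
    }
  }
  ratios <- do.call(rbind, rows); rownames(ratios) <- NULL
  structure(list(ratios = ratios, series = series, times = t),
            class = "redox_report")
}

#' Glycolytic vs oxidative flux ratios
#'
#' Per-cell time series of JATPglyc/JATPox and JNADHglyc/JNADHox: gross
#' glycolytic ATP production (2 per lower-glycolysis event) over
#' ATP-synthase flux, and glycolytic NADH production over ETC oxidation
#' (both in the flux's own reference compartment; the mitochondrial fluxes
#' are volume-corrected to cytosolic units so the ratios are dimensionless
#' and comparable).
#'
#' @param result A `ngv_result`.
#' @return List per cell with `atp_ratio`, `nadh_ratio` series and their
#'   means; samples with zero denominator are NA.
#' @export
flux_ratios <- function(result) {
  fl <- result$flux
  vols <- ngv_volumes()
  out <- list()
  for (cell in c("n", "a")) {
    sf <- paste0("_", cell)
    cn <- if (cell == "n") "neuron" else "astro"
    v_fac <- vols[[paste0(cn, "_mito")]] / vols[[paste0(cn, "_cyt")]]
    glyc_atp <- 2 * fl[, paste0("lgly", sf)]
    ox_atp <- (fl[, paste0("atpsyn", sf)] + fl[, paste0("scs", sf)]) * v_fac
    glyc_nadh <- fl[, paste0("lgly", sf)]
    ox_nadh <- fl[, paste0("etc", sf)] * v_fac
    out[[if (cell == "n") "neuron" else "astrocyte"]] <- list(
      atp_ratio = ifelse(ox_atp != 0, glyc_atp / ox_atp, NA_real_),
      nadh_ratio = ifelse(ox_nadh != 0, glyc_nadh / ox_nadh, NA_real_),
      atp_ratio_mean = mean(ifelse(ox_atp != 0, glyc_atp / ox_atp, NA),
                            na.rm = TRUE),
      nadh_ratio_mean = mean(ifelse(ox_nadh != 0, glyc_nadh / ox_nadh, NA),
                             na.rm = TRUE))
  }
  out$times <- result$times
  out
}

# the ratio families entering the restoration score
.score_families <- function(mode) {
  switch(mode,
    total_redox = c("nad_cyt", "nad_mito", "nadp_cyt", "atp_adp_cyt",
                    "atp_adp_mito"),
    atp_only = c("atp_adp_cyt", "atp_adp_mito"),
    stop("unknown mode: ", mode))
}

#' Redox-restoration score of a therapy
#'
#' Restoration distance of the therapy run from the control run: for each
#' ratio family in the mode's set (cytosolic and mitochondrial, both
#' cells), the absolute relative deviation of the therapy baseline from the
#' control baseline, summed. Lower is better; a therapy identical to
#' control scores 0. A raw sum of ratios would reward overshoot, so the
#' normalized absolute deviation is used.
#'
#' @param result_therapy,result_control,result_disease `ngv_result` objects
#'   on the same protocol grid (the disease run is accepted for interface
#'   symmetry and sanity checks).
#' @param mode `"total_redox"` (NAD+/NADH + ATP/ADP + NADP+/NADPH) or
#'   `"atp_only"`.
#' @return Numeric score (dimensionless, >= 0).
#' @export
therapy_score <- function(result_therapy, result_control,
                          result_disease = NULL,
                          mode = c("total_redox", "atp_only")) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(result_therapy$times, result_control$times)))
    stop("invalid input: protocol grids differ")
  rt <- redox_ratios(result_therapy)$ratios
  rc <- redox_ratios(result_control)$ratios
  fams <- .score_families(mode)
  sel <- rt$family %in% fams
  sum(abs(rt$baseline[sel] - rc$baseline[sel]) / rc$baseline[sel])
}

#' Rank therapies by restoration score
#'
#' @param scores Named numeric vector therapy -> score (lower = better).
#' @return Data frame of class `therapy_ranking`: therapy, score, rank
#'   (ascending by score, ties broken alphabetically by label).
#' @export
rank_therapies <- function(scores) {
  stopifnot(length(scores) >= 1)
  ord <- order(scores, names(scores))
  out <- data.frame(therapy = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_along(scores))
  class(out) <- c("therapy_ranking", "data.frame")
  out
}

#' Net lactate flux per cell
#'
#' Net lactate gain of each cell (transport in plus LDH production, minus
#' consumption; mM/s in the cell's cytosol; positive = lactate accumulating
#' or being produced by the cell) plus the extracellular balance terms.
#'
#' @param result A `ngv_result`.
#' @return List with per-cell series (`neuron`, `astrocyte`), their means,
#'   and `blood_exchange` (endothelium-blood MCT flux).
#' @export
lactate_flux_summary <- function(result) {
  fl <- result$flux
  vols <- ngv_volumes()
  # transport into neuron: mct_n (ref ecsAN); into astro: mct_ea (ref ecsBA)
  # minus mct_an out (ref astro_cyt)
  n_in <- fl[, "mct_n"] * vols[["ecsAN"]] / vols[["neuron_cyt"]]
  a_in <- fl[, "mct_ea"] * vols[["ecsBA"]] / vols[["astro_cyt"]] - fl[, "mct_an"]
  neuron <- n_in + fl[, "ldh_n"]
  astro <- a_in + fl[, "ldh_a"]
  list(neuron = neuron, astrocyte = astro,
       neuron_mean = mean(neuron), astro_mean = mean(astro),
       ldh = list(neuron = fl[, "ldh_n"], astro = fl[, "ldh_a"]),
       transport = list(neuron = n_in, astro = a_in),
       blood_exchange = fl[, "mct_be"], times = result$times)
}

#' Hierarchical clustering of metabolite changes
#'
#' Agglomerative clustering (average linkage, cosine distance) of a
#' metabolite x condition matrix of log2 fold changes versus control.
#'
#' @param change_matrix Numeric matrix, rows = metabolites (named),
#'   columns = conditions.
#' @return List with `hclust` (the merge tree), `order` (row order),
#'   `distance` (the cosine distance matrix).
#' @export
cluster_metabolite_changes <- function(change_matrix) {
  m <- as.matrix(change_matrix)
  if (nrow(m) < 2) stop("need at least 2 rows")
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero))
    stop("invalid input: all-zero row for ",
         paste(rownames(m)[zero], collapse = ", "))
  sim <- (m / norms) %*% t(m / norms)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order, distance = d)
}

#' Log2 fold-change matrix versus control
#'
#' Builds the metabolite x condition change matrix used for clustering,
#' with `log2((x + eps) / (ref + eps))` and `eps = 1e-6` mM guarding
#' near-zero metabolites.
#'
#' @param baselines Named list of named numeric vectors: per condition, the
#'   baseline (pre-stimulus mean) metabolite concentrations.
#' @param control Name of the control condition in `baselines`.
#' @param eps Regularization (mM).
#' @return Matrix of log2 fold changes (conditions as columns, control
#'   omitted).
#' @export
fold_change_matrix <- function(baselines, control = "control", eps = 1e-6) {
  ref <- baselines[[control]]
  conds <- setdiff(names(baselines), control)
  out <- vapply(conds, function(cd)
    log2((baselines[[cd]] + eps) / (ref + eps)), numeric(length(ref)))
  rownames(out) <- names(ref)
  out
}

#' Baseline (pre-stimulus mean) state of a result
#'
#' @param result A `ngv_result`.
#' @return Named numeric vector: mean of every state over the pre-stimulus
#'   window.
#' @export
baseline_state <- function(result) {
  pre <- result$times < result$protocol$stim_start
  colMeans(result$state[pre, , drop = FALSE])
}
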