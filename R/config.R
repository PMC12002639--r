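# Study configuration and the end-to-end study runner.

.config_keys <- c("label", "seed", "deficiency_factor", "therapies",
                  "atp_ladder_n", "atp_ladder_dmax", "cv_duration",
                  "parameter_overrides", "stimulus")
.stim_keys <- c("amplitude", "duration", "start", "t_end")

#' Load and validate a study configuration
#'
#' Reads a YAML study configuration: seed, deficiency factor, therapy
#' selection, ATP-ladder settings, variability-study duration, optional
#' parameter overrides and stimulus overrides. Unknown keys are rejected
#' with the offending key named; a loaded configuration round-trips through
#' [yaml::as.yaml()] identically.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list of class `ngv_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  defaults <- list(label = "ngv_study", seed = 1L, deficiency_factor = 0.4,
                   therapies = names(make_standard_therapies()),
                   atp_ladder_n = 5L, atp_ladder_dmax = 1.0,
                   cv_duration = 600, parameter_overrides = list(),
                   stimulus = list())
  cfg <- utils::modifyList(defaults, cfg)
  if (length(cfg$stimulus)) {
    bad <- setdiff(names(cfg$stimulus), .stim_keys)
    if (length(bad)) stop("unknown stimulus key: ", paste(bad, collapse = ", "))
  }
  known_th <- names(make_standard_therapies())
  bad_th <- setdiff(cfg$therapies, known_th)
  if (length(bad_th))
    stop("unknown therapy: ", paste(bad_th, collapse = ", "))
  if (cfg$deficiency_factor < 0 || cfg$deficiency_factor > 1)
    stop("deficiency_factor must be in [0, 1]")
  if (length(cfg$parameter_overrides)) {
    p <- make_default_parameters()
    bad_p <- setdiff(names(cfg$parameter_overrides), names(p))
    if (length(bad_p))
      stop("unknown parameter override: ", paste(bad_p, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "ngv_config")
}

.study_params <- function(config) {
  p <- make_default_parameters()
  ov <- config$parameter_overrides
  if (length(ov)) p[names(ov)] <- unlist(ov)
  p
}

.study_seizure_protocol <- function(config, label, deficiency = NULL,
                                    therapy = NULL) {
  st <- config$stimulus
  args <- list(label = label, deficiency = deficiency, therapy = therapy)
  if (!is.null(st$amplitude)) args$stim_amplitude <- st$amplitude
  if (!is.null(st$duration)) args$stim_dur <- st$duration
  if (!is.null(st$start)) args$stim_start <- st$start
  if (!is.null(st$t_end)) args$t_end <- st$t_end
  do.call(seizure_protocol, args)
}

#' Run the full study
#'
#' Executes the complete analysis pipeline of the package: control and
#' deficiency seizure runs, the ATP dose ladder and glucose rescue, the
#' fluctuating-blood variability experiment, the therapy panel with the
#' redox-restoration ranking, the lactate-flux summary, and the
#' metabolite-change clustering. Tabular outputs are written as CSV, the
#' summary as JSON, into `out_dir`.
#'
#' @param config A `ngv_config` (see [load_config()]) or `NULL` for the
#'   defaults.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all results and summary tables.
#' @export
run_study <- function(config = NULL, out_dir = tempfile("ngv_study_"),
                      quiet = FALSE) {
  if (is.null(config))
    config <- structure(list(label = "ngv_study", seed = 1L,
                             deficiency_factor = 0.4,
                             therapies = names(make_standard_therapies()),
                             atp_ladder_n = 5L, atp_ladder_dmax = 1.0,
                             cv_duration = 600,
                             parameter_overrides = list(), stimulus = list()),
                        class = "ngv_config")
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- .study_params(config)
  def <- glut1_coefficients(config$deficiency_factor)

  ## --- seizure phenotype and rescue ---
  say("seizure runs (control, deficiency, ATP ladder, GLC rescue) ...")
  pr_c <- .study_seizure_protocol(config, "control")
  pr_d <- .study_seizure_protocol(config, "glut1_ds", deficiency = def)
  res_c <- run_protocol(pr_c, p)
  res_d <- run_protocol(pr_d, p)
  sw <- c(pr_c$stim_start, pr_c$stim_end)
  n_ad <- function(r) detect_spikes(voltage_trace(r),
                                    stim_window = sw)$afterdischarge_count
  ladder <- atp_dose_ladder(config$atp_ladder_n, config$atp_ladder_dmax)
  rescue <- data.frame(condition = c("control", "glut1_ds"),
                       dose_mM = c(0, 0),
                       afterdischarges = c(n_ad(res_c), n_ad(res_d)))
  for (th in ladder) {
    pr <- .study_seizure_protocol(config, th$name, deficiency = def,
                                  therapy = th)
    rescue <- rbind(rescue, data.frame(condition = th$name,
                                       dose_mM = unname(th$inject[["ATP"]]),
                                       afterdischarges = n_ad(run_protocol(pr, p))))
  }
  # glucose rescue: transporter coefficient restored to 1
  pr_g <- .study_seizure_protocol(config, "glc_rescue",
                                  deficiency = glut1_coefficients(1.0))
  rescue <- rbind(rescue, data.frame(condition = "glc_rescue", dose_mM = 0,
                                     afterdischarges = n_ad(run_protocol(pr_g, p))))
  utils::write.csv(rescue, file.path(out_dir, "rescue_table.csv"),
                   row.names = FALSE)

  ## --- variability under fluctuating blood ---
  say("variability runs (fluctuating blood) ...")
  spec <- blood_trace_spec(duration = config$cv_duration, seed = config$seed)
  mk_cv <- function(label, deficiency = NULL)
    make_protocol(label, t_end = config$cv_duration, stim_start = 50,
                  stim_dur = 0.03, stim_amplitude = 0,
                  deficiency = deficiency, blood_mode = "fluctuating",
                  blood_spec = spec, seed = config$seed, output_dt = 0.5,
                  spike_window = 0.5)
  cv_c <- cv_report(run_protocol(mk_cv("cv_control"), p))
  cv_d <- cv_report(run_protocol(mk_cv("cv_glut1_ds", def), p))
  utils::write.csv(cv_c$table, file.path(out_dir, "cv_control.csv"),
                   row.names = FALSE)
  utils::write.csv(cv_d$table, file.path(out_dir, "cv_glut1_ds.csv"),
                   row.names = FALSE)

  ## --- therapy panel, redox ranking, lactate, clustering ---
  say("therapy panel and ranking ...")
  mk_th <- function(label, therapy = NULL, deficiency = def)
    make_protocol(label, t_end = 120, stim_start = 100, stim_dur = 0.03,
                  stim_amplitude = 0, deficiency = deficiency,
                  therapy = therapy, output_dt = 0.2, spike_window = 1)
  base_c <- run_protocol(mk_th("redox_control", deficiency = NULL), p)
  base_d <- run_protocol(mk_th("redox_glut1_ds"), p)
  therapies <- make_standard_therapies()[config$therapies]
  th_res <- lapply(therapies, function(th)
    run_protocol(mk_th(th$name, therapy = th), p))
  scores <- vapply(th_res, therapy_score, numeric(1),
                   result_control = base_c, result_disease = base_d,
                   mode = "total_redox")
  ranking <- rank_therapies(scores)
  scores_atp <- vapply(th_res, therapy_score, numeric(1),
                       result_control = base_c, result_disease = base_d,
                       mode = "atp_only")
  ranking_atp <- rank_therapies(scores_atp)
  utils::write.csv(ranking, file.path(out_dir, "therapy_ranking_total_redox.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking_atp, file.path(out_dir, "therapy_ranking_atp_only.csv"),
                   row.names = FALSE)
  redox_tab <- do.call(rbind, c(
    list(cbind(condition = "control", redox_ratios(base_c)$ratios),
         cbind(condition = "glut1_ds", redox_ratios(base_d)$ratios)),
    lapply(names(th_res), function(nm)
      cbind(condition = nm, redox_ratios(th_res[[nm]])$ratios))))
  utils::write.csv(redox_tab, file.path(out_dir, "redox_ratios.csv"),
                   row.names = FALSE)
  lac <- do.call(rbind, c(
    list(data.frame(condition = "control",
                    neuron = lactate_flux_summary(base_c)$neuron_mean,
                    astrocyte = lactate_flux_summary(base_c)$astro_mean),
         data.frame(condition = "glut1_ds",
                    neuron = lactate_flux_summary(base_d)$neuron_mean,
                    astrocyte = lactate_flux_summary(base_d)$astro_mean)),
    lapply(names(th_res), function(nm)
      data.frame(condition = nm,
                 neuron = lactate_flux_summary(th_res[[nm]])$neuron_mean,
                 astrocyte = lactate_flux_summary(th_res[[nm]])$astro_mean))))
  utils::write.csv(lac, file.path(out_dir, "lactate_flux.csv"),
                   row.names = FALSE)

  say("clustering metabolite changes ...")
  bl <- c(list(control = baseline_state(base_c),
               glut1_ds = baseline_state(base_d)),
          lapply(th_res, baseline_state))
  fc <- fold_change_matrix(bl, control = "control")
  keep <- apply(fc, 1, function(r) any(r != 0)) &
    !grepl("^(V|gate_|Na_in|K_out|Qpool)", rownames(fc))
  clust <- cluster_metabolite_changes(fc[keep, , drop = FALSE])
  utils::write.csv(data.frame(metabolite = rownames(fc[keep, ])[clust$order],
                              position = seq_along(clust$order)),
                   file.path(out_dir, "cluster_order.csv"), row.names = FALSE)

  summary <- list(
    label = config$label, seed = config$seed,
    deficiency_factor = config$deficiency_factor,
    afterdischarges_control = rescue$afterdischarges[1],
    afterdischarges_glut1_ds = rescue$afterdischarges[2],
    afterdischarges_top_dose = utils::tail(
      rescue$afterdischarges[grepl("ATP_dose", rescue$condition)], 1),
    best_therapy_total_redox = ranking$therapy[1],
    best_therapy_atp_only = ranking_atp$therapy[1],
    astro_cv_majority = mean(cv_c$paired$astro_higher[
      cv_c$paired$group %in% c("GLCLS", "TCA")]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, rescue = rescue, cv_control = cv_c,
                 cv_glut1_ds = cv_d, ranking = ranking,
                 ranking_atp = ranking_atp, redox = redox_tab,
                 lactate = lac, clustering = clust, summary = summary,
                 results = list(control = res_c, glut1_ds = res_d,
                                redox_control = base_c,
                                redox_glut1_ds = base_d, therapies = th_res),
                 out_dir = out_dir))
}
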