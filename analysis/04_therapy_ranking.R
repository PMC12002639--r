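#!/usr/bin/env Rscript
# Redox-restoration scoring of the standard therapy panel on the GLUT1
# deficiency background. Writes results/therapy_ranking_*.csv and
# results/redox_ratios.csv.

suppressMessages(library(ngvmet))
dir.create("results", showWarnings = FALSE)

p <- make_default_parameters()
def <- glut1_coefficients(0.4)
mk <- function(label, therapy = NULL, deficiency = def)
  make_protocol(label, t_end = 120, stim_start = 100, stim_dur = 0.03,
                stim_amplitude = 0, deficiency = deficiency,
                therapy = therapy, output_dt = 0.2, spike_window = 1)
b_c <- suppressWarnings(run_protocol(mk("control", deficiency = NULL), p))
b_d <- suppressWarnings(run_protocol(mk("glut1_ds"), p))
ths <- make_standard_therapies()
res <- lapply(ths, function(th)
  suppressWarnings(run_protocol(mk(th$name, therapy = th), p)))

for (mode in c("total_redox", "atp_only")) {
  sc <- vapply(res, therapy_score, numeric(1), result_control = b_c,
               result_disease = b_d, mode = mode)
  rk <- rank_therapies(sc)
  write.csv(rk, paste0("results/therapy_ranking_", mode, ".csv"),
            row.names = FALSE)
  message("mode ", mode, ": best therapy is ", rk$therapy[1],
          " (score ", round(rk$score[1], 3), "; untreated deficiency ",
          round(therapy_score(b_d, b_c, b_d, mode = mode), 3), ")")
  print(rk, row.names = FALSE)
}
redox_tab <- do.call(rbind, c(
  list(cbind(condition = "control", redox_ratios(b_c)$ratios),
       cbind(condition = "glut1_ds", redox_ratios(b_d)$ratios)),
  lapply(names(res), function(nm)
    cbind(condition = nm, redox_ratios(res[[nm]])$ratios))))
write.csv(redox_tab, "results/redox_ratios.csv", row.names = FALSE)
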