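#!/usr/bin/env Rscript
# Stage 3: characterize the balloon-alone pressure-volume curves.
# Per curve: residual volume (change-point), elastance (least-squares slope),
# and the volume at which internal pressure reaches 40 cmH2O; per catheter:
# median and interquartile range.

library(ebbench)

pv <- read_pv_csv("results/pv_curves.csv")
fits <- fit_pv_curves(pv)
utils::write.csv(fits, "results/elastance_fits.csv", row.names = FALSE)

summ <- do.call(rbind, lapply(split(fits, factor(fits$catheter,
                                                 levels = unique(fits$catheter))),
                              function(d) {
  e <- summarize_values(d$elastance_hat)
  v <- summarize_values(d$v_res_hat)
  v40 <- summarize_values(d$v40_hat)
  tibble::tibble(catheter = d$catheter[1],
                 elastance_median = e$median, elastance_q1 = e$q1,
                 elastance_q3 = e$q3,
                 v_res_median = v$median, v_res_q1 = v$q1, v_res_q3 = v$q3,
                 v40_median = v40$median, v40_q1 = v40$q1, v40_q3 = v40$q3)
}))
utils::write.csv(summ, "results/elastance_summary.csv", row.names = FALSE)

for (i in seq_len(nrow(summ)))
  message(sprintf(
    "  %-13s elastance %.1f (%.1f-%.1f) cmH2O/mL, V_res %.1f mL, V_40 %.1f mL",
    summ$catheter[i], summ$elastance_median[i], summ$elastance_q1[i],
    summ$elastance_q3[i], summ$v_res_median[i], summ$v40_median[i]))
message("wrote results/elastance_fits.csv, results/elastance_summary.csv")
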