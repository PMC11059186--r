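#!/usr/bin/env Rscript
# Stage 4: the surrogate positive-pressure occlusion test.
# Starting from each catheter's mean V_accuracy-min (stage 2), titrate the
# inflation volume in 0.1-mL steps until delta-Pes/delta-Pbox lies in
# 0.8-1.2, then sweep the chamber pressures at the titrated volume
# (9 pressures x 3 replicates = 27 TEP values per catheter).

library(ebbench)

seed <- 20260104
sc <- default_study_config(seed = seed)
rng <- utils::read.csv("results/accuracy_ranges.csv")
start <- tapply(rng$v_accuracy_min, rng$catheter,
                function(x) mean(x, na.rm = TRUE))

ph <- run_ppot_phase(sc$catheters, sc$esophagus, start, sc$bench, seed = seed)

utils::write.csv(ph$teps, "results/ppot_teps.csv", row.names = FALSE)
utils::write.csv(ph$summary, "results/ppot_summary.csv", row.names = FALSE)
titr <- lapply(ph$titrations, function(t)
  t[c("catheter_name", "start_volume", "final_volume", "final_ratio",
      "n_adjustments", "converged", "oscillated")])
jsonlite::write_json(titr, "results/ppot_titrations.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

for (t in ph$titrations)
  message(sprintf("  %-13s %.2f -> %.2f mL (%d adj), ratio %.2f%s",
                  t$catheter_name, t$start_volume, t$final_volume,
                  t$n_adjustments, t$final_ratio,
                  if (t$converged) "" else "  [NOT CONVERGED]"))
s <- ph$summary
for (i in seq_len(nrow(s)))
  message(sprintf("  %-13s %d/%d in band (%.1f%%), TEP median %.1f (%.1f to %.1f)",
                  s$catheter[i], s$n_in_band[i], s$n_total[i], s$percent[i],
                  s$tep_median[i], s$tep_q1[i], s$tep_q3[i]))
message("total fixed-volume TEP values: ", nrow(ph$teps))
message("wrote results/ppot_teps.csv, results/ppot_summary.csv, results/ppot_titrations.json")
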