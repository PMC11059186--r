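#!/usr/bin/env Rscript
# Stage 2: TEP accuracy banding on the chamber sweeps.
# Per sweep: V_accuracy-min, V_accuracy-max, V_working at the 0 +/- 1 cmH2O
# band; per catheter: pooled descriptive summary and the accuracy rate at the
# manufacturer-recommended inflation volumes.

library(ebbench)

sweeps <- read_sweeps_csv("results/chamber_sweeps.csv")
caths <- default_catheters()

rng <- accuracy_ranges(sweeps)
utils::write.csv(rng, "results/accuracy_ranges.csv", row.names = FALSE)

t2 <- table2_summary(rng)
utils::write.csv(t2, "results/accuracy_volume_summary.csv", row.names = FALSE)

rec <- recommended_volume_accuracy(sweeps, caths)
utils::write.csv(rec, "results/recommended_volume_accuracy.csv",
                 row.names = FALSE)

message(nrow(rng), " sweeps banded; ", sum(!is.na(rng$v_working)),
        " had >= 2 in-band volumes (V_working defined)")
for (i in seq_len(nrow(t2)))
  message(sprintf("  %-13s V_working mean %.2f mL, median %.2f mL",
                  t2$catheter[i], t2$v_working_mean[i], t2$v_working_median[i]))
ok <- !rec$skipped
message("accuracy at recommended volumes: ",
        paste(sprintf("%s %.1f%%", rec$catheter[ok], rec$percent[ok]),
              collapse = ", "))
message("wrote results/accuracy_ranges.csv, results/accuracy_volume_summary.csv, results/recommended_volume_accuracy.csv")
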