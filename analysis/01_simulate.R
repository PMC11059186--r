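#!/usr/bin/env Rscript
# Stage 1: simulate the two bench phases for the bundled seven-catheter study
# and write the raw datasets.
#   - chamber phase: 7 catheters x 9 chamber pressures (-20..+20 cmH2O) x 3
#     replicates = 189 inflation sweeps
#   - balloon-alone phase: 7 catheters x 3 samples = 21 pressure-volume curves

library(ebbench)

seed <- 20260101
sc <- default_study_config(seed = seed)
dir.create("results", showWarnings = FALSE)

sweeps <- run_study_grid(sc$catheters, sc$esophagus, sc$bench, seed = seed)
n_sweeps <- nrow(unique(sweeps[c("catheter", "p_box_cmH2O", "replicate")]))
write_sweeps_csv(sweeps, "results/chamber_sweeps.csv")

pv <- run_elastance_grid(sc$catheters, sc$bench, seed = seed + 1L)
n_curves <- nrow(unique(pv[c("catheter", "replicate")]))
write_pv_csv(pv, "results/pv_curves.csv")

provenance_record(sc, seed,
                  counts = list(chamber_sweeps = n_sweeps,
                                chamber_steps = nrow(sweeps),
                                pv_curves = n_curves,
                                pv_steps = nrow(pv)),
                  path = "results/provenance.json")

message("chamber phase: ", n_sweeps, " sweeps (", nrow(sweeps), " steps)")
message("balloon-alone phase: ", n_curves, " curves (", nrow(pv), " steps)")
message("wrote results/chamber_sweeps.csv, results/pv_curves.csv, results/provenance.json")
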