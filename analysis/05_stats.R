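#!/usr/bin/env Rscript
# Stage 5: the statistical layer across catheters.
# Kruskal-Wallis global tests with Bonferroni-corrected pairwise rank-sum
# post-hoc comparisons for V_accuracy-max, V_working, elastance and the
# post-occlusion-test TEP; Fisher exact test on the in/out-of-band counts.

library(ebbench)

rng <- utils::read.csv("results/accuracy_ranges.csv")
fits <- utils::read.csv("results/elastance_fits.csv")
teps <- utils::read.csv("results/ppot_teps.csv")
ppot <- utils::read.csv("results/ppot_summary.csv")

metrics <- list(
  v_accuracy_max = list(values = rng$v_accuracy_max, group = rng$catheter),
  v_working = list(values = rng$v_working, group = rng$catheter),
  elastance = list(values = fits$elastance_hat, group = fits$catheter),
  ppot_tep = list(values = teps$tep_cmH2O, group = teps$catheter)
)

results <- list()
for (nm in names(metrics)) {
  m <- metrics[[nm]]
  cmp <- group_comparison(m$values, m$group)
  results[[nm]] <- list(
    global = cmp$global,
    n_significant_pairs = sum(cmp$pairwise$significant),
    pairwise = cmp$pairwise)
  message(sprintf("%-15s H = %6.2f (df %d), p = %.4g; %d/%d pairs significant",
                  nm, cmp$global$statistic, cmp$global$df, cmp$global$p_value,
                  sum(cmp$pairwise$significant),
                  max(nrow(cmp$pairwise), choose(length(unique(m$group)), 2))))
}

counts <- cbind(in_band = ppot$n_in_band,
                out_band = ppot$n_total - ppot$n_in_band)
rownames(counts) <- ppot$catheter
fe <- fisher_exact_test(counts, seed = 20260105)
message(sprintf("Fisher exact on occlusion-test accuracy counts: p = %.4g (%s)",
                fe$p_value, fe$method))
results$ppot_accuracy_counts <- list(table = as.data.frame(counts),
                                     p_value = fe$p_value, method = fe$method)

jsonlite::write_json(results, "results/stats_results.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, dataframe = "rows")
message("wrote results/stats_results.json")
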