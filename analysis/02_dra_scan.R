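#!/usr/bin/env Rscript
# Stage 2: per-gene confounder-adjusted regression of expression on drug
# sensitivity (activity area), BH-FDR at 0.1, then a permutation study of the
# significant-gene count (sensitivity labels shuffled, covariates kept).
# Finishes with subsampling power curves.

library(dranet)

seed <- 20240902L
data_dir <- "results/data"
out <- "results"

expr <- read_expression_matrix(file.path(data_dir, "expression.tsv"))
samples <- read_sample_table(file.path(data_dir, "samples.tsv"))
truth <- read_result_table(file.path(data_dir, "truth_dra.tsv"))

scan <- run_dra_scan(expr, samples, "drugA", alpha = 0.1)
write_result_table(scan, file.path(out, "dra_scan.tsv"),
                   list(seed = seed, alpha = 0.1))
hits <- scan$gene[scan$sign_class != "nonsignificant"]
message(length(hits), " DRA genes (",
        sum(scan$sign_class == "positive"), " positive, ",
        sum(scan$sign_class == "negative"), " negative); recovery of planted: ",
        round(100 * mean(truth$gene %in% hits), 1), "%, FDP ",
        round(100 * mean(!(hits %in% truth$gene)), 1), "%")

pn <- permutation_null(expr, samples, "drugA", n_perm = 100, alpha = 0.1,
                       seed = seed)
write_result_table(
  data.frame(observed_count = pn$observed_count, frequency = pn$frequency,
             average_count = pn$average_count, n_perm = pn$n_perm),
  file.path(out, "permutation_null.tsv"), list(seed = seed))
message("permutation null: frequency ", pn$frequency, "/", pn$n_perm,
        ", average significant count ", round(pn$average_count, 2),
        " (observed ", pn$observed_count, ")")

pw <- subsample_power(expr, samples, "drugA",
                      sizes = c(60, 120, 180, 240, 300), reps = 20,
                      seed = seed + 1)
write_result_table(pw, file.path(out, "subsample_power.tsv"),
                   list(seed = seed + 1, reps = 20))
message("power curve: ", paste(sprintf("n=%d:%.0f", pw$size, pw$mean_count),
                               collapse = " "))
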