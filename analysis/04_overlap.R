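#!/usr/bin/env Rscript
# Stage 4: sex-stratified analysis. The scan is re-run separately on male and
# female cell lines and the two p-value rankings are compared by one-tailed
# Fisher tests on their top-k prefixes (k = 100, 200, ...), the same sweep
# used to compare demographic strata.

library(dranet)

seed <- 20240904L
data_dir <- "results/data"
out <- "results"

expr <- read_expression_matrix(file.path(data_dir, "expression.tsv"))
samples <- read_sample_table(file.path(data_dir, "samples.tsv"))

strata <- split(samples, samples$sex)
rankings <- lapply(strata, function(s) {
  sc <- run_dra_scan(expr, droplevels(s), "drugA", alpha = 0.1)
  sc <- sc[!is.na(sc$p_value), ]
  sc$gene[order(sc$p_value)]
})
universe <- length(intersect(rankings[[1]], rankings[[2]]))

sw <- topk_overlap_sweep(rankings$male, rankings$female,
                         ks = seq(100, 1000, by = 100),
                         universe_size = universe)
write_result_table(sw, file.path(out, "sex_overlap_sweep.tsv"),
                   list(seed = seed, universe = universe))
message("male n=", nrow(strata$male), ", female n=", nrow(strata$female),
        "; overlap significant (p <= 0.05) at k >= ",
        if (any(sw$significant)) min(sw$k[sw$significant]) else NA)
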