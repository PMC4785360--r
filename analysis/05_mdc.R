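#!/usr/bin/env Rscript
# Stage 5: modular differential connectivity. Modules (>= 30 measured genes)
# are scored by the ratio of mean absolute pairwise correlation in resistant
# vs sensitive lines, with a one-sided 50-permutation FDR; DRA genes are also
# tested for over-representation in the modules.

library(dranet)

seed <- 20240905L
data_dir <- "results/data"
out <- "results"

expr <- read_expression_matrix(file.path(data_dir, "expression.tsv"))
samples <- read_sample_table(file.path(data_dir, "samples.tsv"))
collection <- read_gene_sets(file.path(data_dir, "modules.gmt"))
scan <- read_result_table(file.path(out, "dra_scan.tsv"))

classes <- trichotomize(drug_sensitivity(samples, "drugA"), k = 0.8)
filtered <- filter_modules(collection, rownames(expr), min_size = 30)
mdc_tab <- mdc_scan(expr, classes, filtered, n_perm = 50, seed = seed)
write_result_table(mdc_tab, file.path(out, "mdc.tsv"),
                   list(seed = seed, n_perm = 50, min_size = 30,
                        connectivity = "mean |pearson r|"))
message(paste(sprintf("%s: MDC %.2f (%s, fdr %.2f)", mdc_tab$module,
                      mdc_tab$mdc, mdc_tab$direction, mdc_tab$fdr),
              collapse = "; "))

dra <- scan$gene[scan$sign_class != "nonsignificant"]
enr <- gene_set_enrichment(dra, filtered, universe = rownames(expr))
write_result_table(enr, file.path(out, "dra_module_enrichment.tsv"),
                   list(seed = seed))
message(sum(enr$significant), " module(s) enriched for DRA genes at BH <= 0.05")
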