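#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cell-line panel the downstream analyses run
# on: 2,000 background genes (200 with planted sensitivity associations at
# marginal |r| ~ 0.4) x 300 cell lines, two 40-gene co-expression modules
# (one gaining connectivity in resistant lines, one null), and a 300-node
# protein-interaction network with one planted hub driver. All files land in
# results/data/ in the same formats the loaders read.

library(dranet)

seed <- 20240901L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- simulate_panel(sim_config(n_samples = 300, n_genes = 2000,
                                   n_dra = 200, seed = seed))
classes <- trichotomize(drug_sensitivity(panel$samples, "drugA"), k = 0.8)
mods <- simulate_differential_modules(
  panel,
  data.frame(name = c("mod_gain", "mod_null"), size = c(40, 40),
             rho_s = c(0.2, 0.4), rho_r = c(0.7, 0.4)),
  classes = classes, seed = seed + 1)

set.seed(seed + 2)
net_module <- sprintf("N%04d", sort(sample(300, 30)))
net <- simulate_network(300, 1, list(net_module = net_module), seed = seed + 3)

write_expression_matrix(mods$expr, file.path(out, "expression.tsv"))
write_sample_table(panel$samples, file.path(out, "samples.tsv"))
write_gene_sets(mods$collection, file.path(out, "modules.gmt"))
write_network_edges(net$network, file.path(out, "network.tsv"))
write_result_table(panel$truth, file.path(out, "truth_dra.tsv"),
                   list(seed = seed))
write_result_table(mods$truth, file.path(out, "truth_modules.tsv"),
                   list(seed = seed))
write_result_table(net$truth, file.path(out, "truth_network.tsv"),
                   list(seed = seed, net_module = net_module))

message("panel: ", nrow(mods$expr), " genes x ", nrow(panel$samples),
        " cell lines; ", nrow(panel$truth), " planted DRA genes; ",
        "network: ", igraph::vcount(net$network), " nodes, hub ",
        net$truth$hub[1], " wired to ", net$truth$n_wired[1], "/30 module genes")
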