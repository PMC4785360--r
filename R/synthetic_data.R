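#' Synthetic cell-line panel generation
#'
#' Generates panels with the statistical structure the analyses assume:
#' expression produced by the same linear model the regression fits (planted
#' sensitivity effects plus covariate confounding and Gaussian noise),
#' equicorrelated differentially connected modules, and networks with planted
#' hub drivers — together with ground-truth tables for recovery testing.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate a downsized cancer cell-line panel: ~300 lines, activity
#' areas on the 0-7.8 scale drawn from a right-skewed Beta(2,5), age from
#' N(53, 10) truncated at 18, balanced sexes, and uniform categorical batch /
#' cancer / tissue labels.
#'
#' @param n_samples,n_genes panel dimensions.
#' @param n_dra number of planted drug-response-associated genes.
#' @param effect_size sensitivity coefficient gamma for planted genes; the
#'   default targets a marginal |correlation| of about 0.4 (see
#'   [effect_for_correlation()]). Signs alternate positive/negative.
#' @param noise_sd residual standard deviation.
#' @param covariate_sd standard deviation of the per-gene covariate
#'   coefficients (age, sex, batch, cancer, tissue, genotype PCs); 0 disables
#'   confounding.
#' @param n_batch,n_cancer,n_tissue factor level counts.
#' @param sens_range activity-area range, default `c(0, 7.8)`.
#' @param sens_shape Beta shape parameters of the scaled sensitivity draw.
#' @param seed master RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 2000L, n_dra = 50L,
                       effect_size = NULL, noise_sd = 1,
                       covariate_sd = 0.3,
                       n_batch = 4L, n_cancer = 5L, n_tissue = 6L,
                       sens_range = c(0, 7.8), sens_shape = c(2, 5),
                       seed = 1L) {
  if (n_samples < 1L || n_genes < 1L) stop("counts must be positive")
  if (n_dra > n_genes) stop("n_dra cannot exceed n_genes")
  if (diff(sens_range) <= 0) stop("sens_range bounds must be ordered")
  if (is.null(effect_size))
    effect_size <- effect_for_correlation(
      0.4, sens_sd = scaled_beta_sd(sens_shape, sens_range),
      noise_sd = noise_sd)
  structure(as.list(environment()), class = "sim_config")
}

scaled_beta_sd <- function(shape, range) {
  a <- shape[1]; b <- shape[2]
  sqrt(a * b / ((a + b)^2 * (a + b + 1))) * diff(range)
}

#' Effect size achieving a target marginal correlation
#'
#' For y = gamma * s + noise, |cor(y, s)| = r requires
#' gamma = r/sqrt(1-r^2) * noise_sd / sens_sd.
#'
#' @param r target absolute Pearson correlation.
#' @param sens_sd standard deviation of the sensitivity values.
#' @param noise_sd residual standard deviation.
#' @return gamma.
#' @export
effect_for_correlation <- function(r, sens_sd, noise_sd = 1) {
  r / sqrt(1 - r^2) * noise_sd / sens_sd
}

# Seed-stream splitting: each stage of a simulation or pipeline derives its
# own 32-bit seed from the master seed and a stage name, so stages are
# independently reproducible.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  x
}

#' Simulate a cell-line panel with planted DRA genes
#'
#' Expression is generated exactly by the regression model: intercept +
#' gamma * sensitivity for the planted genes + covariate terms (per-gene
#' coefficients drawn N(0, covariate_sd)) + N(0, noise_sd) noise. Activity
#' areas are drawn from the scaled Beta and always lie within `sens_range`.
#'
#' @param config a [sim_config()].
#' @param drug drug name used for the sensitivity column, default `"drugA"`.
#' @return list: `expr` (genes x samples matrix), `samples` (sample table),
#'   `truth` (data.frame `gene`, `gamma`, `sign` for the planted genes).
#' @export
simulate_panel <- function(config, drug = "drugA") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  G <- config$n_genes
  set.seed(derive_seed(config$seed, "panel"))
  sens <- config$sens_range[1] +
    diff(config$sens_range) * stats::rbeta(n, config$sens_shape[1],
                                           config$sens_shape[2])
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    age = round(rtruncnorm_min(n, 53, 10, 18), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    batch = sample(paste0("b", seq_len(config$n_batch)), n, replace = TRUE),
    cancer = sample(paste0("c", seq_len(config$n_cancer)), n, replace = TRUE),
    tissue = sample(paste0("t", seq_len(config$n_tissue)), n, replace = TRUE),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    stringsAsFactors = FALSE)
  samples[[paste0("sens_", drug)]] <- sens
  samples <- validate_sample_table(samples)

  genes <- sprintf("G%05d", seq_len(G))
  dra_idx <- if (config$n_dra > 0L) seq_len(config$n_dra) else integer()
  gamma <- numeric(G)
  if (length(dra_idx))
    gamma[dra_idx] <- config$effect_size *
      rep_len(c(1, -1), length(dra_idx))

  # covariate design shared by all genes; per-gene coefficients
  covars <- stats::model.matrix(
    ~ age + sex + batch + cancer + tissue + pc1 + pc2 + pc3,
    data = samples)[, -1L, drop = FALSE]
  covars <- scale(covars)  # unit-scale so covariate_sd is comparable across terms
  B <- matrix(stats::rnorm(G * ncol(covars), 0, config$covariate_sd),
              nrow = G)
  expr <- matrix(stats::rnorm(G * n, 0, config$noise_sd), nrow = G,
                 dimnames = list(genes, samples$sample))
  expr <- expr + outer(gamma, sens) + B %*% t(covars) + 5  # baseline intercept
  truth <- data.frame(gene = genes[dra_idx], gamma = gamma[dra_idx],
                      sign = ifelse(gamma[dra_idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  list(expr = validate_expression_matrix(expr), samples = samples,
       truth = truth)
}

# Equicorrelated Gaussian block: m genes x length(idx) samples with pairwise
# correlation rho (must lie in (-1/(m-1), 1) for positive definiteness).
equicorrelated_block <- function(m, n, rho) {
  if (rho <= -1 / (m - 1) || rho >= 1)
    stop("rho must lie in (-1/(m-1), 1) for a module of size ", m)
  sigma <- matrix(rho, m, m); diag(sigma) <- 1
  L <- chol(sigma)
  t(L) %*% matrix(stats::rnorm(m * n), m, n)
}

#' Simulate differentially connected modules
#'
#' Appends module gene blocks to a panel: within each module, expression of
#' the sensitive-group samples is drawn from an equicorrelated Gaussian with
#' pairwise correlation `rho_s`, and of the resistant-group samples with
#' `rho_r` (indeterminate samples get independent noise — they are excluded
#' from the connectivity analysis anyway). Background genes stay independent,
#' so the true MDC of a module is monotone in `rho_r / rho_s`.
#'
#' @param panel result of [simulate_panel()] (or any list with `expr`,
#'   `samples`).
#' @param classes sample classes from [trichotomize()], or a named character
#'   vector; if `NULL`, derived from the panel's first drug at `k = 0.8`.
#' @param module_specs data.frame with columns `name`, `size`, `rho_s`,
#'   `rho_r`; modules of size < 30 are emitted but flagged `below_filter`.
#' @param seed RNG seed.
#' @return list: `expr` (panel matrix with module genes appended),
#'   `collection` (named list of module gene sets), `truth` (the spec table
#'   with a `below_filter` flag), `classes`.
#' @export
simulate_differential_modules <- function(panel, module_specs, classes = NULL,
                                          seed = 1L) {
  samples <- panel$samples
  if (is.null(classes)) {
    drug <- drug_names(samples)[1L]
    classes <- trichotomize(drug_sensitivity(samples, drug))
  }
  cl <- if (is.list(classes)) classes$classes else classes
  set.seed(derive_seed(seed, "modules"))
  n <- nrow(samples)
  ids <- samples$sample
  blocks <- list()
  collection <- list()
  for (i in seq_len(nrow(module_specs))) {
    m <- module_specs$size[i]
    nm <- module_specs$name[i]
    genes <- sprintf("%s_g%03d", nm, seq_len(m))
    block <- matrix(0, m, n, dimnames = list(genes, ids))
    for (grp in c("sensitive", "resistant", "indeterminate")) {
      in_grp <- ids[cl[ids] == grp]
      if (!length(in_grp)) next
      rho <- switch(grp, sensitive = module_specs$rho_s[i],
                    resistant = module_specs$rho_r[i], indeterminate = 0)
      block[, in_grp] <- if (rho == 0)
        matrix(stats::rnorm(m * length(in_grp)), m) else
        equicorrelated_block(m, length(in_grp), rho)
    }
    blocks[[nm]] <- block
    collection[[nm]] <- genes
  }
  truth <- cbind(module_specs,
                 below_filter = module_specs$size < 30L)
  list(expr = rbind(panel$expr, do.call(rbind, blocks)),
       collection = collection, truth = truth, classes = classes)
}

#' Simulate a PPI network with planted hub drivers
#'
#' A preferential-attachment background graph plus `n_hubs` planted hubs,
#' each wired directly to at least 80% (default 85%) of one module's genes —
#' so every planted hub has the module inside its 1-hop, hence 2-hop,
#' neighborhood.
#'
#' @param n_nodes number of background nodes.
#' @param n_hubs number of planted hubs (must be < `n_nodes`).
#' @param module_assignment named list: hub-module name -> character vector of
#'   member node names; members must be among the `n_nodes` background nodes.
#' @param attachment_degree edges each new background node brings, default 2.
#' @param hub_coverage fraction of a module wired to its hub, default 0.85.
#' @param seed RNG seed.
#' @return list: `network` (igraph; background nodes `N0001`... and hubs
#'   `HUB1`...), `truth` (data.frame `hub`, `module`, `n_wired`).
#' @export
simulate_network <- function(n_nodes, n_hubs, module_assignment,
                             attachment_degree = 2L, hub_coverage = 0.85,
                             seed = 1L) {
  if (n_hubs >= n_nodes) stop("n_hubs must be smaller than n_nodes")
  if (length(module_assignment) != n_hubs)
    stop("need one module assignment per hub")
  if (any(lengths(module_assignment) > n_nodes))
    stop("module larger than n_nodes")
  set.seed(derive_seed(seed, "network"))
  g <- igraph::sample_pa(n_nodes, m = attachment_degree, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n_nodes))
  hubs <- sprintf("HUB%d", seq_len(n_hubs))
  g <- igraph::add_vertices(g, n_hubs, name = hubs)
  truth <- data.frame(hub = hubs, module = names(module_assignment),
                      n_wired = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n_hubs)) {
    members <- module_assignment[[i]]
    if (!all(members %in% igraph::V(g)$name))
      stop("module members must be existing nodes")
    k <- ceiling(hub_coverage * length(members))
    wired <- sample(members, k)
    g <- igraph::add_edges(g, rbind(hubs[i], wired))
    truth$n_wired[i] <- k
  }
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- 1
  list(network = g, truth = truth)
}
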