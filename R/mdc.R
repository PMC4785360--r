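#' Modular differential connectivity
#'
#' For a gene-set module, connectivity within a sample group is the mean over
#' all unordered gene pairs of co-expression strength (absolute Pearson
#' correlation, optionally raised to a soft-threshold power). MDC is the ratio
#'   MDC = connectivity(resistant) / connectivity(sensitive);
#' values above 1 mean the module gains connectivity moving from the sensitive
#' to the resistant state, values below 1 mean it loses connectivity. MDC
#' ranges over (0, infinity). Significance comes from permuting sample group
#' labels: when the observed MDC exceeds 1 the FDR is the fraction of
#' permutations with a larger MDC, when below 1 the fraction with a smaller
#' one.
#'
#' @name mdc
NULL

#' Restrict a module collection to measured genes and a minimum size
#'
#' Each set is intersected with the measured genes; sets with fewer than
#' `min_size` members after intersection are dropped (a 30-gene set is kept at
#' the default: only sets with less than 30 are removed).
#'
#' @param collection named list of gene sets.
#' @param measured_genes character vector of genes present in the expression
#'   data.
#' @param min_size minimum post-intersection size, default 30.
#' @return filtered collection (named list).
#' @export
filter_modules <- function(collection, measured_genes, min_size = 30L) {
  sets <- lapply(collection, function(s) intersect(unique(s), measured_genes))
  sets[lengths(sets) >= min_size]
}

#' Mean pairwise connectivity of a module within one sample group
#'
#' @param expr_group expression matrix (genes in rows) restricted to the
#'   group's samples.
#' @param module_genes character vector of module members (must be rows of
#'   `expr_group`; zero-variance genes are excluded with a warning).
#' @param power soft-threshold exponent applied to |correlation|, default 1.
#' @return mean over unordered gene pairs of |Pearson r|^power.
#' @export
module_connectivity <- function(expr_group, module_genes, power = 1) {
  if (ncol(expr_group) < 3L) stop("need at least 3 samples in the group")
  module_genes <- intersect(unique(module_genes), rownames(expr_group))
  sub <- expr_group[module_genes, , drop = FALSE]
  v <- apply(sub, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from connectivity")
    sub <- sub[v > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 usable module genes")
  cm <- abs(stats::cor(t(sub)))^power
  mean(cm[upper.tri(cm)])
}

# Split samples into the resistant / sensitive groups of a trichotomy.
# `classes` is a trichotomize() result or a named character vector;
# indeterminate samples are eliminated from analysis.
split_response_groups <- function(expr, classes) {
  cl <- if (is.list(classes)) classes$classes else classes
  cl <- cl[names(cl) %in% colnames(expr)]
  list(resistant = names(cl)[cl == "resistant"],
       sensitive = names(cl)[cl == "sensitive"])
}

#' Compute MDC for one module
#'
#' @param expr expression matrix, genes in rows, all samples.
#' @param classes [trichotomize()] result (or named class vector); the
#'   indeterminate samples are excluded.
#' @param module_genes module member genes.
#' @param power soft-threshold exponent, default 1.
#' @return list: `mdc` (ratio, `Inf` with `infinite = TRUE` when the sensitive
#'   connectivity is 0), `connectivity_resistant`, `connectivity_sensitive`,
#'   `n_genes`, group sizes.
#' @export
compute_mdc <- function(expr, classes, module_genes, power = 1) {
  grp <- split_response_groups(expr, classes)
  if (length(grp$resistant) < 3L || length(grp$sensitive) < 3L)
    stop("both resistant and sensitive groups need at least 3 samples")
  kr <- module_connectivity(expr[, grp$resistant, drop = FALSE], module_genes, power)
  ks <- module_connectivity(expr[, grp$sensitive, drop = FALSE], module_genes, power)
  mdc <- if (ks == 0) Inf else kr / ks
  list(mdc = mdc, connectivity_resistant = kr, connectivity_sensitive = ks,
       n_genes = length(intersect(module_genes, rownames(expr))),
       n_resistant = length(grp$resistant), n_sensitive = length(grp$sensitive),
       infinite = !is.finite(mdc))
}

#' MDC with one-sided permutation FDR
#'
#' Group labels are permuted across the union of resistant and sensitive
#' samples, preserving the group sizes. The count is one-sided in the observed
#' direction: permutations with larger MDC when the observed value exceeds 1,
#' smaller when below 1; `fdr = count / n_perm`. An observed MDC of exactly 1
#' is direction-`neutral` and reported with fdr 1. With the default 50
#' permutations the smallest nonzero FDR is 0.02.
#'
#' @inheritParams compute_mdc
#' @param n_perm number of permutations, default 50.
#' @param seed RNG seed.
#' @param module_name optional label for the result row.
#' @return one-row data.frame: `module`, `n_genes`, `mdc`, `fdr`, `direction`
#'   in \{gain, loss, neutral\}.
#' @export
mdc_fdr <- function(expr, classes, module_genes, n_perm = 50L, seed = 1L,
                    power = 1, module_name = "module") {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  obs <- compute_mdc(expr, classes, module_genes, power)
  grp <- split_response_groups(expr, classes)
  pool <- c(grp$resistant, grp$sensitive)
  n_res <- length(grp$resistant)
  set.seed(seed)
  perm_mdc <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(pool)
    cl <- stats::setNames(rep("sensitive", length(pool)), perm)
    cl[seq_len(n_res)] <- "resistant"
    compute_mdc(expr, cl, module_genes, power)$mdc
  }, numeric(1))
  if (obs$mdc > 1) {
    direction <- "gain"; fdr <- sum(perm_mdc > obs$mdc) / n_perm
  } else if (obs$mdc < 1) {
    direction <- "loss"; fdr <- sum(perm_mdc < obs$mdc) / n_perm
  } else {
    direction <- "neutral"; fdr <- 1
  }
  data.frame(module = module_name, n_genes = obs$n_genes, mdc = obs$mdc,
             fdr = fdr, direction = direction, stringsAsFactors = FALSE)
}

#' Run MDC with FDR over a whole module collection
#'
#' @inheritParams mdc_fdr
#' @param collection named list of modules (already size-filtered, see
#'   [filter_modules()]).
#' @return data.frame with one [mdc_fdr()] row per module.
#' @export
mdc_scan <- function(expr, classes, collection, n_perm = 50L, seed = 1L,
                     power = 1) {
  rows <- lapply(seq_along(collection), function(i)
    mdc_fdr(expr, classes, collection[[i]], n_perm = n_perm,
            seed = seed + i, power = power, module_name = names(collection)[i]))
  do.call(rbind, rows)
}

# Within-drug ranking key: FDR-significant modules first, ordered by
# |log MDC| descending (most extreme differential connectivity), then the
# rest by ascending fdr and descending |log MDC|.
rank_within_drug <- function(tab, sig_threshold = 0.05) {
  extremity <- abs(log(tab$mdc))
  extremity[!is.finite(extremity)] <- max(extremity[is.finite(extremity)], 0) + 1
  sig <- tab$fdr <= sig_threshold
  ord <- order(!sig, ifelse(sig, -extremity, tab$fdr),
               -extremity)
  r <- integer(nrow(tab))
  r[ord] <- seq_len(nrow(tab))
  stats::setNames(r, tab$module)
}

#' Order modules by rank sum across drugs
#'
#' Each drug's modules are ranked (significant modules first, by extremity of
#' their MDC, see Details of [mdc]); modules are then ordered by the ascending
#' sum of their per-drug ranks.
#'
#' @param per_drug_tables named list of [mdc_scan()] tables over the same
#'   module collection.
#' @param sig_threshold FDR threshold used by the within-drug ranking.
#' @return data.frame: `module`, `rank_sum`, one rank column per drug, ordered
#'   by ascending rank sum.
#' @export
rank_modules_across_drugs <- function(per_drug_tables, sig_threshold = 0.05) {
  if (length(per_drug_tables) < 1L) stop("need at least one drug table")
  mods <- per_drug_tables[[1L]]$module
  ranks <- vapply(per_drug_tables, function(tab) {
    if (!setequal(tab$module, mods))
      stop("all drugs must share the same module collection")
    rank_within_drug(tab, sig_threshold)[mods]
  }, numeric(length(mods)))
  ranks <- matrix(ranks, nrow = length(mods),
                  dimnames = list(mods, names(per_drug_tables)))
  out <- data.frame(module = mods, rank_sum = rowSums(ranks), ranks,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[order(out$rank_sum, out$module), , drop = FALSE]
}
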