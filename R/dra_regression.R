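#' Per-gene drug-response association by confounder-adjusted regression
#'
#' The model for gene j is
#'   Y_ij = beta_j + gamma_j * Sensitivity_i + lambda_j * Age_i
#'          + mu_j * Sex_i + theta_j * Batch_i + kappa_j * Cancer_i
#'          + phi_j * Tissue_i + sum_k delta_jk * GenotypePC_ik + eps_ij
#' fitted by ordinary least squares; the gene is drug-response-associated when
#' the two-sided t-test of gamma_j = 0 survives Benjamini-Hochberg control.
#'
#' @name dra_regression
NULL

# Design matrix for one drug: complete cases on sensitivity and covariates,
# factors dummy-coded against the lexicographically first level. Single-level
# factors are dropped (they are constants). Returns the matrix, the retained
# sample ids and the column index of the sensitivity coefficient.
build_design <- function(samples, drug) {
  sens <- drug_sensitivity(samples, drug)
  covars <- samples[, c("age", "sex", "batch", "cancer", "tissue",
                        "pc1", "pc2", "pc3")]
  ok <- !is.na(sens) & stats::complete.cases(covars)
  if (!any(ok)) stop("no usable samples for drug '", drug, "'")
  covars <- droplevels(covars[ok, , drop = FALSE])
  keep <- vapply(covars, function(v) !is.factor(v) || nlevels(v) > 1L, logical(1))
  covars <- covars[, keep, drop = FALSE]
  df <- cbind(data.frame(sensitivity = sens[ok]), covars)
  X <- stats::model.matrix(~ ., data = df)
  list(X = X, sample_ids = samples$sample[ok],
       sensitivity = unname(sens[ok]),
       gamma_col = match("sensitivity", colnames(X)))
}

# OLS of many response vectors on a shared design. Y is genes x samples
# (samples aligned to rows of X). Returns gamma_hat, its two-sided t-test p,
# and degeneracy flags, vectorized across genes via one QR decomposition.
ols_gamma <- function(X, Y, gamma_col) {
  n <- nrow(X)
  fit <- stats::lm.fit(X, t(Y))
  # sensitivity is unidentified when dropping its column leaves the rank
  # unchanged (e.g. a covariate perfectly aliased with sensitivity)
  if (qr(X[, -gamma_col, drop = FALSE])$rank == fit$rank) {
    G <- nrow(Y)
    return(list(gamma_hat = rep(NA_real_, G), p_value = rep(NA_real_, G),
                degenerate = rep(FALSE, G), aliased = rep(TRUE, G),
                df_residual = n - fit$rank))
  }
  r <- fit$rank
  df_res <- n - r
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L,
                                           dimnames = list(names(coefs), NULL))
  gamma_hat <- coefs[gamma_col, ]
  aliased <- is.na(gamma_hat)
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  # unscaled variance of gamma_hat from the pivoted R factor
  piv <- fit$qr$pivot
  R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv_diag <- diag(chol2inv(R))  # order: piv[1:r]
  pos <- match(gamma_col, piv[seq_len(r)])
  p <- rep(NA_real_, ncol(res))
  degenerate <- rep(FALSE, ncol(res))
  if (!is.na(pos) && df_res > 0L) {
    sigma2 <- rss / df_res
    tiny <- rss <= 1e-12 * pmax(colSums(t(Y)^2), 1)
    se <- sqrt(sigma2 * XtXinv_diag[pos])
    tstat <- gamma_hat / se
    p <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
    p[tiny] <- 0
    degenerate <- tiny
  }
  p[aliased] <- NA_real_
  list(gamma_hat = unname(gamma_hat), p_value = unname(p),
       degenerate = unname(degenerate), aliased = unname(aliased),
       df_residual = df_res)
}

#' Fit the association model for a single gene
#'
#' @param y numeric expression vector for one gene, one value per sample.
#' @param sensitivity numeric drug-sensitivity (activity area) vector.
#' @param covariates data.frame of confounders aligned with `y` (any mix of
#'   numeric and factor columns); may be omitted for an unadjusted fit.
#' @return list with `gamma_hat`, `p_value`, and flags `degenerate` (residual
#'   variance numerically zero; p reported as 0) and `aliased` (sensitivity
#'   coefficient not estimable; p is `NA`).
#' @export
fit_gene_model <- function(y, sensitivity, covariates = NULL) {
  if (length(y) != length(sensitivity))
    stop("y and sensitivity lengths differ")
  df <- data.frame(sensitivity = sensitivity)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates <- droplevels(covariates)
    keep <- vapply(covariates, function(v) {
      if (is.character(v)) v <- factor(v)
      !is.factor(v) || nlevels(v) > 1L
    }, logical(1))
    df <- cbind(df, covariates[, keep, drop = FALSE])
  }
  ok <- stats::complete.cases(df) & !is.na(y)
  df <- droplevels(df[ok, , drop = FALSE])
  y <- y[ok]
  X <- stats::model.matrix(~ ., data = df)
  if (nrow(X) < ncol(X) + 2L)
    stop("need at least 2 more complete samples than design columns")
  out <- ols_gamma(X, matrix(y, nrow = 1L), match("sensitivity", colnames(X)))
  list(gamma_hat = out$gamma_hat[1L], p_value = out$p_value[1L],
       degenerate = out$degenerate[1L], aliased = out$aliased[1L])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, capped at 1, monotone in the sorted order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Scan every gene for association with one drug
#'
#' Samples enter the scan only if sensitivity and all covariates are present
#' (per-drug sample counts therefore vary). Genes with zero expression
#' variance are skipped and flagged rather than tested.
#'
#' @param expr expression matrix, genes in rows.
#' @param samples sample table (see [read_sample_table()]).
#' @param drug drug name.
#' @param alpha FDR significance threshold, default 0.1.
#' @return data.frame with one row per gene: `gene`, `gamma_hat`, `p_value`,
#'   `fdr`, `sign_class` in \{positive, negative, nonsignificant\}, and a
#'   `flag` column (`""`, `"zero_variance"`, `"degenerate"`, `"aliased"`).
#'   Attributes: `n_samples`, `drug`, `alpha`.
#' @export
run_dra_scan <- function(expr, samples, drug, alpha = 0.1) {
  d <- build_design(samples, drug)
  common <- intersect(colnames(expr), d$sample_ids)
  if (length(common) == 0L)
    stop("no overlapping samples between expression matrix and sample table")
  idx <- match(common, d$sample_ids)
  X <- d$X[idx, , drop = FALSE]
  Y <- expr[, common, drop = FALSE]
  v <- apply(Y, 1L, stats::var)
  testable <- v > 0
  res <- data.frame(gene = rownames(expr),
                    gamma_hat = NA_real_, p_value = NA_real_, fdr = NA_real_,
                    sign_class = "nonsignificant", flag = "",
                    stringsAsFactors = FALSE)
  res$flag[!testable] <- "zero_variance"
  if (any(testable)) {
    fit <- ols_gamma(X, Y[testable, , drop = FALSE],
                     match("sensitivity", colnames(X)))
    res$gamma_hat[testable] <- fit$gamma_hat
    res$p_value[testable] <- fit$p_value
    res$flag[testable][fit$degenerate] <- "degenerate"
    res$flag[testable][fit$aliased] <- "aliased"
    usable <- testable & !is.na(res$p_value)
    res$fdr[usable] <- adjust_bh(res$p_value[usable])
    sig <- usable & res$fdr <= alpha
    res$sign_class[sig & res$gamma_hat > 0] <- "positive"
    res$sign_class[sig & res$gamma_hat < 0] <- "negative"
  }
  attr(res, "n_samples") <- length(common)
  attr(res, "drug") <- drug
  attr(res, "alpha") <- alpha
  res
}

#' Count significant genes in a scan result
#' @param scan result of [run_dra_scan()].
#' @return integer count of genes classed positive or negative.
#' @export
count_significant <- function(scan) {
  sum(scan$sign_class != "nonsignificant")
}

#' Permutation null for the number of significant genes
#'
#' Permutes the sensitivity values across the drug's usable samples (each
#' sample keeps its own covariates), repeats the full scan, and summarizes how
#' the observed significant-gene count compares with the permuted counts.
#'
#' @param expr,samples,drug,alpha as in [run_dra_scan()].
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @param tie `">="` counts permutations with at least the observed count
#'   (conservative default); `">"` counts strictly more.
#' @return list: `observed_count`, `frequency` (permutations meeting the tie
#'   rule), `average_count`, `n_perm`, `counts` (per-permutation vector).
#' @export
permutation_null <- function(expr, samples, drug, n_perm = 1000, alpha = 0.1,
                             seed = 1L, tie = c(">=", ">")) {
  tie <- match.arg(tie)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  observed <- count_significant(run_dra_scan(expr, samples, drug, alpha))
  col <- paste0("sens_", drug)
  usable <- which(!is.na(samples[[col]]))
  counts <- integer(n_perm)
  set.seed(seed)
  perm_samples <- samples
  for (b in seq_len(n_perm)) {
    perm_samples[[col]][usable] <- samples[[col]][sample(usable)]
    counts[b] <- count_significant(run_dra_scan(expr, perm_samples, drug, alpha))
  }
  freq <- if (tie == ">=") sum(counts >= observed) else sum(counts > observed)
  list(observed_count = observed, frequency = freq,
       average_count = mean(counts), n_perm = n_perm, counts = counts)
}

#' Detection power as a function of sample size
#'
#' For each requested size, draws `reps` random subsamples without
#' replacement, re-runs the scan, and reports the mean significant-gene count.
#'
#' @param expr,samples,drug,alpha as in [run_dra_scan()].
#' @param sizes integer vector of subsample sizes.
#' @param reps subsamples per size, default 100.
#' @param seed RNG seed.
#' @return data.frame with columns `size`, `mean_count`.
#' @export
subsample_power <- function(expr, samples, drug, sizes, reps = 100,
                            alpha = 0.1, seed = 1L) {
  col <- paste0("sens_", drug)
  usable <- which(!is.na(samples[[col]]))
  if (any(sizes > length(usable)))
    stop("requested subsample size exceeds available samples (",
         length(usable), ")")
  set.seed(seed)
  mean_count <- vapply(sizes, function(sz) {
    mean(vapply(seq_len(reps), function(r) {
      take <- usable[sample(length(usable), sz)]
      sub <- samples[take, , drop = FALSE]
      count_significant(run_dra_scan(expr, sub, drug, alpha))
    }, numeric(1)))
  }, numeric(1))
  data.frame(size = sizes, mean_count = mean_count)
}
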