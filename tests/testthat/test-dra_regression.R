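test_that("single-gene fits match the normal-equations oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    cov <- data.frame(f = factor(sample(c("a", "b"), n, TRUE)))
    while (nlevels(droplevels(cov$f)) < 2) {
      cov$f <- factor(sample(c("a", "b"), n, TRUE))
    }
    s <- rnorm(n)
    y <- 1 + 0.3 * s + rnorm(n)
    fit <- fit_gene_model(y, s, cov)
    X <- model.matrix(~ s + f, data = cov)
    orc <- ols_oracle(X, y, 2)
    expect_equal(fit$gamma_hat, orc$beta, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("noiseless and degenerate designs are flagged, not crashed", {
  s <- c(1, 2, 3, 4, 5, 6)
  fit <- fit_gene_model(2 * s + 3, s, data.frame(c = rep(1, 6)))
  expect_equal(fit$gamma_hat, 2, tolerance = 1e-10)
  expect_true(fit$degenerate)
  expect_equal(fit$p_value, 0)

  # sensitivity aliased with a covariate: flagged with undefined p
  fit2 <- fit_gene_model(rnorm(6), s, data.frame(x = 2 * s))
  expect_true(fit2$aliased || is.na(fit2$p_value))
})

test_that("p-values are uniform under the null", {
  set.seed(5)
  n <- 100
  s <- runif(n, 0, 7.8)
  cov <- data.frame(age = rnorm(n, 53, 10),
                    sex = factor(sample(c("m", "f"), n, TRUE)))
  p <- vapply(1:1000, function(i) {
    fit_gene_model(rnorm(n), s, cov)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("adjust_bh equals the step-up definition and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  expect_error(adjust_bh(c(0.5, NA)), "0, 1")
})

test_that("the scan recovers planted genes and classifies signs", {
  p <- simulate_panel(sim_config(n_samples = 300, n_genes = 500, n_dra = 50,
                                 seed = 8))
  scan <- run_dra_scan(p$expr, p$samples, "drugA", alpha = 0.1)
  hits <- scan$gene[scan$sign_class != "nonsignificant"]
  expect_gte(mean(p$truth$gene %in% hits), 0.8)

  # sign classes agree with the planted direction and partition the total
  sig <- scan[scan$sign_class != "nonsignificant", ]
  expect_true(all(sig$gamma_hat[sig$sign_class == "positive"] > 0))
  expect_true(all(sig$gamma_hat[sig$sign_class == "negative"] < 0))
  expect_equal(sum(sig$sign_class == "positive") +
                 sum(sig$sign_class == "negative"), nrow(sig))

  pos_truth <- p$truth$gene[p$truth$sign == "positive"]
  found_pos <- intersect(pos_truth, sig$gene)
  expect_true(all(sig$sign_class[match(found_pos, sig$gene)] == "positive"))
})

test_that("scan handles zero-variance genes, disjoint samples, and shuffles", {
  p <- simulate_panel(sim_config(n_samples = 60, n_genes = 50, n_dra = 5,
                                 seed = 9))
  expr <- p$expr
  expr["G00050", ] <- 7  # flat gene
  scan <- run_dra_scan(expr, p$samples, "drugA")
  expect_equal(scan$flag[scan$gene == "G00050"], "zero_variance")
  expect_true(is.na(scan$fdr[scan$gene == "G00050"]))

  bad <- expr
  colnames(bad) <- paste0("X", seq_len(ncol(bad)))
  expect_error(run_dra_scan(bad, p$samples, "drugA"), "overlap")

  # permuting gene order leaves per-gene results unchanged
  shuf <- expr[sample(nrow(expr)), ]
  s2 <- run_dra_scan(shuf, p$samples, "drugA")
  m <- match(scan$gene, s2$gene)
  expect_equal(scan$gamma_hat, s2$gamma_hat[m])
  expect_equal(scan$fdr, s2$fdr[m])

  # location invariance: shifting a gene's expression only moves the intercept
  shifted <- expr
  shifted["G00001", ] <- shifted["G00001", ] + 100
  s3 <- run_dra_scan(shifted, p$samples, "drugA")
  expect_equal(s3$gamma_hat[1], scan$gamma_hat[1], tolerance = 1e-10)
  expect_equal(s3$p_value[1], scan$p_value[1], tolerance = 1e-10)
})

test_that("a batch-confounded effect vanishes once batch is adjusted", {
  set.seed(77)
  n <- 200
  batch <- rep(c("b1", "b2"), each = n / 2)
  # sensitivity rides on batch; the gene responds to batch only
  sens <- runif(n, 0, 3) + ifelse(batch == "b1", 3, 0)
  y <- ifelse(batch == "b1", 2, 0) + rnorm(n, sd = 0.5)
  no_adjust <- fit_gene_model(y, sens)
  adjusted <- fit_gene_model(y, sens, data.frame(batch = factor(batch)))
  expect_lt(no_adjust$p_value, 1e-6)   # spurious association
  expect_gt(adjusted$p_value, 0.1)     # gone after confounder adjustment
})

test_that("empirical FDR stays controlled on mixture panels", {
  fdp <- power <- numeric(0)
  for (seed in 1:10) {
    p <- simulate_panel(sim_config(n_samples = 300, n_genes = 500, n_dra = 50,
                                   seed = 100 + seed))
    sc <- run_dra_scan(p$expr, p$samples, "drugA", alpha = 0.1)
    hits <- sc$gene[sc$sign_class != "nonsignificant"]
    power <- c(power, mean(p$truth$gene %in% hits))
    fdp <- c(fdp, if (length(hits)) mean(!(hits %in% p$truth$gene)) else 0)
  }
  expect_gte(mean(power), 0.8)
  expect_lte(mean(fdp), 0.2)
})

test_that("permutation null separates signal from noise", {
  planted <- simulate_panel(sim_config(n_samples = 150, n_genes = 200,
                                       n_dra = 30, seed = 41))
  pn <- permutation_null(planted$expr, planted$samples, "drugA",
                         n_perm = 30, seed = 2)
  expect_gt(pn$observed_count, 0)
  expect_equal(pn$frequency, 0)

  nullp <- simulate_panel(sim_config(n_samples = 150, n_genes = 200,
                                     n_dra = 0, seed = 42))
  pn0 <- permutation_null(nullp$expr, nullp$samples, "drugA",
                          n_perm = 30, seed = 2)
  # tie convention: frequency counts permutations at or above the observed
  expect_equal(pn0$frequency, sum(pn0$counts >= pn0$observed_count))
  # observed count 0 means every permutation ties or beats it under ">="
  if (pn0$observed_count == 0) expect_equal(pn0$frequency, pn0$n_perm)

  pn_strict <- permutation_null(nullp$expr, nullp$samples, "drugA",
                                n_perm = 10, seed = 3, tie = ">")
  expect_lte(pn_strict$frequency, pn_strict$n_perm)
  expect_error(permutation_null(nullp$expr, nullp$samples, "drugA",
                                n_perm = 0), "n_perm")

  # determinism under a fixed seed
  pn2 <- permutation_null(planted$expr, planted$samples, "drugA",
                          n_perm = 10, seed = 7)
  pn3 <- permutation_null(planted$expr, planted$samples, "drugA",
                          n_perm = 10, seed = 7)
  expect_identical(pn2$counts, pn3$counts)
})

test_that("subsampling power grows with sample size", {
  p <- simulate_panel(sim_config(n_samples = 200, n_genes = 150, n_dra = 20,
                                 seed = 51))
  full <- count_significant(run_dra_scan(p$expr, p$samples, "drugA"))
  tab1 <- subsample_power(p$expr, p$samples, "drugA", sizes = 200, reps = 1)
  expect_equal(tab1$mean_count, full)  # degenerate subsample = full scan

  tab <- subsample_power(p$expr, p$samples, "drugA",
                         sizes = c(50, 100, 150, 200), reps = 10, seed = 6)
  expect_gt(cor(tab$size, tab$mean_count, method = "spearman"), 0.9)
  expect_error(subsample_power(p$expr, p$samples, "drugA", sizes = 500),
               "exceeds")
})
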