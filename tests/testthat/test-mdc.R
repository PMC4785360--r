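test_that("module filtering applies the post-intersection size rule", {
  measured <- paste0("g", 1:40)
  coll <- list(big = paste0("g", 1:35),            # 35 measured: kept
               partial = paste0("g", c(1:29, 100:105)),  # 29 measured: dropped
               exact = paste0("g", 1:30))          # boundary 30: kept
  out <- filter_modules(coll, measured)
  expect_setequal(names(out), c("big", "exact"))
  expect_length(filter_modules(list(), measured), 0)
})

test_that("connectivity is the mean absolute pairwise correlation", {
  e <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3), g3 = c(2, 4, 6, 8))
  colnames(e) <- paste0("s", 1:4)
  expect_equal(module_connectivity(e, c("g1", "g3")), 1.0)  # r = 1 (y = 2x)
  expect_equal(module_connectivity(e, c("g1", "g2")), 0.6)  # hand-computed r
  dup <- rbind(e, g4 = e["g1", ])
  expect_equal(module_connectivity(dup, c("g1", "g4")), 1.0)
  flat <- rbind(e, g5 = rep(3, 4))
  expect_warning(k <- module_connectivity(flat, c("g1", "g2", "g5")),
                 "zero-variance")
  expect_equal(k, 0.6)
  expect_error(suppressWarnings(
    module_connectivity(flat, c("g1", "g5"))), "usable")
  expect_error(module_connectivity(e[, 1:2], c("g1", "g2")), "3 samples")
})

test_that("MDC matches hand computation, brute force, and its symmetries", {
  e <- rbind(g1 = c(1, 2, 3, 4, 1, 2, 3, 4),
             g2 = c(2, 1, 4, 3, 2, 4, 6, 8))
  colnames(e) <- paste0("s", 1:8)
  cl <- setNames(c(rep("sensitive", 4), rep("resistant", 4)), colnames(e))
  m <- compute_mdc(e, cl, c("g1", "g2"))
  expect_equal(m$mdc, 1 / 0.6, tolerance = 1e-12)

  swap <- ifelse(cl == "sensitive", "resistant", "sensitive")
  names(swap) <- names(cl)
  expect_equal(compute_mdc(e, swap, c("g1", "g2"))$mdc * m$mdc, 1)

  # identical expression in the two groups gives exactly 1
  same <- cbind(e[, 1:4], e[, 1:4])
  colnames(same) <- paste0("s", 1:8)
  expect_equal(compute_mdc(same, cl, c("g1", "g2"))$mdc, 1)

  # brute-force pair loop on random modules; scale invariance; reciprocality
  set.seed(43)
  for (i in 1:20) {
    ng <- sample(3:8, 1)
    ex <- matrix(rnorm(ng * 12), ng, 12,
                 dimnames = list(paste0("g", 1:ng), paste0("s", 1:12)))
    cl2 <- setNames(rep(c("sensitive", "resistant"), each = 6), colnames(ex))
    got <- compute_mdc(ex, cl2, rownames(ex))
    brute <- function(cols) {
      tot <- 0; np <- 0
      for (a in 1:(ng - 1)) for (b in (a + 1):ng) {
        tot <- tot + abs(cor(ex[a, cols], ex[b, cols])); np <- np + 1
      }
      tot / np
    }
    expect_equal(got$mdc, brute(7:12) / brute(1:6), tolerance = 1e-12)

    swap2 <- ifelse(cl2 == "sensitive", "resistant", "sensitive")
    names(swap2) <- names(cl2)
    expect_equal(got$mdc * compute_mdc(ex, swap2, rownames(ex))$mdc, 1)

    scaled <- ex
    scaled[1, ] <- ex[1, ] * runif(1, 0.1, 9)
    expect_equal(compute_mdc(ex, cl2, rownames(ex))$mdc,
                 compute_mdc(scaled, cl2, rownames(ex))$mdc,
                 tolerance = 1e-12)
  }
})

test_that("permutation FDR finds planted differential modules", {
  hits <- vapply(1:20, function(i) {
    p <- simulate_panel(sim_config(n_samples = 260, n_genes = 10, n_dra = 0,
                                   seed = 500 + i))
    cl <- trichotomize(drug_sensitivity(p$samples, "drugA"))
    mo <- simulate_differential_modules(
      p, data.frame(name = "m", size = 40, rho_s = 0.2, rho_r = 0.7),
      classes = cl, seed = 600 + i)
    mdc_fdr(mo$expr, cl, mo$collection$m, n_perm = 50, seed = i)$fdr == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null-module permutation FDR follows the direction-selected tail", {
  # the tail direction is chosen after seeing whether MDC is above or below 1,
  # so under the null P(fdr <= q) is about 2q, uniform within each direction
  p <- simulate_panel(sim_config(n_samples = 200, n_genes = 5, n_dra = 0,
                                 seed = 71))
  cl <- trichotomize(drug_sensitivity(p$samples, "drugA"))
  res <- lapply(1:100, function(i) {
    mo <- simulate_differential_modules(
      p, data.frame(name = "m", size = 30, rho_s = 0.4, rho_r = 0.4),
      classes = cl, seed = 700 + i)
    mdc_fdr(mo$expr, cl, mo$collection$m, n_perm = 50, seed = i)
  })
  fdr <- vapply(res, function(r) r$fdr, numeric(1))
  expect_true(all(fdr %in% seq(0, 1, by = 1 / 50)))
  expect_lt(abs(mean(fdr <= 0.2) - 0.4), 0.12)
  expect_lt(abs(mean(fdr <= 0.5) - 0.9), 0.12)
  dirs <- vapply(res, function(r) r$direction, character(1))
  expect_true(all(dirs %in% c("gain", "loss", "neutral")))
})

test_that("mdc_fdr conventions: neutral boundary, determinism, config errors", {
  e <- rbind(g1 = c(1, 2, 3, 4, 1, 2, 3, 4),
             g2 = c(2, 1, 4, 3, 2, 1, 4, 3))
  colnames(e) <- paste0("s", 1:8)
  cl <- setNames(c(rep("sensitive", 4), rep("resistant", 4)), colnames(e))
  same_mdc <- mdc_fdr(e, cl, c("g1", "g2"), n_perm = 10, seed = 1)
  expect_equal(same_mdc$direction, "neutral")
  expect_equal(same_mdc$fdr, 1)
  expect_error(mdc_fdr(e, cl, c("g1", "g2"), n_perm = 0), "n_perm")

  p <- simulate_panel(sim_config(n_samples = 120, n_genes = 5, n_dra = 0,
                                 seed = 81))
  cl2 <- trichotomize(drug_sensitivity(p$samples, "drugA"))
  mo <- simulate_differential_modules(
    p, data.frame(name = "m", size = 30, rho_s = 0.3, rho_r = 0.6),
    classes = cl2, seed = 82)
  r1 <- mdc_fdr(mo$expr, cl2, mo$collection$m, n_perm = 20, seed = 9)
  r2 <- mdc_fdr(mo$expr, cl2, mo$collection$m, n_perm = 20, seed = 9)
  expect_identical(r1, r2)
})

test_that("cross-drug rank aggregation puts consistent modules first", {
  t1 <- data.frame(module = c("a", "b", "c"), n_genes = 30,
                   mdc = c(3, 1.1, 0.9), fdr = c(0, 0.4, 0.5),
                   direction = c("gain", "gain", "loss"))
  expect_equal(rank_modules_across_drugs(list(d1 = t1))$module,
               c("a", "b", "c"))

  t2 <- t1; t2$mdc <- c(2.5, 1, 1.2); t2$fdr <- c(0.02, 1, 0.3)
  t3 <- t1; t3$mdc <- c(4, 0.8, 1.05); t3$fdr <- c(0, 0.2, 0.6)
  out <- rank_modules_across_drugs(list(d1 = t1, d2 = t2, d3 = t3))
  expect_equal(out$module[1], "a")  # ranked 1 for every drug
  expect_equal(out$rank_sum[1], 3)
  bad <- t1; bad$module <- c("a", "b", "zzz")
  expect_error(rank_modules_across_drugs(list(d1 = t1, d2 = bad)), "same module")

  # planted differential module tops a synthetic 3-drug panel
  p <- simulate_panel(sim_config(n_samples = 240, n_genes = 5, n_dra = 0,
                                 seed = 91))
  cl <- trichotomize(drug_sensitivity(p$samples, "drugA"))
  specs <- data.frame(name = c("planted", "null1", "null2"),
                      size = c(40, 40, 40),
                      rho_s = c(0.2, 0.4, 0.4), rho_r = c(0.7, 0.4, 0.4))
  tops <- vapply(1:10, function(i) {
    tabs <- lapply(1:3, function(d) {
      mo <- simulate_differential_modules(p, specs, classes = cl,
                                          seed = 900 + 10 * i + d)
      mdc_scan(mo$expr, cl, mo$collection, n_perm = 20, seed = i * 3 + d)
    })
    names(tabs) <- paste0("drug", 1:3)
    rank_modules_across_drugs(tabs)$module[1]
  }, character(1))
  expect_true(all(tops == "planted"))
})
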