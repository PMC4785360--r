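# Independent oracles and tiny fixture builders shared across the suite.

# Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Upper hypergeometric tail P(X >= ov) by pmf enumeration.
hyper_tail_oracle <- function(ov, K, n, N) {
  ks <- ov:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# OLS via the normal equations, with the two-sided t-test for one coefficient.
ols_oracle <- function(X, y, col) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  se <- sqrt(sum(res^2) / df * solve(XtX)[col, col])
  t <- beta[col] / se
  list(beta = beta[col], p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Brute-force Ward agglomeration (ward.D2 contract): Lance-Williams update on
# Euclidean distances, merging the cheapest pair until k clusters remain.
# Returns the partition as a list of index vectors.
ward_oracle <- function(points, k = 2) {
  clusters <- lapply(seq_len(nrow(points)), identity)
  d2 <- as.matrix(dist(points))^2
  repeat {
    if (length(clusters) <= k) break
    best <- c(NA, NA); best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      ci <- clusters[[i]]; cj <- clusters[[j]]
      # increase in within-cluster sum of squares on merging ci, cj
      mi <- colMeans(points[ci, , drop = FALSE])
      mj <- colMeans(points[cj, , drop = FALSE])
      cost <- length(ci) * length(cj) / (length(ci) + length(cj)) *
        sum((mi - mj)^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# Minimal valid sample table with one drug column.
tiny_samples <- function(n, sens, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    age = runif(n, 30, 70),
    sex = sample(c("male", "female"), n, TRUE),
    batch = sample(c("b1", "b2"), n, TRUE),
    cancer = sample(c("c1", "c2"), n, TRUE),
    tissue = sample(c("t1", "t2"), n, TRUE),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    stringsAsFactors = FALSE)
  df$sens_drugA <- sens
  validate_sample_table(df)
}

# 14-node hand-verified KDA fixture: candidate CAND reaches, within 2 hops,
# the hub H, all six module genes a1..a6 and two bystanders b1, b2 (|B| = 9);
# four fringe nodes f1..f4 hang off module genes so the 2-hop subnetwork of
# the module covers all 14 nodes. Hence p(CAND) = P(X >= 6),
# X ~ Hypergeom(N = 14, K = 6, n = 9) = C(8,3)/C(14,9) = 56/2002.
kda_fixture <- function() {
  edges <- rbind(
    c("CAND", "H"),
    cbind("H", paste0("a", 1:6)),
    cbind("H", c("b1", "b2")),
    cbind(paste0("f", 1:4), paste0("a", 1:4)))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::E(g)$weight <- 1
  list(graph = g, module = paste0("a", 1:6), candidate = "CAND",
       p_candidate = 56 / 2002)
}
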