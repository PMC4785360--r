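#' Sensitivity grouping of cell lines
#'
#' Samples are clustered on the expression of the drug's DRA genes
#' (hierarchical, Euclidean distance with Ward linkage, cut at two groups),
#' and separately trichotomized into sensitive / indeterminate / resistant by
#' the 0.8-standard-deviation rule.
#'
#' @name group_cluster
NULL

#' Cluster samples into sensitive and non-sensitive groups
#'
#' Agglomerative Ward clustering (the squared-Euclidean "ward.D2" contract:
#' each merge minimizes the increase in within-cluster sum of squares) on
#' Euclidean distances between sample expression profiles, cut into two
#' clusters. The cluster with the higher mean sensitivity is labeled
#' `"sensitive"`, the other `"non_sensitive"`.
#'
#' @param expr expression matrix restricted to the genes of interest
#'   (typically the drug's DRA genes), genes in rows.
#' @param sensitivity named numeric vector of activity areas; names must cover
#'   the matrix's samples.
#' @return list: `labels` (named character vector over samples), `hclust`
#'   (the agglomeration record), `group_means` (mean sensitivity per label).
#' @export
cluster_samples <- function(expr, sensitivity) {
  if (ncol(expr) < 2L) stop("need at least 2 samples to cluster")
  if (nrow(expr) < 1L) stop("need at least 1 gene")
  hc <- stats::hclust(stats::dist(t(expr), method = "euclidean"),
                      method = "ward.D2")
  cut <- stats::cutree(hc, k = 2L)
  s <- sensitivity[colnames(expr)]
  m <- tapply(s, cut, mean, na.rm = TRUE)
  sens_cluster <- as.integer(names(m)[which.max(m)])
  labels <- ifelse(cut == sens_cluster, "sensitive", "non_sensitive")
  names(labels) <- colnames(expr)
  list(labels = labels, hclust = hc,
       group_means = c(sensitive = unname(max(m)),
                       non_sensitive = unname(min(m))))
}

#' Student's t-test between the two clustered groups' sensitivities
#'
#' Two-sample pooled-variance (Student) t-test, two-sided.
#'
#' @param sensitivity named numeric vector of activity areas.
#' @param assignment result of [cluster_samples()], or a named character
#'   vector of labels with exactly two levels.
#' @return list: `t_statistic` (sensitive minus non-sensitive), `p_value`,
#'   `group_sizes` (named integer vector), `df`.
#' @export
compare_groups <- function(sensitivity, assignment) {
  labels <- if (is.list(assignment)) assignment$labels else assignment
  groups <- split(sensitivity[names(labels)], labels)
  if (length(groups) != 2L) stop("need exactly two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 members")
  ord <- c(grep("^sensitive$", names(groups)),
           grep("^sensitive$", names(groups), invert = TRUE))
  groups <- groups[ord]
  tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       group_sizes = stats::setNames(lengths(groups), names(groups)),
       df = unname(tt$parameter))
}

#' Trichotomize samples by sensitivity
#'
#' Values at least `k` sample standard deviations above the mean are classed
#' `resistant`; at least `k` SD below, `sensitive`; the remaining window of
#' width `2k` SD around the mean is `indeterminate` (those samples are
#' eliminated from the differential-connectivity analysis). Boundary values
#' exactly at mean +/- k*SD fall in the extreme class. With the default
#' `k = 0.8` the indeterminate window spans 1.6 SD.
#'
#' The "resistant = high activity area" orientation follows the stated rule
#' verbatim; set `invert_labels = TRUE` to swap the two extreme labels.
#'
#' @param sensitivity numeric vector (names preserved); needs >= 3 finite
#'   values and nonzero SD.
#' @param k window half-width in standard deviations, default 0.8.
#' @param invert_labels swap `sensitive`/`resistant`.
#' @return list: `classes` (named character vector), `mean`, `sd`, `k`,
#'   `counts` (named integer vector summing to the number of finite values).
#' @export
trichotomize <- function(sensitivity, k = 0.8, invert_labels = FALSE) {
  v <- sensitivity[is.finite(sensitivity)]
  if (length(v) < 3L) stop("need at least 3 finite sensitivity values")
  mu <- mean(v)
  sdv <- stats::sd(v)  # sample SD, n-1 denominator
  if (sdv == 0) stop("sensitivity has zero standard deviation")
  hi <- if (invert_labels) "sensitive" else "resistant"
  lo <- if (invert_labels) "resistant" else "sensitive"
  classes <- ifelse(v >= mu + k * sdv, hi,
                    ifelse(v <= mu - k * sdv, lo, "indeterminate"))
  names(classes) <- names(v)
  counts <- c(sensitive = sum(classes == "sensitive"),
              indeterminate = sum(classes == "indeterminate"),
              resistant = sum(classes == "resistant"))
  list(classes = classes, mean = mu, sd = sdv, k = k, counts = counts)
}
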