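#' Overlap and over-representation testing
#'
#' One-tailed Fisher (hypergeometric tail) tests of gene-list overlap: between
#' sample strata (male/female, young/old) over top-k ranked prefixes, across
#' drugs, and against gene-set collections.
#'
#' @name overlap_enrichment
NULL

# Upper hypergeometric tail P(X >= overlap), X ~ Hypergeom(N, K = |A|, n = |B|)
hyper_tail <- function(overlap, size_a, size_b, universe_size) {
  stats::phyper(overlap - 1L, size_a, universe_size - size_a, size_b,
                lower.tail = FALSE)
}

#' One-tailed Fisher's exact test of set overlap
#'
#' Tests over-enrichment: p = P(X >= |A intersect B|) for X hypergeometric
#' with population `universe_size`, `|A|` successes and `|B|` draws.
#'
#' @param set_a,set_b character vectors (deduplicated internally).
#' @param universe_size size of the common gene universe.
#' @return one-tailed p-value.
#' @export
fisher_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(union(set_a, set_b)) > universe_size)
    stop("universe smaller than the union of the two sets")
  hyper_tail(length(intersect(set_a, set_b)),
             length(set_a), length(set_b), universe_size)
}

#' Overlap significance of two rankings across top-k prefixes
#'
#' For each k, intersects the two top-k prefixes and computes the one-tailed
#' Fisher p; prefixes are flagged significantly overlapping at p <= 0.05.
#'
#' @param ranking_a,ranking_b character vectors of genes sorted by increasing
#'   p-value, no duplicates, over a shared universe.
#' @param ks prefix sizes, default `seq(100, 5000, by = 100)`.
#' @param universe_size size of the shared universe (typically the number of
#'   genes tested in both strata).
#' @return data.frame: `k`, `overlap`, `p_value`, `significant` (p <= 0.05).
#' @export
topk_overlap_sweep <- function(ranking_a, ranking_b,
                               ks = seq(100L, 5000L, by = 100L),
                               universe_size) {
  if (anyDuplicated(ranking_a) || anyDuplicated(ranking_b))
    stop("rankings must not contain duplicated genes")
  if (max(ks) > min(length(ranking_a), length(ranking_b)))
    stop("largest k exceeds a ranking's length")
  overlap <- vapply(ks, function(k)
    length(intersect(ranking_a[seq_len(k)], ranking_b[seq_len(k)])),
    integer(1))
  p <- hyper_tail(overlap, ks, ks, universe_size)
  data.frame(k = ks, overlap = overlap, p_value = p,
             significant = p <= 0.05)
}

#' How often each gene recurs across per-drug DRA sets
#'
#' @param per_drug_sets named list of character vectors, one per drug.
#' @return data.frame `gene`, `n_drugs`, sorted by descending count.
#' @export
recurrence_table <- function(per_drug_sets) {
  if (length(per_drug_sets) < 1L) stop("need at least one drug set")
  counts <- table(unlist(lapply(per_drug_sets, unique)))
  df <- data.frame(gene = names(counts), n_drugs = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_drugs, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Hypergeometric gene-set over-representation
#'
#' For each set in the collection (intersected with the universe first), the
#' one-tailed hypergeometric p of its overlap with the query, adjusted across
#' sets by Benjamini-Hochberg; sets are flagged at adjusted p <= 0.05.
#'
#' @param query_genes character vector, must be contained in `universe`.
#' @param collection named list of gene sets (e.g. from [read_gene_sets()]).
#' @param universe character vector of all measurable genes.
#' @param fdr_threshold significance threshold on the adjusted value.
#' @return data.frame: `set`, `set_size`, `overlap`, `p_value`, `fdr`,
#'   `significant`.
#' @export
gene_set_enrichment <- function(query_genes, collection, universe,
                                fdr_threshold = 0.05) {
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0L) stop("empty query")
  if (!all(query_genes %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 5), collapse = ", "))
  n_univ <- length(unique(universe))
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  set_size <- lengths(sets)
  overlap <- vapply(sets, function(s) length(intersect(s, query_genes)),
                    integer(1))
  p <- hyper_tail(overlap, set_size, length(query_genes), n_univ)
  fdr <- adjust_bh(p)
  data.frame(set = names(collection), set_size = set_size, overlap = overlap,
             p_value = p, fdr = fdr, significant = fdr <= fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
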