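#' Key driver analysis on a protein-interaction network
#'
#' A significant module's genes (set A) are mapped into the PPI network and
#' the analysis subnetwork induced on A plus its 2-hop neighbors is extracted.
#' Every subnetwork node is a candidate driver: with B its neighborhood of
#' nodes at shortest-path distance <= 2, enrichment of A within B is scored by
#' the hypergeometric tail P(X >= |A intersect B|), X ~ Hypergeom(N, |A|, |B|)
#' with N the subnetwork size. A permutation FDR (resampling |A| genes from
#' the subnetwork) flags key drivers at FDR < 0.05.
#'
#' @name kda
NULL

#' Nodes within h hops of a gene
#'
#' Breadth-first set of nodes at shortest-path distance <= `h` from `gene`,
#' excluding the seed itself by default (`h = 0` then yields the empty set).
#'
#' @param network igraph.
#' @param gene node name.
#' @param h hop limit, default 2.
#' @param include_self keep the seed in its own neighborhood.
#' @return character vector of node names.
#' @export
neighborhood <- function(network, gene, h = 2L, include_self = FALSE) {
  if (!gene %in% igraph::V(network)$name)
    stop("gene '", gene, "' not in network")
  if (h == 0L) return(if (include_self) gene else character(0))
  nb <- igraph::ego(network, order = h, nodes = gene,
                    mindist = if (include_self) 0L else 1L)[[1L]]
  nb$name
}

#' Extract the analysis subnetwork around a module
#'
#' Induced subgraph on the mapped module genes and every node within `h` hops
#' of any of them. Node attributes `in_module` (and, when `drivers` is given,
#' `key_driver`) annotate the export.
#'
#' @param network igraph PPI network.
#' @param module_genes_a module gene set (A); genes absent from the network
#'   are ignored, but A must map to at least one node.
#' @param h hop limit, default 2.
#' @param drivers optional character vector of key-driver genes to annotate.
#' @return igraph with logical node attributes `in_module` and `key_driver`.
#' @export
extract_subnetwork <- function(network, module_genes_a, h = 2L, drivers = NULL) {
  a <- intersect(unique(module_genes_a), igraph::V(network)$name)
  if (length(a) == 0L) stop("module does not map into the network")
  reach <- unique(unlist(lapply(
    igraph::ego(network, order = h, nodes = a, mindist = 0L),
    function(v) v$name)))
  g <- igraph::induced_subgraph(network, reach)
  igraph::V(g)$in_module <- igraph::V(g)$name %in% a
  igraph::V(g)$key_driver <- igraph::V(g)$name %in% (drivers %||% character())
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Neighborhood membership matrix of a graph: logical candidates x nodes,
# M[i, j] TRUE when node j lies within h hops of candidate i (seed excluded
# unless include_self).
neighborhood_matrix <- function(g, h, include_self = FALSE) {
  d <- igraph::distances(g)
  m <- d <= h
  if (!include_self) diag(m) <- FALSE
  m
}

#' Hypergeometric key-driver scores for every candidate
#'
#' @param network igraph PPI network.
#' @param module_genes_a module gene set (A).
#' @param h hop limit for neighborhoods, default 2.
#' @param include_self count the candidate itself in its neighborhood B.
#' @param universe `"subnetwork"` (default) scores within the extracted
#'   analysis subnetwork; `"network"` uses the whole input graph as both
#'   candidate pool and universe.
#' @return data.frame: `gene`, `neighborhood_size`, `overlap`, `p_value`,
#'   plus attributes `subnetwork` (the igraph) and `n_module` (|A| mapped).
#' @export
kda_score <- function(network, module_genes_a, h = 2L, include_self = FALSE,
                      universe = c("subnetwork", "network")) {
  universe <- match.arg(universe)
  g <- if (universe == "subnetwork")
    extract_subnetwork(network, module_genes_a, h) else network
  nodes <- igraph::V(g)$name
  a <- intersect(unique(module_genes_a), nodes)
  if (length(a) == 0L) stop("module does not map into the network")
  nb <- neighborhood_matrix(g, h, include_self)
  in_a <- nodes %in% a
  size_b <- rowSums(nb)
  overlap <- as.integer(nb %*% in_a)
  p <- hyper_tail(overlap, length(a), size_b, length(nodes))
  out <- data.frame(gene = nodes, neighborhood_size = size_b,
                    overlap = overlap, p_value = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "subnetwork") <- g
  attr(out, "n_module") <- length(a)
  out
}

#' Key drivers by permutation FDR
#'
#' The null resamples |A| genes uniformly from the subnetwork node set and
#' recomputes every candidate's enrichment p; a candidate's FDR is the
#' fraction of its null p-values at or below the observed one. Candidates
#' with FDR below `threshold` are flagged key drivers.
#'
#' @inheritParams kda_score
#' @param n_perm number of resampled module draws, default 1000.
#' @param seed RNG seed.
#' @param threshold key-driver FDR threshold, default 0.05 (flag iff
#'   fdr < threshold).
#' @return data.frame: `gene`, `neighborhood_size`, `overlap`, `p_value`,
#'   `fdr`, `key_driver`; attribute `subnetwork` carries the annotated graph.
#' @export
kda_fdr <- function(network, module_genes_a, h = 2L, n_perm = 1000L,
                    seed = 1L, threshold = 0.05, include_self = FALSE,
                    universe = c("subnetwork", "network")) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  obs <- kda_score(network, module_genes_a, h, include_self, universe)
  g <- attr(obs, "subnetwork")
  nodes <- igraph::V(g)$name
  n_a <- attr(obs, "n_module")
  nb <- neighborhood_matrix(g, h, include_self)
  size_b <- rowSums(nb)
  set.seed(seed)
  exceed <- integer(length(nodes))
  for (b in seq_len(n_perm)) {
    a_star <- logical(length(nodes))
    a_star[sample(length(nodes), n_a)] <- TRUE
    ov <- as.integer(nb %*% a_star)
    p_null <- hyper_tail(ov, n_a, size_b, length(nodes))
    exceed <- exceed + (p_null <= obs$p_value)
  }
  obs$fdr <- exceed / n_perm
  obs$key_driver <- obs$fdr < threshold
  igraph::V(g)$key_driver <- nodes %in% obs$gene[obs$key_driver]
  attr(obs, "subnetwork") <- g
  obs[order(obs$fdr, obs$p_value), , drop = FALSE]
}

#' Write a subnetwork as edge list plus node attribute table
#'
#' @param g annotated subnetwork from [extract_subnetwork()] or [kda_fdr()].
#' @param edge_path,node_path output paths.
#' @export
write_subnetwork <- function(g, edge_path, node_path) {
  write_network_edges(g, edge_path)
  nodes <- data.frame(gene = igraph::V(g)$name,
                      in_module = igraph::V(g)$in_module,
                      key_driver = igraph::V(g)$key_driver,
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
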