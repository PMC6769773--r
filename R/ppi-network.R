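#' Build a seeded protein-protein interaction network
#'
#' First-order network: the seed genes plus all of their direct interactors in
#' the interactome, with the induced edges among those nodes. If a tissue
#' filter is given, the interactome is restricted first (both edge endpoints
#' must be tissue-expressed) and the seeds are expanded in the restricted
#' graph — tissue specificity filters the interactome, not the seeds. Seeds
#' absent from the interactome are kept as isolated flagged nodes. Self-loops
#' and duplicate edges are dropped on ingest.
#'
#' @param seeds character vector of seed gene symbols (non-empty).
#' @param interactome data.frame of symbol pairs (first two columns used).
#' @param tissue optional character vector of tissue-expressed symbols.
#' @return An igraph graph with logical vertex attribute `seed`.
#' @export
build_ppi <- function(seeds, interactome, tissue = NULL) {
  if (!length(seeds)) stop("seed list must be non-empty")
  if (!nrow(interactome)) stop("interactome must be non-empty")
  seeds <- unique(toupper(seeds))
  a <- toupper(as.character(interactome[[1]]))
  b <- toupper(as.character(interactome[[2]]))
  keep <- a != b
  e <- unique(data.frame(a = pmin(a[keep], b[keep]),
                         b = pmax(a[keep], b[keep]),
                         stringsAsFactors = FALSE))
  if (!is.null(tissue)) {
    tissue <- unique(toupper(tissue))
    if (!length(tissue)) stop("tissue filter must be non-empty")
    e <- e[e$a %in% tissue & e$b %in% tissue, , drop = FALSE]
  }
  touch <- e$a %in% seeds | e$b %in% seeds
  e1 <- e[touch, , drop = FALSE]
  nodes <- unique(c(seeds, e1$a, e1$b))
  # induced edges among first-order nodes (includes interactor-interactor)
  e_ind <- e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e_ind, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$seed <- igraph::V(g)$name %in% seeds
  g
}

#' Minimum network: prune peripheral non-seed nodes
#'
#' Iteratively deletes non-seed nodes of degree <= 1 until a fixed point. The
#' rule is confluent: the result does not depend on deletion order, and the
#' operation is idempotent. Connectors lying on paths between seeds survive;
#' dead-end branches of non-seeds are removed.
#'
#' @param g a [build_ppi()] graph with vertex attribute `seed`.
#' @return The pruned igraph subgraph.
#' @export
minimum_network <- function(g) {
  repeat {
    drop <- igraph::V(g)[!igraph::V(g)$seed & igraph::degree(g) <= 1]
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

#' Rank network hubs by degree and betweenness
#'
#' Degree descending, ties by betweenness descending then id; the top `k`
#' nodes are labeled hubs.
#'
#' @param g an igraph graph.
#' @param k number of hub labels (default 20).
#' @return data.frame: `id`, `seed`, `degree`, `betweenness`, `rank`,
#'   `is_hub`.
#' @export
rank_hubs <- function(g, k = 20) {
  if (!igraph::vcount(g)) stop("graph is empty")
  tab <- data.frame(id = igraph::V(g)$name,
                    seed = igraph::V(g)$seed %||% NA,
                    degree = unname(igraph::degree(g)),
                    betweenness = unname(igraph::betweenness(g, directed = FALSE)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, -tab$betweenness, tab$id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$is_hub <- tab$rank <= k
  rownames(tab) <- NULL
  tab
}
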