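#' Assemble a target database from edge tables
#'
#' Merges one or more (miRNA, gene, evidence) edge tables into a single
#' database: gene symbols upper-cased, duplicate (miRNA, gene) pairs collapsed
#' (keeping the strongest evidence seen).
#'
#' @param ... data.frames with columns `mirna`, `gene`, `evidence`
#'   (`strong|weak`) and optionally `source`.
#' @return A `target_db` data.frame.
#' @export
target_db <- function(...) {
  tabs <- list(...)
  e <- do.call(rbind, lapply(tabs, function(t) {
    stopifnot(all(c("mirna", "gene", "evidence") %in% names(t)))
    data.frame(mirna = as.character(t$mirna),
               gene = toupper(trimws(as.character(t$gene))),
               evidence = as.character(t$evidence),
               source = if ("source" %in% names(t)) as.character(t$source)
                        else "user",
               stringsAsFactors = FALSE)
  }))
  if (any(e$gene == "")) stop("empty gene symbol")
  bad <- setdiff(unique(e$evidence), c("strong", "weak"))
  if (length(bad)) stop("evidence must be strong|weak, got: ",
                        paste(bad, collapse = ", "))
  # strongest evidence wins on duplicates
  e <- e[order(e$mirna, e$gene, e$evidence != "strong"), ]
  e <- e[!duplicated(e[, c("mirna", "gene")]), ]
  rownames(e) <- NULL
  structure(e, class = c("target_db", "data.frame"))
}

#' Build a miRNA-target bipartite network
#'
#' Keeps exactly the database edges whose miRNA is in `mirnas` and whose
#' evidence passes the filter. Listed miRNAs with no passing edge are retained
#' as isolated degree-0 nodes (with a warning for ids absent from the
#' database).
#'
#' @param mirnas character vector of miRNA ids (non-empty).
#' @param db a [target_db()].
#' @param evidence `"strong"`, `"weak"` or `"any"` (default `"any"`).
#' @return An igraph graph with vertex attributes `type` (`"mirna"`/`"gene"`).
#' @export
build_network <- function(mirnas, db, evidence = c("any", "strong", "weak")) {
  evidence <- match.arg(evidence)
  if (!length(mirnas)) stop("miRNA list must be non-empty")
  unknown <- setdiff(mirnas, unique(db$mirna))
  if (length(unknown))
    warning("miRNA(s) absent from database kept as isolated nodes: ",
            paste(unknown, collapse = ", "))
  e <- db[db$mirna %in% mirnas, , drop = FALSE]
  if (evidence != "any") e <- e[e$evidence == evidence, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("mirna", "gene")], directed = FALSE,
    vertices = data.frame(name = c(unique(mirnas), setdiff(unique(e$gene), mirnas))))
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% mirnas, "mirna", "gene")
  g
}

#' Rank miRNAs of a bipartite network by centrality
#'
#' Degree is the neighbor count; betweenness is classical unnormalized
#' shortest-path betweenness (endpoints excluded) on the undirected graph.
#' Rows are sorted by degree descending, ties broken by betweenness descending
#' then lexicographic id, so output order is deterministic.
#'
#' @param net a [build_network()] graph.
#' @param nodes which nodes to rank: `"mirna"` (default), `"gene"` or
#'   `"all"`.
#' @return data.frame: `id`, `degree`, `betweenness`, `rank`.
#' @export
rank_centrality <- function(net, nodes = c("mirna", "gene", "all")) {
  nodes <- match.arg(nodes)
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  tab <- data.frame(id = igraph::V(net)$name, degree = unname(deg),
                    betweenness = unname(btw),
                    type = igraph::V(net)$type %||% "all",
                    stringsAsFactors = FALSE)
  if (nodes != "all") tab <- tab[tab$type == nodes, , drop = FALSE]
  tab <- tab[order(-tab$degree, -tab$betweenness, tab$id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("id", "degree", "betweenness", "rank")]
}

#' Extract the multiply-targeted core of a miRNA-target network
#'
#' Keeps genes with at least `min_interactions` miRNA partners together with
#' those partners; each kept gene is labeled `"high"` (more than two
#' interactions) or `"mid"` (exactly two). Disconnected components are
#' preserved.
#'
#' @param net a [build_network()] graph (typically strong-evidence filtered).
#' @param min_interactions minimum miRNA partners for a gene (default 2).
#' @return An igraph subgraph with gene vertex attribute `core_label`; empty
#'   graph allowed.
#' @export
core_network <- function(net, min_interactions = 2) {
  is_gene <- igraph::V(net)$type == "gene"
  deg <- igraph::degree(net)
  keep_genes <- igraph::V(net)$name[is_gene & deg >= min_interactions]
  if (!length(keep_genes))
    return(igraph::induced_subgraph(net, integer(0)))
  partners <- unique(unlist(lapply(
    igraph::adjacent_vertices(net, keep_genes), names)))
  sub <- igraph::induced_subgraph(net, c(keep_genes, partners))
  lab <- rep(NA_character_, igraph::vcount(sub))
  gdeg <- deg[igraph::V(sub)$name]
  lab[igraph::V(sub)$type == "gene"] <-
    ifelse(gdeg[igraph::V(sub)$type == "gene"] > 2, "high", "mid")
  igraph::V(sub)$core_label <- lab
  sub
}

#' Exclusive Venn regions of named gene sets
#'
#' Exact set algebra over 2 or 3 named sets. For three sets returns the 7
#' exclusive regions (members and sizes); `total_shared` is the sum of the
#' multi-set regions.
#'
#' @param sets named list of character vectors (2 or 3 sets).
#' @return A list: `regions` (named list of member vectors, names like
#'   `"A&B"`, `"A&B&C"`, `"A"` for the exclusive regions), `sizes` (named
#'   integer vector), `total_shared` (size of the union of multi-set regions).
#' @export
intersect_target_sets <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 named sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  n <- length(sets)
  universe <- unique(unlist(sets))
  membership <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  regions <- list()
  for (k in n:1) {
    combos <- utils::combn(nm, k, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(membership[, cmb, drop = FALSE]) == k &
        rowSums(membership[, setdiff(nm, cmb), drop = FALSE]) == 0
      regions[[paste(cmb, collapse = "&")]] <- sort(universe[inside])
    }
  }
  sizes <- vapply(regions, length, integer(1))
  multi <- grepl("&", names(regions))
  list(regions = regions, sizes = sizes,
       total_shared = sum(sizes[multi]))
}
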