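#' Simulate an evidence-graded miRNA-target edge database
#'
#' Stands in for curated target databases: each miRNA receives a random number
#' of gene targets from a synthetic universe, each edge graded `strong` or
#' `weak`. A `shared_core` of genes is guaranteed to be targeted by at least
#' one miRNA of every group in `groups`, so group-wise target-set intersections
#' have a known non-empty triple region.
#'
#' @param mirna_ids character vector of miRNA ids.
#' @param gene_universe_size number of genes in the synthetic universe.
#' @param edges_per_mirna_range integer length-2 range of targets per miRNA.
#' @param shared_core character vector of gene symbols every group must hit;
#'   symbols are added to the universe if not generated.
#' @param groups optional named list mapping group name -> miRNA ids (subset of
#'   `mirna_ids`); required when `shared_core` is non-empty.
#' @param strong_fraction probability an edge is graded `strong`.
#' @param seed integer seed.
#' @return A `target_db` data.frame with columns `mirna`, `gene`, `evidence`,
#'   `source`; no duplicate (mirna, gene) pairs; symbols upper-cased.
#' @export
generate_target_db <- function(mirna_ids, gene_universe_size = 500,
                               edges_per_mirna_range = c(5L, 40L),
                               shared_core = character(),
                               groups = NULL,
                               strong_fraction = 0.6,
                               seed) {
  if (!length(mirna_ids)) stop("mirna_ids must be non-empty")
  stopifnot(gene_universe_size >= max(edges_per_mirna_range))
  universe <- toupper(unique(c(sprintf("GENE%04d", seq_len(gene_universe_size)),
                               shared_core)))
  if (length(shared_core) && is.null(groups))
    stop("groups must be given when shared_core is requested")
  edges <- with_seed(seed, {
    lo <- edges_per_mirna_range[1]; hi <- edges_per_mirna_range[2]
    rows <- lapply(mirna_ids, function(m) {
      k <- if (lo == hi) lo else sample(lo:hi, 1)
      data.frame(mirna = m, gene = sample(universe, k),
                 stringsAsFactors = FALSE)
    })
    e <- do.call(rbind, rows)
    # guarantee the shared core is hit by one miRNA of every group
    if (length(shared_core)) {
      for (g in names(groups)) {
        carrier <- sample(intersect(groups[[g]], mirna_ids), 1)
        e <- rbind(e, data.frame(mirna = carrier, gene = toupper(shared_core),
                                 stringsAsFactors = FALSE))
      }
    }
    e <- unique(e)
    e$evidence <- ifelse(stats::runif(nrow(e)) < strong_fraction, "strong", "weak")
    # core edges must survive a strong-evidence filter
    e$evidence[e$gene %in% toupper(shared_core)] <- "strong"
    e
  })
  edges$source <- "synthetic"
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("target_db", "data.frame"))
}

#' Simulate a triplicate qPCR Ct plate
#'
#' Draws cycle-threshold values for a set of assays over samples. The true
#' relative level of assay `a` in sample `s` maps to an expected
#' `Ct = offset - log2(level)`; replicate noise is normal with sd
#' `replicate_sd`. Draws above `ceiling` cycles are recorded as
#' `"Undetermined"`, the instrument's out-of-range token.
#'
#' @param true_levels numeric matrix of true relative levels, samples in rows
#'   (rownames = sample ids), assays in columns (colnames = assay ids); all
#'   levels must be positive.
#' @param cohort character vector of cohort labels, one per sample row.
#' @param n_replicates replicates per (sample, assay), default 3.
#' @param replicate_sd replicate Ct noise in cycles (default 0.25).
#' @param ct_offset Ct of a level-1 assay (default 30 cycles).
#' @param ceiling determinable range in cycles (default 45).
#' @param seed integer seed.
#' @return A `ct_plate` data.frame: `sample`, `cohort`, `assay`, `replicate`,
#'   `ct` (character; cycles or `"Undetermined"`).
#' @export
generate_qpcr_plate <- function(true_levels, cohort, n_replicates = 3L,
                                replicate_sd = 0.25, ct_offset = 30,
                                ceiling = 45, seed) {
  true_levels <- as.matrix(true_levels)
  if (any(true_levels <= 0)) stop("true relative levels must be positive")
  stopifnot(ceiling > 0, n_replicates >= 1,
            length(cohort) == nrow(true_levels))
  samples <- rownames(true_levels); assays <- colnames(true_levels)
  if (is.null(samples) || is.null(assays))
    stop("true_levels needs sample rownames and assay colnames")
  grid <- expand.grid(replicate = seq_len(n_replicates), assay = assays,
                      sample = samples, stringsAsFactors = FALSE)
  ct <- with_seed(seed, {
    mu <- ct_offset - log2(true_levels[cbind(grid$sample, grid$assay)])
    mu + stats::rnorm(nrow(grid), 0, replicate_sd)
  })
  out <- data.frame(sample = grid$sample,
                    cohort = cohort[match(grid$sample, samples)],
                    assay = grid$assay,
                    replicate = grid$replicate,
                    ct = ifelse(ct > ceiling, "Undetermined",
                                formatC(ct, digits = 6, format = "f")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$assay, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ct_plate_raw", "data.frame"))
}

#' Simulate a GMT-writable gene-set collection
#'
#' Random gene sets over a universe, with an optional planted set whose
#' members can be enriched by construction in a downstream query.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param set_size_range integer length-2 range of set sizes.
#' @param enriched_set optional character vector included verbatim as set
#'   `"PLANTED_SET"`.
#' @param seed integer seed.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
generate_genesets <- function(universe, n_sets = 50, set_size_range = c(10L, 50L),
                              enriched_set = NULL, seed) {
  universe <- toupper(unique(universe))
  if (max(set_size_range) > length(universe))
    stop("set size exceeds universe")
  sets <- with_seed(seed, {
    lo <- set_size_range[1]; hi <- set_size_range[2]
    s <- lapply(seq_len(n_sets), function(i) {
      k <- if (lo == hi) lo else sample(lo:hi, 1)
      sort(sample(universe, k))
    })
    names(s) <- sprintf("SET_%03d", seq_len(n_sets))
    s
  })
  if (!is.null(enriched_set)) {
    bad <- setdiff(toupper(enriched_set), universe)
    if (length(bad)) stop("enriched_set genes outside universe: ",
                          paste(bad, collapse = ", "))
    sets$PLANTED_SET <- sort(toupper(enriched_set))
  }
  gene_set_collection(sets, universe)
}

#' Simulate an interactome edge list
#'
#' Undirected simple graph over gene symbols. With `hub_bias = 0` edge
#' endpoints are sampled uniformly (degrees approach a binomial null); larger
#' `hub_bias` preferentially attaches edges to a subset of hub genes, giving
#' the heavy-tailed degree structure real interactomes show.
#'
#' @param universe character vector of gene symbols.
#' @param n_edges number of (unique, loop-free) edges to draw.
#' @param hub_bias non-negative real; 0 = uniform endpoints.
#' @param seed integer seed.
#' @return A data.frame with columns `a`, `b` (symbols, upper-cased) plus an
#'   attribute `n_components` with the connected-component count.
#' @export
generate_interactome <- function(universe, n_edges = 2000, hub_bias = 2,
                                 seed) {
  universe <- toupper(unique(universe))
  stopifnot(length(universe) >= 2, n_edges >= 1, hub_bias >= 0)
  edges <- with_seed(seed, {
    w <- if (hub_bias == 0) rep(1, length(universe))
         else exp(hub_bias * stats::runif(length(universe)))
    seen <- character(0)
    out <- matrix(character(0), ncol = 2)
    # oversample then dedupe; repeat until enough unique loop-free edges
    while (nrow(out) < n_edges) {
      need <- n_edges - nrow(out)
      a <- sample(universe, 2 * need + 10, replace = TRUE, prob = w)
      b <- sample(universe, 2 * need + 10, replace = TRUE, prob = w)
      keep <- a != b
      a <- a[keep]; b <- b[keep]
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi)
      fresh <- !(key %in% seen) & !duplicated(key)
      seen <- c(seen, key[fresh])
      out <- rbind(out, cbind(lo[fresh], hi[fresh]))
    }
    out[seq_len(n_edges), , drop = FALSE]
  })
  df <- data.frame(a = edges[, 1], b = edges[, 2], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  attr(df, "n_components") <- igraph::count_components(g)
  df
}
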