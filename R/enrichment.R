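#' Gene-set collection with a defined universe
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe background gene symbols; defaults to the union of all set
#'   members (collection-defined background).
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a non-empty named list")
  sets <- lapply(sets, function(s) sort(unique(toupper(s))))
  if (any(lengths(sets) == 0)) stop("set sizes must be >= 1")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  else universe <- sort(unique(toupper(universe)))
  outside <- setdiff(unlist(sets), universe)
  if (length(outside))
    stop("set member(s) outside universe: ", paste(utils::head(outside, 5), collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, the one-sided upper-tail hypergeometric probability of the
#' observed overlap k between the query and the set:
#' P(X >= k), X ~ Hypergeom(N = |universe|, K = |set|, n = |query ∩ universe|).
#' Query genes outside the universe are dropped (count reported), never added
#' to the background. Benjamini-Hochberg q-values are reported alongside raw p.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param background optional user-supplied universe overriding the
#'   collection's.
#' @return A data.frame sorted by p then set name: `set`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `p`, `q`,
#'   `overlap_genes` (comma-joined); `attr(, "dropped")` counts query genes
#'   outside the universe.
#' @examples
#' # universe 20, set 5, query 5, overlap 3 -> p = 1126/15504 = 0.0726
#' @export
ora_test <- function(query, collection, background = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- if (is.null(background)) collection$universe
              else sort(unique(toupper(background)))
  query <- unique(toupper(query))
  eff <- intersect(query, universe)
  dropped <- length(query) - length(eff)
  if (!length(eff)) stop("no query genes in the universe")
  N <- length(universe); n <- length(eff)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    K <- length(s)
    ov <- intersect(eff, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, p = p,
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), c("set", "overlap", "query_size",
                                      "set_size", "universe_size", "p", "q",
                                      "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving FDR q-values with monotonicity enforcement; thin named
#' wrapper over [stats::p.adjust()] so the adjustment used throughout the
#' package is explicit and testable in one place.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Shared and unique enriched categories across miRNA groups
#'
#' Partitions the categories significant (raw p < alpha) in at least one
#' group into: significant in all groups, in each exact pair (and no others),
#' and unique to each group.
#'
#' @param results_by_group named list of [ora_test()] result data.frames.
#' @param alpha significance threshold on raw p (default 0.05).
#' @return A list of buckets: `all` plus one entry per exact pair
#'   (`"g1&g2"`) and per group (`"g1"`); each a character vector of set names.
#' @export
compare_groups <- function(results_by_group, alpha = 0.05) {
  if (length(results_by_group) < 2) stop("need >= 2 groups of results")
  sig <- lapply(results_by_group, function(r) r$set[r$p < alpha])
  nm <- names(results_by_group)
  all_sets <- unique(unlist(sig))
  inside <- sapply(sig, function(s) all_sets %in% s)
  if (length(all_sets) == 1) inside <- matrix(inside, nrow = 1)
  count <- rowSums(inside)
  buckets <- list(all = sort(all_sets[count == length(nm)]))
  if (length(nm) > 2) {
    for (cmb in utils::combn(nm, 2, simplify = FALSE)) {
      inpair <- rowSums(inside[, cmb, drop = FALSE]) == 2 & count == 2
      buckets[[paste(cmb, collapse = "&")]] <- sort(all_sets[inpair])
    }
  }
  for (g in nm)
    buckets[[g]] <- sort(all_sets[inside[, g] & count == 1])
  buckets
}
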