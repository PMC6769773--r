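# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: betweenness by exhaustive simple-path enumeration,
# hypergeometric tails by direct binomial-coefficient sums, BH by literal
# step-up arithmetic.

# All-pairs shortest-path betweenness (endpoints excluded, unnormalized) by
# enumerating every simple path between every node pair and keeping the
# shortest ones. Feasible for graphs up to ~12 nodes.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  ids <- igraph::V(g)$name
  btw <- stats::setNames(rep(0, n), ids)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (nxt in which(adj[last, ])) if (!nxt %in% path) walk(c(path, nxt))
    }
    walk(s)
    paths
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, integer(1))
    short <- paths[len == min(len)]
    for (p in short) {
      inner <- p[-c(1, length(p))]
      if (length(inner)) btw[inner] <- btw[inner] + 1 / length(short)
    }
  }
  btw
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration of the tail.
hyper_tail_exact <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of
# p_(j) * m / j, capped at 1.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random bipartite graph on a + b nodes for centrality property tests.
random_bipartite <- function(a, b, p_edge = 0.4) {
  left <- sprintf("m%02d", seq_len(a))
  right <- sprintf("g%02d", seq_len(b))
  e <- expand.grid(mirna = left, gene = right, stringsAsFactors = FALSE)
  e <- e[stats::runif(nrow(e)) < p_edge, , drop = FALSE]
  e$evidence <- "strong"
  if (!nrow(e)) e <- data.frame(mirna = left[1], gene = right[1],
                                evidence = "strong")
  suppressWarnings(build_network(left, target_db(e), evidence = "strong"))
}

# Tiny hand-built count matrix used by the normalization tests.
tiny_count_matrix <- function(endo, neg, pos, hk, cohort = NULL) {
  counts <- rbind(endo, neg, pos, hk)
  rownames(counts) <- c(sprintf("miR-%d", seq_len(nrow(endo))),
                        sprintf("NEG_%d", seq_len(nrow(neg))),
                        sprintf("POS_%d", seq_len(nrow(pos))),
                        sprintf("HK_%d", seq_len(nrow(hk))))
  colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  cls <- c(rep("endogenous", nrow(endo)), rep("negative", nrow(neg)),
           rep("positive", nrow(pos)), rep("housekeeping", nrow(hk)))
  count_matrix(counts, cls, cohort %||% rep("Control", ncol(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
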