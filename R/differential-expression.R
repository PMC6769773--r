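#' Kruskal-Wallis rank test across cohorts
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = k - 1). This is the nonparametric one-way ANOVA used to compare miRNA
#' counts across the Control and FIGO cohorts. Delegates to
#' [stats::kruskal.test()], whose statistic is the mid-rank, tie-corrected H.
#' The degenerate all-tied input returns H = 0, p = 1.
#'
#' @param values_by_cohort named list of numeric vectors, one per cohort.
#' @return A list with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9, d = 10:12))  # H = 10.3846
#' @export
kruskal_wallis <- function(values_by_cohort) {
  n <- lengths(values_by_cohort)
  if (length(values_by_cohort) < 2 || any(n == 0))
    stop("need >= 2 cohorts, each with >= 1 observation")
  x <- unlist(values_by_cohort, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total")
  g <- factor(rep(names(values_by_cohort), n), levels = names(values_by_cohort))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(values_by_cohort) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Exact-by-simulation permutation p-value for the Kruskal-Wallis statistic
#'
#' Monte Carlo permutation null for H: group labels are permuted, H recomputed,
#' and the upper-tail proportion returned (with the +1 correction). Used as a
#' small-sample alternative to the chi-square approximation and as an
#' independent check of it.
#'
#' @param values_by_cohort named list of numeric vectors.
#' @param n_perm number of permutations (default 1e5).
#' @param seed RNG seed.
#' @return A list with `H`, `p_perm`, `n_perm`.
#' @export
kruskal_wallis_permutation <- function(values_by_cohort, n_perm = 1e5, seed = 1) {
  obs <- kruskal_wallis(values_by_cohort)
  x <- unlist(values_by_cohort, use.names = FALSE)
  n <- lengths(values_by_cohort)
  g <- rep(names(values_by_cohort), n)
  r <- rank(x)  # ranks are permutation-invariant; permute labels only
  N <- length(x)
  ties <- table(r)
  tie_term <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_of <- function(lab) {
    rs <- tapply(r, lab, sum)
    (12 / (N * (N + 1)) * sum(rs^2 / n[names(rs)]) - 3 * (N + 1)) / tie_term
  }
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) h_of(sample(g)) >= obs$H - 1e-12,
               logical(1)))
  })
  list(H = obs$H, p_perm = (count + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled mid-ranks following a Kruskal-Wallis
#' test, with tie correction:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left[\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right]\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' Two-sided normal p-values are adjusted by multiplying by the number of
#' pairs (Bonferroni, the classical Dunn adjustment) or by Holm's step-down.
#'
#' @param values_by_cohort named list of numeric vectors.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @examples
#' d <- dunn_posthoc(list(a = 1:3, b = 4:6, c = 7:9, d = 10:12))
#' d[d$group1 == "a" & d$group2 == "d", "z"]  # -3.0571 (a below d)
#' @export
dunn_posthoc <- function(values_by_cohort, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  n <- lengths(values_by_cohort)
  if (length(values_by_cohort) < 2 || any(n == 0))
    stop("need >= 2 cohorts, each with >= 1 observation")
  x <- unlist(values_by_cohort, use.names = FALSE)
  lab <- rep(names(values_by_cohort), n)
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, factor(lab, levels = names(values_by_cohort)), mean)
  ties <- table(x)
  tie_adj <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(values_by_cohort), 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    denom <- sqrt((N * (N + 1) / 12 - tie_adj) * (1 / n[[i]] + 1 / n[[j]]))
    if (denom == 0) return(0)
    (rbar[[i]] - rbar[[j]]) / denom
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjust == "bonferroni") pmin(p * ncol(pairs), 1)
           else stats::p.adjust(p, method = "holm")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p = p, p_adj = p_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative fold change against the control mean
#'
#' `(stage mean count - control mean count) / control mean count`: 0 means no
#' change, 2 means a tripled mean, negative values mean down-regulation (-0.5
#' is a halved mean). A zero control mean makes the ratio undefined; such
#' probes are flagged `control-absent` and get `NA`, never +/-Inf.
#'
#' @param stage_mean,control_mean cohort arithmetic means of normalized counts.
#' @return Named list: `fold_change` (numeric or NA) and `flag` (`"ok"` or
#'   `"control-absent"`).
#' @export
fold_change <- function(stage_mean, control_mean) {
  if (is.na(control_mean) || control_mean == 0)
    return(list(fold_change = NA_real_, flag = "control-absent"))
  list(fold_change = (stage_mean - control_mean) / control_mean, flag = "ok")
}

#' Detection call for a probe within a cohort
#'
#' Operationalizes "expressed in cohort X": detected iff the (background
#' corrected) count exceeds `threshold` in at least `min_fraction` of that
#' cohort's samples.
#'
#' @param min_fraction fraction of samples required (default 0.5).
#' @param threshold count threshold, exceeded strictly (default 0, i.e. any
#'   signal surviving background subtraction).
#' @return A `detection_rule` list.
#' @export
detection_rule <- function(min_fraction = 0.5, threshold = 0) {
  stopifnot(min_fraction > 0, min_fraction <= 1, threshold >= 0)
  structure(list(min_fraction = min_fraction, threshold = threshold),
            class = "detection_rule")
}

#' Per-cohort differential expression of normalized counts
#'
#' For every endogenous probe: per-cohort means, tie-corrected Kruskal-Wallis
#' across all cohorts, Dunn pairwise post hoc, fold change of each FIGO stage
#' against Control, detection flags per cohort, and the stratified group call:
#' \describe{
#'   \item{group1}{detected in Control and in at least one patient cohort, and
#'     KW p < alpha (significantly differentially expressed).}
#'   \item{group2}{not detected in Control; detected in the first patient
#'     cohort (FIGO I) only.}
#'   \item{group3}{not detected in Control; detected in all patient cohorts.}
#'   \item{none}{anything else.}
#' }
#' Groups are mutually exclusive by construction.
#'
#' @param m normalized [count_matrix()] (endogenous probes are tested).
#' @param control cohort label serving as reference (default `"Control"`).
#' @param detection a [detection_rule()].
#' @param alpha significance level for the KW gate (default 0.05).
#' @param adjust Dunn adjustment passed to [dunn_posthoc()].
#' @return A `de_result` data.frame, one row per probe: per-cohort means
#'   (`mean_<cohort>`), `H`, `p`, per-stage fold changes (`fc_<stage>`),
#'   per-cohort detection (`det_<cohort>`), `group`; Dunn tables in
#'   `attr(, "dunn")` (named list per probe).
#' @export
differential_expression <- function(m, control = "Control",
                                    detection = detection_rule(),
                                    alpha = 0.05,
                                    adjust = "bonferroni") {
  stopifnot(inherits(m, "count_matrix"), control %in% m$cohort)
  cohorts <- unique(unname(m$cohort))
  stages <- setdiff(cohorts, control)
  endo <- m$counts[m$probe_class == "endogenous", , drop = FALSE]
  split_cols <- lapply(cohorts, function(co) which(m$cohort == co))
  names(split_cols) <- cohorts

  dunn_tabs <- vector("list", nrow(endo))
  names(dunn_tabs) <- rownames(endo)
  rows <- lapply(seq_len(nrow(endo)), function(i) {
    x <- endo[i, ]
    by_cohort <- lapply(split_cols, function(j) unname(x[j]))
    means <- vapply(by_cohort, mean, numeric(1))
    kw <- kruskal_wallis(by_cohort)
    dunn_tabs[[i]] <<- dunn_posthoc(by_cohort, adjust = adjust)
    det <- vapply(by_cohort, function(v)
      mean(v > detection$threshold) >= detection$min_fraction, logical(1))
    fc <- vapply(stages, function(st)
      fold_change(means[[st]], means[[control]])$fold_change, numeric(1))
    c(means, H = kw$H, p = kw$p, stats::setNames(fc, paste0("fc_", stages)),
      stats::setNames(as.numeric(det), paste0("det_", cohorts)))
  })
  res <- as.data.frame(do.call(rbind, rows))
  names(res)[seq_along(cohorts)] <- paste0("mean_", cohorts)
  res <- cbind(probe_id = rownames(endo), res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  det_cols <- paste0("det_", cohorts)
  res$group <- stratify(res, control = control, cohorts = cohorts, alpha = alpha)
  attr(res, "dunn") <- dunn_tabs
  attr(res, "cohorts") <- cohorts
  attr(res, "control") <- control
  class(res) <- c("de_result", "data.frame")
  res
}

#' Assign each probe to expression group 1, 2, 3 or none
#'
#' Applies the stratification rules on the detection flags and KW p-values of a
#' differential-expression table (see [differential_expression()] for the rule
#' definitions). Total function: every probe receives exactly one label.
#'
#' @param res data.frame with columns `det_<cohort>` (0/1) and `p`.
#' @param control reference cohort label.
#' @param cohorts all cohort labels in design order (control first).
#' @param alpha KW significance gate for group 1.
#' @return Character vector `group1|group2|group3|none`, one per row.
#' @export
stratify <- function(res, control = "Control",
                     cohorts = c("Control", "FIGO_I", "FIGO_III", "FIGO_IV"),
                     alpha = 0.05) {
  stages <- setdiff(cohorts, control)
  first_stage <- stages[1]
  det <- as.matrix(res[, paste0("det_", cohorts), drop = FALSE]) > 0
  colnames(det) <- cohorts
  vapply(seq_len(nrow(res)), function(i) {
    in_control <- det[i, control]
    in_stages <- det[i, stages]
    if (in_control && any(in_stages) && res$p[i] < alpha) return("group1")
    if (!in_control && in_stages[[first_stage]] && sum(in_stages) == 1)
      return("group2")
    if (!in_control && all(in_stages)) return("group3")
    "none"
  }, character(1))
}

#' Hierarchical clustering of differential miRNAs
#'
#' Rows are z-scored on log2(count + 1), distances are Euclidean, linkage is
#' average (UPGMA). Input rows are ordered lexicographically by probe id before
#' clustering so leaf order is deterministic under input permutation. Constant
#' rows (z-score undefined) are flagged and assigned the zero vector.
#'
#' @param counts numeric matrix of normalized counts for the differential
#'   probes (rownames = probe ids); at least 2 rows.
#' @param scale_rows z-score rows first (default TRUE).
#' @return A list: `hclust` (the [stats::hclust()] tree), `ordered` (matrix in
#'   dendrogram leaf order), `newick` (dendrogram as a Newick string),
#'   `constant_rows` (ids flagged).
#' @export
cluster_heatmap <- function(counts, scale_rows = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need >= 2 probes to cluster")
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  x <- log2(counts + 1)
  constant <- character(0)
  if (scale_rows) {
    sds <- apply(x, 1, stats::sd)
    constant <- rownames(x)[sds == 0]
    x <- t(scale(t(x)))
    x[sds == 0, ] <- 0
  }
  hc <- stats::hclust(stats::dist(x), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       ordered = counts[hc$order, , drop = FALSE],
       newick = ape::write.tree(phy),
       constant_rows = constant)
}
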