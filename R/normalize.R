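#' Background correction from negative-control probes
#'
#' Per sample, estimates nonspecific background as the mean plus two sample
#' standard deviations of the negative-control counts and subtracts that
#' threshold from every other probe, flooring at zero. This is the one-sided
#' upper bound of the negative-control distribution: subtracting the lower
#' bound would under-correct. Negative-control rows are consumed (dropped from
#' the output).
#'
#' @param m a [count_matrix()] with at least two negative-control probes.
#' @return A list: `counts` (background-corrected [count_matrix()] without
#'   negative rows) and `thresholds` (named per-sample numeric).
#' @examples
#' # negatives {1..5}: threshold 3 + 2*sd = 6.1623; a count of 100 -> 93.8377
#' @export
background_correct <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  neg <- probes_of_class(m, "negative")
  if (nrow(neg) < 2)
    stop("need >= 2 negative-control probes to estimate background sd")
  thresholds <- apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x))
  out <- drop_class(m, "negative")
  out$counts <- pmax(sweep(out$counts, 2, thresholds, `-`), 0)
  list(counts = out, thresholds = thresholds)
}

#' Per-sample control-probe scaling factor
#'
#' Shared arithmetic of the positive-control and housekeeping stages: summarize
#' each lane by the geometric mean g_s of its control counts (zeros replaced by
#' 1 before log-averaging), then scale lanes to a common level with
#' factor_s = center(g) / g_s where center is the across-lane arithmetic mean
#' (nCounter convention) or, optionally, geometric mean.
#' @noRd
scaling_factors <- function(ctrl_counts, center = c("arithmetic", "geometric")) {
  center <- match.arg(center)
  g <- apply(ctrl_counts, 2, geo_mean)
  num <- if (center == "arithmetic") mean(g) else exp(mean(log(g)))
  num / g
}

#' Positive-control (lane) normalization
#'
#' Corrects lane-by-lane technical variation using the spiked positive-control
#' ladder: each lane is summarized by the geometric mean of its positive-control
#' counts and scaled so all lanes share the across-lane mean level. Positive
#' rows are consumed.
#'
#' @param m a [count_matrix()] containing positive-control probes.
#' @param center across-lane center for the factor numerator, `"arithmetic"`
#'   (default, platform convention) or `"geometric"`.
#' @return A list: `counts` ([count_matrix()] without positive rows) and
#'   `factors` (named per-sample numeric, strictly positive).
#' @export
positive_control_normalize <- function(m, center = "arithmetic") {
  stopifnot(inherits(m, "count_matrix"))
  pos <- probes_of_class(m, "positive")
  if (nrow(pos) < 1) stop("no positive-control probes present")
  all_zero <- colSums(pos) == 0
  if (any(all_zero))
    stop("all positive controls zero in sample(s): ",
         paste(colnames(pos)[all_zero], collapse = ", "))
  factors <- scaling_factors(pos, center)
  out <- drop_class(m, "positive")
  out$counts <- sweep(out$counts, 2, factors, `*`)
  list(counts = out, factors = factors)
}

#' Housekeeping normalization
#'
#' Scales each lane by the geometric mean of its housekeeping miRNA counts
#' (default panel carries 10), bringing all lanes to the across-lane mean
#' housekeeping level. Housekeeping rows are retained in the output (flagged by
#' their probe class) and rescaled along with the endogenous counts, so the
#' stage is idempotent: re-running it on its own output gives unit factors.
#'
#' @param m a [count_matrix()] containing housekeeping probes.
#' @param hk_ids optional explicit housekeeping probe ids; default all probes
#'   of class `"housekeeping"`. Missing ids are an error.
#' @param center across-lane center, `"arithmetic"` (default) or
#'   `"geometric"`.
#' @return A list: `counts` ([count_matrix()]) and `factors` (named
#'   per-sample numeric).
#' @export
housekeeping_normalize <- function(m, hk_ids = NULL, center = "arithmetic") {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(hk_ids)) hk_ids <- names(m$probe_class)[m$probe_class == "housekeeping"]
  missing <- setdiff(hk_ids, rownames(m$counts))
  if (length(missing))
    stop("housekeeping probe(s) not present: ", paste(missing, collapse = ", "))
  if (!length(hk_ids)) stop("no housekeeping probes given")
  hk <- m$counts[hk_ids, , drop = FALSE]
  factors <- scaling_factors(hk, center)
  out <- m
  scaled <- m$probe_class %in% c("endogenous", "housekeeping")
  out$counts[scaled, ] <- sweep(m$counts[scaled, , drop = FALSE], 2, factors, `*`)
  list(counts = out, factors = factors)
}

#' Full three-stage normalization chain
#'
#' Applies, in this fixed order: negative-control background subtraction,
#' positive-control lane correction, housekeeping scaling. The order is part of
#' the contract and is recorded in the report.
#'
#' @param m a raw [count_matrix()] with all three control classes.
#' @param center across-lane center passed to both scaling stages.
#' @return A list: `counts` (normalized [count_matrix()]; endogenous +
#'   housekeeping rows) and `report`, a data.frame with per-sample
#'   `background_threshold`, `positive_factor`, `housekeeping_factor`, plus an
#'   attribute `stage_order`.
#' @export
normalize_counts <- function(m, center = "arithmetic") {
  bg <- background_correct(m)
  pc <- positive_control_normalize(bg$counts, center)
  hk <- housekeeping_normalize(pc$counts, center = center)
  report <- data.frame(sample = colnames(m$counts),
                       cohort = unname(m$cohort),
                       background_threshold = unname(bg$thresholds),
                       positive_factor = unname(pc$factors),
                       housekeeping_factor = unname(hk$factors),
                       stringsAsFactors = FALSE)
  attr(report, "stage_order") <- c("background", "positive", "housekeeping")
  list(counts = hk$counts, report = report)
}
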