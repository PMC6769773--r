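#' Panel definition for a hybridization-counting miRNA codeset
#'
#' Describes the probe content of the panel: endogenous miRNA probes,
#' negative-control probes (no target; estimate background), positive-control
#' probes (spiked synthetic targets on a geometric concentration ladder;
#' estimate lane scaling) and housekeeping miRNAs (assumed invariant; per-sample
#' normalization factor). Defaults mirror a 798-probe human miRNA panel with
#' 10 housekeeping probes and platform-conventional 6 negative / 6 positive
#' controls.
#'
#' @param n_endogenous number of endogenous probes (default 798).
#' @param n_negative number of negative-control probes (default 6).
#' @param n_positive number of positive-control probes (default 6).
#' @param n_housekeeping number of housekeeping probes (default 10).
#' @param positive_ladder nominal positive-control concentrations, strictly
#'   decreasing; default a geometric ladder 128, 32, 8, 2, 0.5, 0.125 scaled to
#'   counts internally.
#' @return A `panel_definition` list with id vectors and the ladder.
#' @examples
#' p <- panel_definition()
#' length(p$endogenous_ids)  # 798
#' @export
panel_definition <- function(n_endogenous = 798L, n_negative = 6L,
                             n_positive = 6L, n_housekeeping = 10L,
                             positive_ladder = 128 / 4^(0:(n_positive - 1))) {
  stopifnot(n_endogenous > 0, n_negative > 0, n_positive > 0, n_housekeeping > 0)
  if (length(positive_ladder) != n_positive)
    stop("positive_ladder length must equal n_positive")
  if (any(diff(positive_ladder) >= 0))
    stop("positive ladder must be strictly decreasing")
  p <- list(
    endogenous_ids   = sprintf("hsa-miR-sim-%04d", seq_len(n_endogenous)),
    negative_ids     = sprintf("NEG_%s", LETTERS[seq_len(n_negative)]),
    positive_ids     = sprintf("POS_%s", LETTERS[seq_len(n_positive)]),
    housekeeping_ids = sprintf("HK_%02d", seq_len(n_housekeeping)),
    positive_ladder  = positive_ladder)
  ids <- c(p$endogenous_ids, p$negative_ids, p$positive_ids, p$housekeeping_ids)
  if (anyDuplicated(ids)) stop("probe id sets must be pairwise disjoint")
  structure(p, class = "panel_definition")
}

#' Simulation configuration for synthetic panel counts
#'
#' Encodes the cohort design the pipeline assumes: four cohorts (healthy
#' Control plus FIGO I / III / IV ovarian-cancer stages), negative-binomial
#' counts with a shared per-lane scale factor, additive background, and three
#' planted miRNA expression patterns:
#' \describe{
#'   \item{group1}{present in every cohort; cohort-specific log2 effects vs
#'     Control (significantly differential).}
#'   \item{group2}{background-only except in FIGO I (expressed only in early
#'     stage).}
#'   \item{group3}{background-only in Control, expressed in all three FIGO
#'     stages.}
#' }
#' Planted effect lists are named numeric vectors `probe id -> log2 effect`;
#' the effect gives expression relative to `baseline_mean` in the cohorts where
#' the probe is "present" under its group's pattern.
#'
#' @param samples_per_cohort samples per cohort (default 6).
#' @param cohorts ordered cohort labels.
#' @param baseline_mean expected count of an unperturbed expressed probe.
#' @param dispersion negative-binomial size parameter; larger is closer to
#'   Poisson.
#' @param lane_scale_sd sd of the per-sample log-normal lane scale factor.
#' @param background_mean expected nonspecific background count.
#' @param planted_group1,planted_group2,planted_group3 named numeric vectors of
#'   log2 effects (see Details); ids must be endogenous and disjoint across
#'   groups.
#' @param hk_mean expected housekeeping probe count (invariant across cohorts).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(samples_per_cohort = 6L,
                              cohorts = c("Control", "FIGO_I", "FIGO_III", "FIGO_IV"),
                              baseline_mean = 50,
                              dispersion = 10,
                              lane_scale_sd = 0.3,
                              background_mean = 2,
                              planted_group1 = NULL,
                              planted_group2 = NULL,
                              planted_group3 = NULL,
                              hk_mean = 200) {
  stopifnot(samples_per_cohort >= 2, baseline_mean > 0, dispersion > 0,
            lane_scale_sd >= 0, background_mean >= 0, length(cohorts) >= 2)
  cfg <- list(samples_per_cohort = as.integer(samples_per_cohort),
              cohorts = as.character(cohorts),
              baseline_mean = baseline_mean, dispersion = dispersion,
              lane_scale_sd = lane_scale_sd, background_mean = background_mean,
              planted_group1 = planted_group1, planted_group2 = planted_group2,
              planted_group3 = planted_group3, hk_mean = hk_mean)
  structure(cfg, class = "simulation_config")
}

#' Default planted expression patterns
#'
#' Study-condition defaults mirroring the three differential groups reported
#' for the staged ovarian-cancer cohort design: 17 group-1 probes (16 planted
#' up at log2 effect 2, one down at -2, mirroring the single down-regulated
#' miRNA), 19 group-2 probes (log2 effect 2 in FIGO I only) and 9 group-3
#' probes (log2 effect 2 in all FIGO stages).
#'
#' @param panel a [panel_definition()].
#' @param effect log2 effect size for planted probes (default 2).
#' @return A list with elements `planted_group1/2/3` suitable for
#'   [simulation_config()].
#' @export
default_planted_groups <- function(panel = panel_definition(), effect = 2) {
  ids <- panel$endogenous_ids
  g1 <- ids[1:17]; g2 <- ids[18:36]; g3 <- ids[37:45]
  e1 <- stats::setNames(rep(effect, 17), g1)
  e1[17] <- -effect  # one down-regulated probe, like hsa-miR-584-5p
  list(planted_group1 = e1,
       planted_group2 = stats::setNames(rep(effect, 19), g2),
       planted_group3 = stats::setNames(rep(effect, 9), g3))
}

#' Simulate a probe-by-sample count matrix with known ground truth
#'
#' Draws negative-binomial counts under the cohort design of
#' [simulation_config()]. Per sample, a log-normal lane scale factor
#' `L_s = exp(N(0, lane_scale_sd))` multiplies the specific signal of every
#' probe in that lane (so positive-control correction is identifiable);
#' nonspecific background adds `background_mean` to every probe's expectation.
#' "Absent" probes (group 2/3 patterns outside their expressed cohorts) carry
#' background only, not structural zeros, so detection calls are exercised.
#' Positive controls follow the panel ladder times the lane scale with
#' negative-binomial noise at high size (tight); negative controls are
#' background-only.
#'
#' @param config a [simulation_config()].
#' @param panel a [panel_definition()].
#' @param seed integer; identical (config, panel, seed) gives byte-identical
#'   output.
#' @return A list with `counts` (a [count_matrix()]) and `truth`, a data.frame
#'   with one row per endogenous probe: `probe_id`, `group`
#'   (`group1|group2|group3|none`) and the true per-cohort mean columns.
#' @export
generate_counts <- function(config, panel = panel_definition(), seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "panel_definition"))
  planted <- list(group1 = config$planted_group1,
                  group2 = config$planted_group2,
                  group3 = config$planted_group3)
  planted_ids <- unlist(lapply(planted, names), use.names = FALSE)
  if (anyDuplicated(planted_ids))
    stop("planted probe lists must be disjoint across groups")
  unknown <- setdiff(planted_ids, panel$endogenous_ids)
  if (length(unknown))
    stop("planted probe ids not on the panel: ", paste(unknown, collapse = ", "))

  cohorts <- config$cohorts
  n_per <- config$samples_per_cohort
  sample_cohort <- rep(cohorts, each = n_per)
  sample_ids <- sprintf("S%02d_%s", seq_along(sample_cohort), sample_cohort)

  # true per-cohort mean of the specific (pre-lane, pre-background) signal
  expressed_in <- function(group, cohort) {
    switch(group,
           group1 = TRUE,
           group2 = cohort == "FIGO_I",
           group3 = cohort != "Control",
           none = TRUE)
  }
  truth <- data.frame(probe_id = panel$endogenous_ids, group = "none",
                      stringsAsFactors = FALSE)
  for (g in names(planted)) {
    if (!is.null(planted[[g]])) truth$group[match(names(planted[[g]]), truth$probe_id)] <- g
  }
  effect_of <- stats::setNames(rep(0, length(panel$endogenous_ids)), panel$endogenous_ids)
  for (g in names(planted)) if (!is.null(planted[[g]])) effect_of[names(planted[[g]])] <- planted[[g]]

  true_mean <- sapply(cohorts, function(co) {
    vapply(panel$endogenous_ids, function(p) {
      g <- truth$group[match(p, truth$probe_id)]
      base <- config$baseline_mean
      if (g == "none") return(base)
      if (!expressed_in(g, co)) return(0)
      # group1 effects apply in FIGO cohorts only (Control is the reference)
      if (g == "group1" && co == "Control") return(base)
      base * 2^effect_of[[p]]
    }, numeric(1))
  })
  colnames(true_mean) <- cohorts
  truth <- cbind(truth, as.data.frame(true_mean, check.names = FALSE))

  all_ids <- c(panel$endogenous_ids, panel$negative_ids,
               panel$positive_ids, panel$housekeeping_ids)
  probe_class <- c(rep("endogenous", length(panel$endogenous_ids)),
                   rep("negative", length(panel$negative_ids)),
                   rep("positive", length(panel$positive_ids)),
                   rep("housekeeping", length(panel$housekeeping_ids)))

  counts <- with_seed(seed, {
    lane <- exp(stats::rnorm(length(sample_ids), 0, config$lane_scale_sd))
    m <- matrix(0L, nrow = length(all_ids), ncol = length(sample_ids),
                dimnames = list(all_ids, sample_ids))
    bg <- config$background_mean
    size <- config$dispersion
    nb <- function(mu, size) {
      # dispersion -> Inf degenerates to Poisson; mu may be 0
      if (is.infinite(size)) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = size)
    }
    for (j in seq_along(sample_ids)) {
      co <- sample_cohort[j]
      mu_endo <- true_mean[, co] * lane[j] + bg
      m[panel$endogenous_ids, j] <- nb(mu_endo, size)
      m[panel$negative_ids, j] <-
        nb(rep(bg, length(panel$negative_ids)), size)
      # positives: tight counts around ladder x lane scale; x200 puts the
      # ladder at ~25..25600 counts, the magnitude span real spike-in
      # ladders cover, so the geometric mean estimates the lane scale well
      mu_pos <- panel$positive_ladder * 200 * lane[j] + bg
      m[panel$positive_ids, j] <- nb(mu_pos, 200)
      mu_hk <- rep(config$hk_mean, length(panel$housekeeping_ids)) * lane[j] + bg
      m[panel$housekeeping_ids, j] <- nb(mu_hk, size)
    }
    m
  })

  list(counts = count_matrix(counts, probe_class, sample_cohort),
       truth = truth,
       lane_scale = stats::setNames(
         with_seed(seed, exp(stats::rnorm(length(sample_ids), 0, config$lane_scale_sd))),
         sample_ids))
}
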