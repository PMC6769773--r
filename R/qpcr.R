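#' Ingest a raw Ct table, applying the determinable-range ceiling
#'
#' Cycle-threshold readings above the determinable range (`ceiling`, default
#' 45 cycles) and `"Undetermined"` tokens are assigned exactly the ceiling
#' value; a provenance flag records which records were censored this way.
#'
#' @param raw data.frame with columns `sample`, `assay`, `replicate`, `ct`
#'   (numeric or character; `"Undetermined"` allowed, case-insensitive) and
#'   optionally `cohort`.
#' @param ceiling determinable range in cycles (default 45).
#' @return A `ct_plate` data.frame with numeric `ct`, logical `censored`, and
#'   the ceiling in `attr(, "ceiling")`.
#' @export
ingest_ct <- function(raw, ceiling = 45) {
  stopifnot(ceiling > 0)
  need <- c("sample", "assay", "replicate", "ct")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  ct_chr <- trimws(as.character(raw$ct))
  undet <- tolower(ct_chr) %in% c("undetermined", "undet", "na", "")
  ct <- suppressWarnings(as.numeric(ct_chr))
  if (any(!undet & is.na(ct))) stop("unparseable Ct value(s)")
  if (any(ct < 0, na.rm = TRUE)) stop("negative Ct values are invalid")
  censored <- undet | (!is.na(ct) & ct > ceiling)
  ct[censored] <- ceiling
  out <- data.frame(sample = as.character(raw$sample),
                    cohort = if ("cohort" %in% names(raw))
                      as.character(raw$cohort) else NA_character_,
                    assay = as.character(raw$assay),
                    replicate = as.integer(raw$replicate),
                    ct = ct, censored = censored,
                    stringsAsFactors = FALSE)
  attr(out, "ceiling") <- ceiling
  class(out) <- c("ct_plate", "data.frame")
  out
}

#' Relative expression by the 2^-deltaCt method
#'
#' For one sample and assay: deltaCt = mean(replicate Ct of the assay) -
#' mean(replicate Ct of the reference assay); relative expression is
#' 2^-deltaCt. Replicate means are taken before differencing. An assay whose
#' replicates all sit at the ceiling keeps the arithmetic but is flagged
#' censored; a reference with all replicates at the ceiling is an error
#' (reference undetectable).
#'
#' @param plate a [ingest_ct()] plate.
#' @param sample sample id.
#' @param assay target assay id.
#' @param reference reference assay id (the internal-control miRNA).
#' @return List: `delta_ct`, `rq` (2^-deltaCt), `censored` (any target
#'   replicate at ceiling).
#' @examples
#' # target mean Ct 30, reference 25 -> deltaCt 5 -> rq = 0.03125
#' @export
relative_expression <- function(plate, sample, assay, reference) {
  stopifnot(inherits(plate, "ct_plate"))
  tgt <- plate[plate$sample == sample & plate$assay == assay, ]
  ref <- plate[plate$sample == sample & plate$assay == reference, ]
  if (!nrow(ref)) stop("reference assay '", reference,
                       "' not measured for sample ", sample)
  if (!nrow(tgt)) stop("assay '", assay, "' not measured for sample ", sample)
  if (all(ref$censored)) stop("reference undetectable (all replicates at ceiling) in sample ", sample)
  d <- mean(tgt$ct) - mean(ref$ct)
  list(delta_ct = d, rq = 2^(-d), censored = any(tgt$censored))
}

#' Relative expression for every (sample, assay) pair
#'
#' @param plate a [ingest_ct()] plate.
#' @param reference reference assay id.
#' @return data.frame: `sample`, `cohort`, `assay`, `delta_ct`, `rq`,
#'   `censored`; the reference assay itself is excluded.
#' @export
relative_expression_table <- function(plate, reference) {
  stopifnot(inherits(plate, "ct_plate"))
  assays <- setdiff(unique(plate$assay), reference)
  samples <- unique(plate$sample)
  grid <- expand.grid(sample = samples, assay = assays,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rq <- relative_expression(plate, grid$sample[i], grid$assay[i], reference)
    data.frame(sample = grid$sample[i],
               cohort = plate$cohort[match(grid$sample[i], plate$sample)],
               assay = grid$assay[i],
               delta_ct = rq$delta_ct, rq = rq$rq, censored = rq$censored,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance of qPCR validation against the panel results
#'
#' Re-tests each shared assay's 2^-deltaCt values across cohorts with
#' Kruskal-Wallis + Dunn and compares significance and direction of effect
#' against the panel's differential-expression call.
#'
#' @param rq_table output of [relative_expression_table()] with cohorts.
#' @param de a [differential_expression()] result.
#' @param assay_map named character vector mapping assay id -> panel probe id
#'   (default identity on shared ids).
#' @param control reference cohort label.
#' @param alpha significance level (default 0.05).
#' @return data.frame per assay: `assay`, `probe_id`, `p_qpcr`,
#'   `direction_qpcr`, `p_panel`, `direction_panel`, `censored_any`, `verdict`
#'   (`both-significant-same-direction`, `discordant`, `underpowered`).
#' @export
validate_against_panel <- function(rq_table, de, assay_map = NULL,
                                   control = "Control", alpha = 0.05) {
  if (is.null(assay_map)) {
    shared <- intersect(unique(rq_table$assay), de$probe_id)
    assay_map <- stats::setNames(shared, shared)
  }
  if (!length(assay_map)) stop("no shared assays between platforms")
  stages <- setdiff(unique(rq_table$cohort), control)
  rows <- lapply(names(assay_map), function(a) {
    probe <- assay_map[[a]]
    sub <- rq_table[rq_table$assay == a, ]
    by_cohort <- split(sub$rq, sub$cohort)
    by_cohort <- by_cohort[c(control, stages)]
    kw <- kruskal_wallis(by_cohort)
    dir_q <- sign(mean(unlist(by_cohort[stages])) - mean(by_cohort[[control]]))
    i <- match(probe, de$probe_id)
    fc_cols <- grep("^fc_", names(de), value = TRUE)
    dir_p <- sign(mean(unlist(de[i, fc_cols]), na.rm = TRUE))
    p_panel <- de$p[i]
    verdict <- if (isTRUE(kw$p < alpha && p_panel < alpha && dir_q == dir_p))
      "both-significant-same-direction"
    else if (isTRUE(xor(kw$p < alpha, p_panel < alpha)) ||
             isTRUE(kw$p < alpha && p_panel < alpha)) "discordant"
    else "underpowered"
    data.frame(assay = a, probe_id = probe, p_qpcr = kw$p,
               direction_qpcr = dir_q, p_panel = p_panel,
               direction_panel = dir_p,
               censored_any = any(sub$censored), verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
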