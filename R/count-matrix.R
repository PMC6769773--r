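#' Probe-by-sample count matrix with probe-class and cohort annotations
#'
#' The container every normalization stage transforms. Raw counts are
#' non-negative integers; normalized counts are non-negative reals. Each probe
#' carries a class (`endogenous`, `negative`, `positive`, `housekeeping`) and
#' each sample a cohort label.
#'
#' @param counts numeric matrix, probes in rows, samples in columns; rownames
#'   are probe ids, colnames sample ids.
#' @param probe_class character vector, one of `"endogenous"`, `"negative"`,
#'   `"positive"`, `"housekeeping"` per row of `counts`.
#' @param cohort character or factor vector, one cohort label per column.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `probe_class` (named by probe) and `cohort` (named by sample).
#' @export
count_matrix <- function(counts, probe_class, cohort) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have probe rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(probe_class) != nrow(counts))
    stop("probe_class length must match number of probes")
  if (length(cohort) != ncol(counts))
    stop("every sample needs a cohort label")
  probe_class <- as.character(probe_class)
  bad <- setdiff(unique(probe_class),
                 c("endogenous", "negative", "positive", "housekeeping"))
  if (length(bad))
    stop("unknown probe class: ", paste(bad, collapse = ", "))
  cohort <- as.character(cohort)
  if (anyNA(cohort)) stop("every sample needs a cohort label")
  structure(
    list(counts = counts,
         probe_class = stats::setNames(probe_class, rownames(counts)),
         cohort = stats::setNames(cohort, colnames(counts))),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "probes x", ncol(x$counts), "samples\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(table(x$probe_class)), table(x$probe_class)),
            collapse = ", "), "\n")
  cat("  cohorts:",
      paste(sprintf("%s=%d", names(table(x$cohort)), table(x$cohort)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by probe class
#' @noRd
probes_of_class <- function(m, cls) {
  m$counts[m$probe_class == cls, , drop = FALSE]
}

#' Drop probes of a class, keeping annotations in step
#' @noRd
drop_class <- function(m, cls) {
  keep <- m$probe_class != cls
  count_matrix(m$counts[keep, , drop = FALSE], m$probe_class[keep], m$cohort)
}
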