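# Plain-text dialects shared by the pipeline: count-matrix TSV (probe_id,
# probe_class, then one column per sample), cohort map TSV, Ct table TSV with
# an "Undetermined" token, edge-list TSVs, and standard GMT.

#' Write / read the count-matrix TSV dialect
#'
#' Rows are probes; the first two columns are `probe_id` and `probe_class`,
#' the remaining columns one sample each. The cohort map is written separately
#' as a two-column TSV (`sample`, `cohort`).
#'
#' @param m a [count_matrix()].
#' @param path output TSV path.
#' @param cohort_path optional cohort-map TSV path.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(m, path, cohort_path = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(probe_id = rownames(m$counts),
                   probe_class = unname(m$probe_class),
                   m$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort_path)) {
    utils::write.table(
      data.frame(sample = names(m$cohort), cohort = unname(m$cohort)),
      cohort_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_count_tsv
#' @param cohorts either a cohort-map TSV path or a named vector.
#' @export
read_count_tsv <- function(path, cohorts) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(cohorts) && length(cohorts) == 1 && file.exists(cohorts)) {
    cm <- utils::read.delim(cohorts, stringsAsFactors = FALSE)
    cohorts <- stats::setNames(cm$cohort, cm$sample)
  }
  samples <- setdiff(names(df), c("probe_id", "probe_class"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$probe_id
  count_matrix(counts, df$probe_class, cohorts[samples])
}

#' Write a Ct plate table with the Undetermined token preserved
#' @param plate raw plate ([generate_qpcr_plate()]) or ingested `ct_plate`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ct_tsv <- function(plate, path) {
  utils::write.table(as.data.frame(plate), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @param ceiling passed to [ingest_ct()].
#' @export
read_ct_tsv <- function(path, ceiling = 45) {
  ingest_ct(utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character"),
            ceiling = ceiling)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.
#'
#' @param collection a [gene_set_collection()].
#' @param path file path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe optional universe for the reader (default: union of sets).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, universe)
}

#' Write an igraph network as an edge-list TSV and optional GraphML
#' @param g igraph graph.
#' @param path edge-list TSV path.
#' @param graphml optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, graphml = NULL) {
  el <- igraph::as_edgelist(g)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  invisible(path)
}
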