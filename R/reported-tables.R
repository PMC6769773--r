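# Accessors for the published result tables of the staged ovarian-cancer
# plasma miRNA study the pipeline operationalizes. These printed lists are
# inputs (e.g. for target-set intersection and bookkeeping checks), shipped as
# plain TSV under extdata.

#' Reported differential miRNA group membership
#'
#' The published three-column listing of differential plasma miRNAs:
#' group 1 (significantly differentially expressed between controls and
#' patients), group 2 (expressed only in FIGO I stage patients), group 3
#' (expressed in patients of all stages but not controls). As printed,
#' hsa-miR-584-5p appears in both group 1 and group 2, so the printed columns
#' are not disjoint; the per-column counts are 17, 19 and 9 (45 entries in
#' total counting the duplicate once per column).
#'
#' @return data.frame with columns `group` (`group1|group2|group3`) and
#'   `mirna`.
#' @export
reported_mirna_groups <- function() {
  utils::read.delim(system.file("extdata", "reported_mirna_groups.tsv",
                                package = "plasmir"),
                    stringsAsFactors = FALSE)
}

#' Reported shared targets of the three miRNA groups
#'
#' The published shared-target listing: genes common to all three groups and
#' to each exclusive pair of groups, i.e. the multi-set regions of the
#' three-way Venn decomposition of the group target sets.
#'
#' @return data.frame with columns `region` (e.g. `"group1&group2&group3"`,
#'   `"group1&group2"`) and `gene`.
#' @export
reported_shared_targets <- function() {
  utils::read.delim(system.file("extdata", "reported_shared_targets.tsv",
                                package = "plasmir"),
                    stringsAsFactors = FALSE)
}

#' Reconstruct the group target sets implied by the reported shared targets
#'
#' Each group's (shared portion of its) target set is the union of every
#' reported region that names the group. Unique-to-one-group targets are not
#' published, so the reconstructed sets carry exactly the multi-set regions —
#' which is all that target-set intersection of the groups needs.
#'
#' @return Named list of character vectors (`group1`, `group2`, `group3`).
#' @export
reported_group_target_sets <- function() {
  tab <- reported_shared_targets()
  groups <- c("group1", "group2", "group3")
  sets <- lapply(groups, function(g)
    sort(unique(tab$gene[grepl(g, tab$region, fixed = TRUE)])))
  stats::setNames(sets, groups)
}
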