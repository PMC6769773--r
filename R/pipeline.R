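#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: output directory, root seed
#' (split deterministically per stage), significance level, detection rule,
#' evidence filter, and stage toggles. Simulation parameters come from a
#' [simulation_config()]; by default the planted patterns of
#' [default_planted_groups()] are used.
#'
#' @param outdir output directory (created if missing).
#' @param seed root RNG seed; each stage derives its own child seed from it.
#' @param alpha significance level used by the testing stages.
#' @param detection a [detection_rule()].
#' @param evidence evidence filter for the target network
#'   (`"any"|"strong"|"weak"`).
#' @param sim a [simulation_config()]; `NULL` for the study-condition default
#'   with planted groups.
#' @param panel a [panel_definition()].
#' @param stages character vector of stages to run, in fixed order; a subset
#'   of `c("simulate", "normalize", "de", "qpcr", "net", "enrich", "ppi")`.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, alpha = 0.05,
                       detection = detection_rule(),
                       evidence = "strong",
                       sim = NULL, panel = panel_definition(),
                       stages = c("simulate", "normalize", "de", "qpcr",
                                  "net", "enrich", "ppi")) {
  stopifnot(alpha > 0, alpha < 1)
  allowed <- c("simulate", "normalize", "de", "qpcr", "net", "enrich", "ppi")
  bad <- setdiff(stages, allowed)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim)) {
    planted <- default_planted_groups(panel)
    sim <- simulation_config(planted_group1 = planted$planted_group1,
                             planted_group2 = planted$planted_group2,
                             planted_group3 = planted$planted_group3)
  }
  structure(list(outdir = outdir, seed = as.integer(seed), alpha = alpha,
                 detection = detection, evidence = evidence, sim = sim,
                 panel = panel, stages = allowed[allowed %in% stages]),
            class = "run_config")
}

#' Run the full plasma-miRNA analysis pipeline
#'
#' Executes the stages in fixed order — simulate, normalize, differential
#' expression, qPCR validation, target network, enrichment, PPI — writing each
#' stage's outputs as plain-text files under `config$outdir` and returning a
#' machine-readable run report (also written as `report.json`). Re-running
#' with an identical config and seed reproduces identical outputs. A stage
#' failure aborts with the failing stage named; outputs of completed stages
#' are retained together with a `FAILED` marker file.
#'
#' @param config a [run_config()].
#' @return The run report, a list of per-stage counts and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("plasmir")),
                 seed = config$seed, alpha = config$alpha,
                 stages = config$stages, files = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(config$outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    invisible(ok)
  }

  run_stage("simulate", function() {
    sim <- generate_counts(config$sim, config$panel,
                           seed = child_seed(config$seed, "simulate"))
    state$sim <- sim
    f <- file.path(config$outdir, "counts_raw.tsv")
    write_count_tsv(sim$counts, f, file.path(config$outdir, "cohorts.tsv"))
    utils::write.table(sim$truth, file.path(config$outdir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$files$counts_raw <<- f
    report$simulate <<- list(probes = nrow(sim$counts$counts),
                             samples = ncol(sim$counts$counts),
                             planted = as.list(
                               vapply(c("group1", "group2", "group3"),
                                      function(g) sum(sim$truth$group == g),
                                      integer(1))))
  })

  run_stage("normalize", function() {
    norm <- normalize_counts(state$sim$counts)
    state$norm <- norm
    f <- file.path(config$outdir, "counts_norm.tsv")
    write_count_tsv(norm$counts, f)
    utils::write.table(norm$report, file.path(config$outdir, "normalization_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$files$counts_norm <<- f
    report$normalize <<- list(stage_order = attr(norm$report, "stage_order"))
  })

  run_stage("de", function() {
    de <- differential_expression(state$norm$counts,
                                  detection = config$detection,
                                  alpha = config$alpha)
    state$de <- de
    f <- file.path(config$outdir, "de_results.tsv")
    utils::write.table(as.data.frame(de), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    diff <- de[de$group != "none", ]
    if (nrow(diff) >= 2) {
      cl <- cluster_heatmap(state$norm$counts$counts[diff$probe_id, , drop = FALSE])
      writeLines(cl$newick, file.path(config$outdir, "dendrogram.nwk"))
      utils::write.table(cl$ordered, file.path(config$outdir, "heatmap_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    report$files$de <<- f
    report$de <<- list(n_tested = nrow(de),
                       n_group1 = sum(de$group == "group1"),
                       n_group2 = sum(de$group == "group2"),
                       n_group3 = sum(de$group == "group3"))
  })

  run_stage("qpcr", function() {
    de <- state$de
    # validate a handful of group-1 probes plus one flat probe, like a
    # targeted follow-up panel; reference level flat at 1
    g1 <- utils::head(de$probe_id[de$group == "group1"], 6)
    flat <- utils::head(de$probe_id[de$group == "none" &
                                    de$det_Control > 0 & de$p > 0.3], 1)
    assays <- c(g1, flat, "reference-miR")
    cohorts <- state$sim$counts$cohort
    truth <- state$sim$truth
    lev <- sapply(assays, function(a) {
      if (a == "reference-miR") return(rep(1, length(cohorts)))
      mu <- truth[match(a, truth$probe_id), unname(cohorts)]
      pmax(as.numeric(mu), 0.05) / max(truth[match(a, truth$probe_id), -(1:2)])
    })
    rownames(lev) <- names(cohorts)
    plate_raw <- generate_qpcr_plate(lev, cohort = unname(cohorts),
                                     seed = child_seed(config$seed, "qpcr"))
    f <- file.path(config$outdir, "ct_plate.tsv")
    write_ct_tsv(plate_raw, f)
    plate <- read_ct_tsv(f)
    rq <- relative_expression_table(plate, reference = "reference-miR")
    conc <- validate_against_panel(rq, de, alpha = config$alpha)
    utils::write.table(conc, file.path(config$outdir, "qpcr_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$files$qpcr <<- f
    report$qpcr <<- list(n_assays = length(assays) - 1,
                         n_concordant = sum(conc$verdict == "both-significant-same-direction"))
  })

  run_stage("net", function() {
    de <- state$de
    mirnas <- de$probe_id[de$group != "none"]
    groups <- split(de$probe_id[de$group != "none"], de$group[de$group != "none"])
    db <- generate_target_db(mirnas,
                             shared_core = c("MET", "SMAD7", "EZH2", "TERT", "IL6"),
                             groups = groups,
                             seed = child_seed(config$seed, "targets"))
    state$db <- db
    net <- build_network(mirnas, db, evidence = config$evidence)
    state$net <- net
    ranking <- rank_centrality(net)
    utils::write.table(ranking, file.path(config$outdir, "mirna_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    core <- core_network(net)
    write_network(core, file.path(config$outdir, "core_network.tsv"))
    sets <- lapply(groups, function(ms)
      sort(unique(db$gene[db$mirna %in% ms & db$evidence == "strong"])))
    state$target_sets <- sets
    venn <- intersect_target_sets(sets)
    venn_tab <- data.frame(region = names(venn$sizes),
                           size = unname(venn$sizes))
    utils::write.table(venn_tab, file.path(config$outdir, "venn_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$net <<- list(nodes = igraph::vcount(net),
                        edges = igraph::ecount(net),
                        venn_sizes = as.list(venn$sizes),
                        total_shared = venn$total_shared)
  })

  run_stage("enrich", function() {
    universe <- sort(unique(state$db$gene))
    coll <- generate_genesets(universe, seed = child_seed(config$seed, "genesets"))
    res_by_group <- lapply(state$target_sets, ora_test, collection = coll)
    buckets <- compare_groups(res_by_group, alpha = config$alpha)
    for (g in names(res_by_group)) {
      utils::write.table(res_by_group[[g]],
                         file.path(config$outdir, paste0("enrichment_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    state$enrichment <- res_by_group
    report$enrich <<- list(
      n_significant = vapply(res_by_group, function(r) sum(r$p < config$alpha),
                             integer(1)),
      shared_all = length(buckets$all))
  })

  run_stage("ppi", function() {
    seeds <- sort(unique(unlist(state$target_sets)))
    universe <- sort(unique(c(state$db$gene,
                              sprintf("PPIG%04d", 1:300))))
    inter <- generate_interactome(universe, n_edges = 2000,
                                  seed = child_seed(config$seed, "interactome"))
    g <- build_ppi(seeds, inter)
    mn <- minimum_network(g)
    hubs <- rank_hubs(mn)
    utils::write.table(hubs, file.path(config$outdir, "ppi_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(mn, file.path(config$outdir, "ppi_minimum.tsv"))
    report$ppi <<- list(nodes_full = igraph::vcount(g),
                        edges_full = igraph::ecount(g),
                        nodes_min = igraph::vcount(mn),
                        edges_min = igraph::ecount(mn),
                        top_hub = hubs$id[1])
  })

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
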