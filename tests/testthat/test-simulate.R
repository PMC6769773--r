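# Synthetic-data generators: panel structure, determinism, planted patterns,
# and the statistical structure downstream stages assume.

test_that("default panel carries 798 endogenous probes and disjoint id sets", {
  p <- panel_definition()
  expect_length(p$endogenous_ids, 798)
  expect_length(p$negative_ids, 6)
  expect_length(p$positive_ids, 6)
  expect_length(p$housekeeping_ids, 10)
  ids <- c(p$endogenous_ids, p$negative_ids, p$positive_ids, p$housekeeping_ids)
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(diff(p$positive_ladder) < 0))
})

test_that("generate_counts has the contracted shape and is seed-deterministic", {
  p <- panel_definition(n_endogenous = 50, n_negative = 4, n_positive = 4,
                        n_housekeeping = 5)
  cfg <- simulation_config(samples_per_cohort = 3)
  a <- generate_counts(cfg, p, seed = 42)
  b <- generate_counts(cfg, p, seed = 42)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_equal(dim(a$counts$counts), c(50 + 4 + 4 + 5, 4 * 3))
  c2 <- generate_counts(cfg, p, seed = 43)
  expect_false(identical(a$counts$counts, c2$counts$counts))
  # generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_counts(cfg, p, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null configuration recovers the baseline mean in expectation", {
  p <- panel_definition(n_endogenous = 400, n_negative = 4, n_positive = 4,
                        n_housekeeping = 5)
  cfg <- simulation_config(samples_per_cohort = 6, lane_scale_sd = 0,
                           background_mean = 0, dispersion = Inf)
  sim <- generate_counts(cfg, p, seed = 7)
  endo <- sim$counts$counts[sim$counts$probe_class == "endogenous", ]
  # Poisson(50) across 400 x 24 cells: overall mean within a few SEM of 50
  expect_lt(abs(mean(endo) - cfg$baseline_mean),
            4 * sqrt(cfg$baseline_mean / length(endo)))
})

test_that("planted patterns put signal only in their contracted cohorts", {
  p <- panel_definition(n_endogenous = 60, n_negative = 4, n_positive = 4,
                        n_housekeeping = 5)
  planted <- list(
    planted_group1 = stats::setNames(c(2, -2), p$endogenous_ids[1:2]),
    planted_group2 = stats::setNames(2, p$endogenous_ids[3]),
    planted_group3 = stats::setNames(2, p$endogenous_ids[4]))
  cfg <- do.call(simulation_config, planted)
  sim <- generate_counts(cfg, p, seed = 5)
  tr <- sim$truth
  g2 <- tr[tr$group == "group2", ]
  expect_equal(unname(unlist(g2[, c("Control", "FIGO_III", "FIGO_IV")])),
               c(0, 0, 0))
  expect_equal(g2$FIGO_I, 50 * 4)
  g3 <- tr[tr$group == "group3", ]
  expect_equal(g3$Control, 0)
  expect_true(all(g3[, c("FIGO_I", "FIGO_III", "FIGO_IV")] == 200))
  g1dn <- tr[tr$probe_id == p$endogenous_ids[2], ]
  expect_equal(g1dn$Control, 50)
  expect_equal(g1dn$FIGO_I, 50 / 4)
})

test_that("overlapping or unknown planted ids are configuration errors", {
  p <- panel_definition(n_endogenous = 10, n_negative = 3, n_positive = 3,
                        n_housekeeping = 3)
  dup <- simulation_config(
    planted_group1 = stats::setNames(2, p$endogenous_ids[1]),
    planted_group2 = stats::setNames(2, p$endogenous_ids[1]))
  expect_error(generate_counts(dup, p, seed = 1), "disjoint")
  unk <- simulation_config(planted_group1 = stats::setNames(2, "not-a-probe"))
  expect_error(generate_counts(unk, p, seed = 1), "not on the panel")
})

test_that("target database guarantees coverage, core intersection and determinism", {
  mirnas <- sprintf("miR-%02d", 1:9)
  groups <- split(mirnas, rep(c("g1", "g2", "g3"), each = 3))
  core <- c("MET", "SMAD7", "EZH2", "TERT", "IL6")
  db <- generate_target_db(mirnas, gene_universe_size = 200,
                           shared_core = core, groups = groups, seed = 3)
  expect_s3_class(db, "target_db")
  expect_true(all(mirnas %in% db$mirna))  # every miRNA has >= 1 target
  expect_equal(anyDuplicated(db[, c("mirna", "gene")]), 0L)
  sets <- lapply(groups, function(ms) unique(db$gene[db$mirna %in% ms]))
  venn <- intersect_target_sets(sets)
  expect_true(all(core %in% venn$regions[["g1&g2&g3"]]))
  db2 <- generate_target_db(mirnas, gene_universe_size = 200,
                            shared_core = core, groups = groups, seed = 3)
  expect_identical(db, db2)
  # boundary: one miRNA, exactly one edge
  one <- generate_target_db("miR-x", gene_universe_size = 50,
                            edges_per_mirna_range = c(1L, 1L), seed = 1)
  expect_equal(nrow(one), 1L)
  expect_error(generate_target_db(character(), seed = 1), "non-empty")
})

test_that("qPCR plates are deterministic and censor sub-detection levels", {
  lev <- matrix(c(1, 1, 1e-7, 1), nrow = 2,
                dimnames = list(c("s1", "s2"), c("ref", "tgt")))
  pl <- generate_qpcr_plate(lev, cohort = c("Control", "FIGO_I"),
                            replicate_sd = 0, seed = 2)
  # level 1e-7 -> expected Ct 30 + 23.3 > 45 -> Undetermined token
  expect_true(all(pl$ct[pl$sample == "s1" & pl$assay == "tgt"] == "Undetermined"))
  expect_true(all(pl$ct[pl$assay == "ref"] != "Undetermined"))
  pl2 <- generate_qpcr_plate(lev, cohort = c("Control", "FIGO_I"),
                             replicate_sd = 0, seed = 2)
  expect_identical(pl, pl2)
  expect_error(generate_qpcr_plate(matrix(0, 1, 1,
                                          dimnames = list("s", "a")),
                                   cohort = "Control", seed = 1),
               "positive")
})

test_that("gene-set and interactome generators respect sizes and seeds", {
  uni <- sprintf("G%03d", 1:120)
  gs <- generate_genesets(uni, n_sets = 5, set_size_range = c(5L, 10L), seed = 4)
  expect_s3_class(gs, "gene_set_collection")
  expect_true(all(lengths(gs$sets) >= 5 & lengths(gs$sets) <= 10))
  expect_error(generate_genesets(uni[1:5], set_size_range = c(10L, 20L), seed = 1),
               "universe")
  it <- generate_interactome(uni, n_edges = 150, hub_bias = 2, seed = 5)
  expect_equal(nrow(it), 150)
  expect_true(all(it$a != it$b))
  expect_equal(anyDuplicated(paste(it$a, it$b)), 0L)
  expect_identical(it, generate_interactome(uni, n_edges = 150, hub_bias = 2,
                                            seed = 5))
})

test_that("hub_bias = 0 gives a binomial-null degree distribution", {
  uni <- sprintf("G%03d", 1:300)
  it <- generate_interactome(uni, n_edges = 900, hub_bias = 0, seed = 8)
  g <- igraph::graph_from_data_frame(it, directed = FALSE)
  deg <- igraph::degree(g)[uni]
  deg[is.na(deg)] <- 0
  expected_mean <- 2 * 900 / 300
  expect_lt(abs(mean(deg) - expected_mean), 1e-9)  # handshake identity
  # at low edge density uniform endpoints give a binomial(2E, 1/N) degree
  # law; check mean/variance agreement and a chi-square GOF on pooled bins
  expect_lt(abs(stats::var(deg) / expected_mean - 1), 0.25)
  pbin <- stats::dbinom(0:8, size = 2 * 900, prob = 1 / 300)
  obs <- tabulate(pmin(deg, 8) + 1, nbins = 9)
  expected <- c(pbin[1:8], 1 - sum(pbin[1:8])) * 300
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, stats::qchisq(0.999, df = 8))
})
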