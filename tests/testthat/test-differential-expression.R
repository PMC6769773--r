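# Kruskal-Wallis, Dunn post hoc, fold change, stratification, clustering.

four_cohorts <- list(Control = c(1, 2, 3), FIGO_I = c(4, 5, 6),
                     FIGO_III = c(7, 8, 9), FIGO_IV = c(10, 11, 12))

test_that("KW statistic matches direct rank arithmetic on the 4x3 example", {
  kw <- kruskal_wallis(four_cohorts)
  # independent route: H from the rank-sum formula, no ties
  r <- rank(unlist(four_cohorts)); N <- 12
  H_direct <- 12 / (N * (N + 1)) *
    sum(tapply(r, rep(names(four_cohorts), each = 3), sum)^2 / 3) - 3 * (N + 1)
  expect_equal(kw$H, H_direct, tolerance = 1e-12)
  expect_equal(kw$H, 10.3846, tolerance = 1e-4)
  expect_equal(kw$p, stats::pchisq(kw$H, 3, lower.tail = FALSE))
})

test_that("all-tied input returns H = 0, p = 1; degenerate cohorts error", {
  expect_equal(kruskal_wallis(list(a = c(5, 5), b = c(5, 5, 5))),
               list(H = 0, p = 1, df = 1L))
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "observation")
  expect_error(kruskal_wallis(list(a = 1)), "2 cohorts")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(60)
  for (i in 1:20) {
    vals <- split(rnorm(24), rep(1:4, 6))
    h0 <- kruskal_wallis(vals)$H
    expect_equal(kruskal_wallis(lapply(vals, function(x) exp(3 * x)))$H, h0,
                 tolerance = 1e-10)
    expect_equal(kruskal_wallis(lapply(vals, function(x) atan(x) - 5))$H, h0,
                 tolerance = 1e-10)
  }
})

test_that("permutation oracle reproduces the enumerable exact p on the 4x3 example", {
  perm <- kruskal_wallis_permutation(four_cohorts, n_perm = 1e5, seed = 17)
  kw <- kruskal_wallis(four_cohorts)
  expect_equal(perm$H, kw$H, tolerance = 1e-10)  # two independent H routes
  # perfectly separated ranks: exactly the 4! block-to-label assignments of
  # 12!/(3!)^4 label sequences reach H >= 10.3846, so exact p = 24/369600
  exact <- 24 / 369600
  expect_gt(perm$p_perm, exact / 5)
  expect_lt(perm$p_perm, exact * 5)
  # both routes reject at the working threshold; the chi-square route is the
  # large-sample approximation and sits well above the exact far-tail p
  expect_lt(perm$p_perm, 0.05)
  expect_lt(kw$p, 0.05)
})

test_that("Dunn z matches the closed form, is antisymmetric, and caps adjusted p", {
  d <- dunn_posthoc(four_cohorts)
  z_ad <- d$z[d$group1 == "Control" & d$group2 == "FIGO_IV"]
  expect_equal(abs(z_ad), (11 - 2) / sqrt(13 * (2 / 3)), tolerance = 1e-10)
  expect_equal(abs(z_ad), 3.0571, tolerance = 1e-4)
  # antisymmetry via reversed cohort order
  d_rev <- dunn_posthoc(rev(four_cohorts))
  z_da <- d_rev$z[d_rev$group1 == "FIGO_IV" & d_rev$group2 == "Control"]
  expect_equal(z_da, -z_ad, tolerance = 1e-12)
  expect_true(all(d$p_adj >= d$p - 1e-15))
  expect_true(all(d$p_adj <= 1))
  expect_equal(d$p_adj, pmin(d$p * 6, 1), tolerance = 1e-12)
  # identical cohorts: z = 0, adjusted p = 1
  d0 <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_adj, 1)
  # holm never exceeds bonferroni
  dh <- dunn_posthoc(four_cohorts, adjust = "holm")
  expect_true(all(dh$p_adj <= d$p_adj + 1e-15))
})

test_that("fold change follows the relative-difference formula with sign", {
  expect_equal(fold_change(30, 10)$fold_change, 2)
  expect_equal(fold_change(10, 10)$fold_change, 0)
  expect_equal(fold_change(5, 10)$fold_change, -0.5)  # down-regulation
  fc0 <- fold_change(5, 0)
  expect_true(is.na(fc0$fold_change))
  expect_equal(fc0$flag, "control-absent")
})

test_that("stratification applies the group rules and stays disjoint", {
  det <- function(ctrl, f1, f3, f4, p) {
    data.frame(det_Control = ctrl, det_FIGO_I = f1, det_FIGO_III = f3,
               det_FIGO_IV = f4, p = p)
  }
  expect_equal(stratify(det(1, 1, 1, 1, 0.01)), "group1")
  expect_equal(stratify(det(1, 1, 1, 1, 0.2)), "none")   # detected but not significant
  expect_equal(stratify(det(0, 1, 0, 0, 0.5)), "group2") # FIGO I only
  expect_equal(stratify(det(0, 1, 1, 1, 0.5)), "group3") # all stages, no control
  expect_equal(stratify(det(0, 0, 1, 0, 0.01)), "none")  # FIGO III only
  expect_equal(stratify(det(0, 1, 1, 0, 0.01)), "none")  # two stages only
  # exhaustive disjointness: every detection/significance combination yields
  # exactly one label
  grid <- expand.grid(ctrl = 0:1, f1 = 0:1, f3 = 0:1, f4 = 0:1, p = c(0.01, 0.5))
  labs <- stratify(data.frame(det_Control = grid$ctrl, det_FIGO_I = grid$f1,
                              det_FIGO_III = grid$f3, det_FIGO_IV = grid$f4,
                              p = grid$p))
  expect_true(all(labs %in% c("group1", "group2", "group3", "none")))
  expect_length(labs, nrow(grid))
})

test_that("differential_expression recovers a planted effect end to end", {
  p <- panel_definition(n_endogenous = 30, n_negative = 4, n_positive = 4,
                        n_housekeeping = 5)
  cfg <- simulation_config(
    planted_group1 = stats::setNames(3, p$endogenous_ids[1]),
    planted_group2 = stats::setNames(3, p$endogenous_ids[2]),
    planted_group3 = stats::setNames(3, p$endogenous_ids[3]))
  sim <- generate_counts(cfg, p, seed = 14)
  de <- differential_expression(normalize_counts(sim$counts)$counts)
  expect_equal(de$group[match(p$endogenous_ids[1:3], de$probe_id)],
               c("group1", "group2", "group3"))
  # fold changes of the planted group-1 probe are positive at every stage
  expect_true(all(de[match(p$endogenous_ids[1], de$probe_id),
                     c("fc_FIGO_I", "fc_FIGO_III", "fc_FIGO_IV")] > 0))
  dunn <- attr(de, "dunn")[[p$endogenous_ids[1]]]
  expect_equal(nrow(dunn), 6)  # 4 cohorts -> 6 pairs
})

test_that("clustering is deterministic, merges identical rows first, and is
          permutation invariant", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 7, 2),
             d = c(0, 8, 1, 9))
  cl <- cluster_heatmap(m)
  expect_equal(cl$hclust$height[1], 0)            # identical rows at height 0
  expect_setequal(cl$hclust$labels[-cl$hclust$merge[1, ]], c("a", "b"))
  # permuting input rows leaves the dendrogram unchanged
  cl2 <- cluster_heatmap(m[c(3, 1, 4, 2), ])
  expect_identical(cl$newick, cl2$newick)
  # constant rows are flagged and zero-assigned, not dropped
  mc <- rbind(const = c(5, 5, 5, 5), x = c(1, 5, 9, 2), y = c(2, 1, 8, 4))
  cl3 <- cluster_heatmap(mc)
  expect_equal(cl3$constant_rows, "const")
  expect_equal(nrow(cl3$ordered), 3)
  expect_error(cluster_heatmap(m[1, , drop = FALSE]), ">= 2")
})

test_that("unscaled clustering merges the closest pair first", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 3), r3 = c(0, 10))
  cl <- cluster_heatmap(m, scale_rows = FALSE)
  # log2(count+1) rows: (0,0), (0,2), (0,3.459); closest pair is r2-r3
  expect_setequal(-cl$hclust$merge[1, ], which(rownames(m) %in% c("r2", "r3")))
})
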