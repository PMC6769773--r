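# Three-stage normalization: background subtraction, positive-control lane
# correction, housekeeping scaling.

test_that("background threshold is mean + 2 sd of negatives, floored at zero", {
  m <- tiny_count_matrix(endo = matrix(c(100, 5), 2, 1),
                         neg = matrix(1:5, 5, 1),
                         pos = matrix(50, 1, 1), hk = matrix(60, 1, 1))
  bg <- background_correct(m)
  t_exp <- 3 + 2 * stats::sd(1:5)
  expect_equal(unname(bg$thresholds), t_exp, tolerance = 1e-12)
  expect_equal(unname(bg$counts$counts["miR-1", 1]), 100 - t_exp)
  expect_equal(unname(bg$counts$counts["miR-2", 1]), 0)  # floored, not negative
  expect_false(any(bg$counts$probe_class == "negative"))
})

test_that("all-zero negatives give threshold 0 and identical lanes identical thresholds", {
  m <- tiny_count_matrix(endo = matrix(c(10, 10), 1, 2),
                         neg = matrix(0, 3, 2),
                         pos = matrix(5, 1, 2), hk = matrix(5, 1, 2))
  bg <- background_correct(m)
  expect_equal(unname(bg$thresholds), c(0, 0))
  expect_equal(unname(bg$counts$counts["miR-1", ]), c(10, 10))
  one_neg <- tiny_count_matrix(endo = matrix(1, 1, 1), neg = matrix(1, 1, 1),
                               pos = matrix(1, 1, 1), hk = matrix(1, 1, 1))
  expect_error(background_correct(one_neg), ">= 2 negative")
})

test_that("positive-control factors follow mean(g)/g_s and rescale lanes", {
  # two lanes with positive geometric means 100 and 400 -> factors 2.5, 0.625
  m <- tiny_count_matrix(endo = matrix(c(10, 10), 1, 2),
                         neg = matrix(0, 2, 2),
                         pos = matrix(c(50, 200, 200, 800), 2, 2),
                         hk = matrix(30, 1, 2))
  pc <- positive_control_normalize(m)
  expect_equal(unname(pc$factors), c(2.5, 0.625), tolerance = 1e-12)
  expect_equal(unname(pc$counts$counts["miR-1", ]), c(25, 6.25))
  expect_false(any(pc$counts$probe_class == "positive"))
  # identity: identical positives leave counts untouched
  m2 <- tiny_count_matrix(endo = matrix(c(7, 9), 1, 2), neg = matrix(0, 2, 2),
                          pos = matrix(100, 3, 2), hk = matrix(1, 1, 2))
  pc2 <- positive_control_normalize(m2)
  expect_equal(unname(pc2$factors), c(1, 1))
  # a lane of all-zero positives is an error naming the sample
  m3 <- tiny_count_matrix(endo = matrix(1, 1, 2), neg = matrix(0, 2, 2),
                          pos = matrix(c(10, 0), 1, 2), hk = matrix(1, 1, 2))
  expect_error(positive_control_normalize(m3), "S2")
})

test_that("doubling an entire lane is undone by positive-control normalization", {
  set.seed(31)
  endo <- matrix(rpois(40, 80), 10, 4)
  pos <- matrix(rpois(12, 200), 3, 4)
  hk <- matrix(rpois(8, 150), 2, 4)
  m <- tiny_count_matrix(endo, matrix(0, 2, 4), pos, hk)
  doubled <- m
  doubled$counts[, 2] <- doubled$counts[, 2] * 2
  a <- positive_control_normalize(m)
  b <- positive_control_normalize(doubled)
  ga <- apply(m$counts[grepl("POS", rownames(m$counts)), ], 2, function(x) exp(mean(log(x))))
  # lane 2's endogenous counts return to the original normalized values up to
  # the change the doubled lane induces in the across-lane mean numerator
  scale_shift <- mean(c(ga[1], 2 * ga[2], ga[3], ga[4])) / mean(ga)
  expect_equal(b$counts$counts[, 2] / scale_shift, a$counts$counts[, 2],
               tolerance = 1e-9)
})

test_that("housekeeping factors share the control-scaling arithmetic and flag rows", {
  m <- tiny_count_matrix(endo = matrix(c(8, 8), 1, 2), neg = matrix(0, 2, 2),
                         pos = matrix(10, 1, 2),
                         hk = matrix(c(50, 200), 1, 2))
  hk <- housekeeping_normalize(m)
  expect_equal(unname(hk$factors), c(2.5, 0.625), tolerance = 1e-12)
  expect_equal(unname(hk$counts$counts["miR-1", ]), c(20, 5))
  expect_true(any(hk$counts$probe_class == "housekeeping"))  # retained
  expect_error(housekeeping_normalize(m, hk_ids = "HK_9"), "HK_9")
  # scale equivariance: multiplying every housekeeping count by 7 leaves factors unchanged
  m7 <- m; m7$counts["HK_1", ] <- m7$counts["HK_1", ] * 7
  expect_equal(housekeeping_normalize(m7)$factors, hk$factors, tolerance = 1e-12)
})

test_that("re-running housekeeping normalization on its own output is a no-op", {
  set.seed(12)
  m <- tiny_count_matrix(matrix(rpois(60, 100), 15, 4), matrix(rpois(8, 3), 2, 4),
                         matrix(rpois(12, 400), 3, 4), matrix(rpois(16, 150), 4, 4))
  once <- normalize_counts(m)
  again <- housekeeping_normalize(once$counts)
  expect_equal(unname(again$factors), rep(1, 4), tolerance = 1e-9)
  expect_equal(attr(once$report, "stage_order"),
               c("background", "positive", "housekeeping"))
})

test_that("geometric-center factors have unit geometric mean", {
  set.seed(4)
  m <- tiny_count_matrix(matrix(rpois(40, 100), 10, 4), matrix(0, 2, 4),
                         matrix(rpois(12, 300), 3, 4), matrix(rpois(8, 100), 2, 4))
  pc <- positive_control_normalize(m, center = "geometric")
  expect_equal(exp(mean(log(pc$factors))), 1, tolerance = 1e-9)
})

test_that("estimated factors recover the inverse simulated lane scales", {
  p <- panel_definition(n_endogenous = 150, n_negative = 6, n_positive = 6,
                        n_housekeeping = 10)
  cfg <- simulation_config(samples_per_cohort = 6, lane_scale_sd = 0.3)
  sim <- generate_counts(cfg, p, seed = 21)
  norm <- normalize_counts(sim$counts)
  rho <- stats::cor(norm$report$positive_factor, 1 / sim$lane_scale,
                    method = "spearman")
  expect_gt(rho, 0.95)  # n = 24 lanes
})
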