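random_experiment <- function(n, p_tested = 0.8, p_conn = 0.3) {
  tested <- matrix(stats::runif(n * n) < p_tested, n, n)
  connected <- tested & matrix(stats::runif(n * n) < p_conn, n, n)
  diag(tested) <- diag(connected) <- FALSE
  connectivity_experiment(tested, connected)
}

test_that("connectivity rates reproduce the printed contingency arithmetic", {
  printed <- list(
    c(164, 3078, 5.33), c(103, 1733, 5.94), c(80, 1397, 5.73),
    c(3, 632, 0.47), c(22, 571, 3.85), c(93, 626, 14.9),
    c(80, 581, 13.8), c(56, 523, 10.7), c(37, 515, 7.18))
  for (p in printed) {
    r <- connectivity_rate(p[1], p[2])
    expect_equal(round(r$rate_pct, 2), round(p[3], 2), tolerance = 0.006)
  }
  expect_identical(connectivity_rate(0, 100)$rate_pct, 0)
})

test_that("connectivity rate is invariant to cell relabeling", {
  set.seed(30)
  e <- random_experiment(8)
  perm <- sample(8)
  e2 <- connectivity_experiment(e$tested[perm, perm],
                                e$connected[perm, perm])
  expect_identical(connectivity_rate(e)$rate_pct,
                   connectivity_rate(e2)$rate_pct)
})

test_that("label filters select pre/post subsets", {
  tested <- matrix(TRUE, 4, 4); diag(tested) <- FALSE
  connected <- matrix(FALSE, 4, 4)
  connected[1, 3] <- connected[2, 4] <- connected[3, 1] <- TRUE
  labels <- data.frame(cell_id = sprintf("c%02d", 1:4),
                       type = c("PC", "PC", "IN", "IN"))
  e <- connectivity_experiment(tested, connected, labels = labels)
  pc_in <- connectivity_rate(e, pre_filter = list(type = "PC"),
                             post_filter = list(type = "IN"))
  expect_identical(pc_in$k, 2L)
  expect_identical(pc_in$n, 4L)
})

test_that("fisher test matches printed p-values and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(164, 3078, 103, 1733), 0.394,
               tolerance = 0.0025)
  expect_equal(fisher_exact_2x2(164, 3078, 80, 1397), 0.619,
               tolerance = 0.0025)
  expect_equal(fisher_exact_2x2(37, 515, 164, 3078), 0.097,
               tolerance = 0.0025)
  # symmetric table: p = 1
  expect_equal(fisher_exact_2x2(5, 50, 5, 50), 1)
  # exact agreement with full enumeration for all small tables
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(2:100, 1); n2 <- sample(2:100, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_exact_2x2(k1, n1, k2, n2),
                 enum_fisher_p(k1, n1, k2, n2), tolerance = 1e-9)
  }
})

test_that("motif census matches hand enumeration on canonical graphs", {
  single <- matrix(FALSE, 3, 3); single[1, 2] <- TRUE
  expect_identical(unname(motif_census(single)),
                   c(0, 0, 0, 0, 0))
  full3 <- matrix(TRUE, 3, 3); diag(full3) <- FALSE
  cen <- motif_census(full3)
  expect_identical(unname(cen["reciprocal"]), 3)
  expect_identical(unname(cen["divergent"]), 3)
  expect_identical(unname(cen["convergent"]), 3)
  expect_identical(unname(cen["three_chain"]), 6)
  expect_true(all(motif_census(matrix(FALSE, 4, 4)) == 0))
})

test_that("census equals the brute-force oracle on 500 random graphs", {
  set.seed(32)
  for (i in 1:500) {
    n <- sample(2:6, 1)
    adj <- matrix(stats::runif(n * n) < stats::runif(1, 0.1, 0.8), n, n)
    diag(adj) <- FALSE
    expect_identical(unname(motif_census(adj)),
                     unname(as.numeric(brute_force_census(adj))))
  }
})

test_that("saturated skeletons give a degenerate bootstrap", {
  tested <- matrix(TRUE, 9, 9); diag(tested) <- FALSE
  set.seed(33)
  connected <- tested # every tested direction connected
  e <- connectivity_experiment(tested, connected)
  bs <- bootstrap_motifs(list(e), n_iter = 50, seed = 1)
  for (m in names(bs$observed)) {
    expect_true(all(bs$samples[, m] == bs$observed[m]))
  }
})

test_that("bootstrap on 2-cell experiments matches the hypergeometric", {
  # each experiment: 2 cells, both directions tested, 1 connection placed.
  # reciprocal count is 0 by construction per experiment; with k = 2 the
  # reciprocal probability is 1. Use k = 1 on a 3-cell skeleton instead:
  # 6 tested directions, place 2; P(reciprocal) = 3/15 (pairs of opposite
  # directions among C(6,2) placements)
  tested <- matrix(TRUE, 3, 3); diag(tested) <- FALSE
  connected <- matrix(FALSE, 3, 3); connected[1, 2] <- connected[2, 1] <- TRUE
  exps <- replicate(30, connectivity_experiment(tested, connected),
                    simplify = FALSE)
  bs <- bootstrap_motifs(exps, n_iter = 2000, seed = 2, min_cells = 3)
  p_recip <- 3 / choose(6, 2)
  expected <- 30 * p_recip
  mc_se <- sqrt(30 * p_recip * (1 - p_recip) / 2000)
  expect_lt(abs(mean(bs$samples[, "reciprocal"]) - expected), 4 * mc_se)
  # fixed seed: bit-identical
  bs2 <- bootstrap_motifs(exps, n_iter = 2000, seed = 2, min_cells = 3)
  expect_identical(bs$samples, bs2$samples)
})

test_that("bootstrap respects the tested-direction skeleton", {
  tested <- matrix(FALSE, 9, 9)
  tested[1, 2:5] <- TRUE # only out-edges of cell 1 are observable
  connected <- matrix(FALSE, 9, 9); connected[1, 2] <- TRUE
  e <- connectivity_experiment(tested, connected)
  bs <- bootstrap_motifs(list(e), n_iter = 100, seed = 3)
  expect_true(all(bs$samples[, "reciprocal"] == 0))
  expect_true(all(bs$samples[, "three_chain"] == 0))
})

test_that("the overall motif test is the plain chi-square", {
  obs <- c(10, 20, 30, 40, 50)
  expect_identical(motif_overall_test(obs, obs)$statistic, 0)
  expect_identical(motif_overall_test(obs, obs)$p_value, 1)
  exp_cnt <- c(12, 18, 33, 35, 52)
  mt <- motif_overall_test(obs, exp_cnt)
  expect_equal(mt$statistic, sum((obs - exp_cnt)^2 / exp_cnt))
  expect_identical(mt$df, 4L)
  expect_equal(mt$p_value,
               stats::pchisq(mt$statistic, 4, lower.tail = FALSE))
})

test_that("chi-square p-values are calibrated under the null", {
  # df = 4 reflects a fixed total across the five categories, as in the
  # bootstrap comparison; multinomial null counts must give uniform p
  set.seed(34)
  expected <- c(30, 25, 40, 20, 35)
  n_tot <- sum(expected)
  ps <- vapply(1:200, function(i) {
    obs <- as.numeric(stats::rmultinom(1, n_tot, expected / n_tot))
    motif_overall_test(obs, expected)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("degree distributions and the log-log fit behave", {
  # all-equal probabilities: one occupied value, fit undefined
  tested <- matrix(TRUE, 9, 9); diag(tested) <- FALSE
  connected <- matrix(FALSE, 9, 9)
  for (i in 1:9) connected[i, (i %% 9) + 1] <- TRUE
  e <- connectivity_experiment(tested, connected)
  dd <- degree_distribution(list(e))
  expect_false(dd$fit_in$defined)
  expect_true(all(dd$cells$p_in == 1 / 8))

  # heterogeneous synthetic sample: fit defined with a negative slope
  set.seed(35)
  exps <- lapply(1:20, function(i) random_experiment(12, 1, 0.08))
  dd2 <- degree_distribution(exps)
  expect_true(dd2$fit_out$defined)
  expect_lt(dd2$fit_out$slope, 0)
  expect_gt(dd2$fit_out$r_squared, 0.5)
})

test_that("experiments under the cell threshold are excluded", {
  small <- random_experiment(5)
  big <- random_experiment(10)
  dd <- degree_distribution(list(small, big))
  expect_identical(nrow(dd$cells), 10L)
})

test_that("hub detection applies the doubled-rate rule", {
  cells <- data.frame(
    cell_id = c("a", "b", "c"),
    p_in = c(0.20, 0.12, 0.05),
    p_out = c(0.20, 0.05, 0.20),
    tested_in = 10, tested_out = 10)
  h <- hub_detect(cells, overall_rate_pct = 5.33)
  # threshold 10.66 %: only cell a exceeds it in both directions
  expect_identical(h$n_hubs, 1L)
  expect_identical(h$hubs$cell_id, "a")
  expect_equal(h$threshold, 0.1066)
  expect_equal(h$expected_hubs, 3 * (2 / 3) * (2 / 3))

  none <- hub_detect(cells, overall_rate_pct = 25)
  expect_identical(none$n_hubs, 0L)
})

test_that("observed hub counts match independence on random graphs", {
  set.seed(36)
  exps <- lapply(1:26, function(i) random_experiment(12, 1, 0.053))
  dd <- degree_distribution(exps)
  rate <- connectivity_rate(exps)
  h <- hub_detect(dd$cells, rate$rate_pct)
  # binomial band around the independence expectation
  p_hat <- h$expected_hubs / nrow(dd$cells)
  band <- 3 * sqrt(nrow(dd$cells) * p_hat * (1 - p_hat))
  expect_lt(abs(h$n_hubs - h$expected_hubs), band + 3)
})

test_that("invalid experiments are refused", {
  tested <- matrix(FALSE, 3, 3)
  connected <- matrix(FALSE, 3, 3); connected[1, 2] <- TRUE
  expect_error(connectivity_experiment(tested, connected), "tested")
})
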