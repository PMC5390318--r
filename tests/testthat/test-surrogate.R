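blood_matrix <- function(rows) {
  ids <- sprintf("d%d_blood", seq_len(ncol(rows)))
  hand_beta(rows, sample_ids = ids)
}

test_that("blood-variable selection uses interpolated quantiles and a strict boundary", {
  vals <- rbind(rep(0.1, 8),                       # constant: excluded
                c(rep(0.10, 4), rep(0.15, 4)),     # range exactly 0.05: excluded
                seq(0.1, 0.8, by = 0.1))           # q10=0.17, q90=0.73: included
  b <- blood_matrix(vals)
  sheet <- sheet_from_ids(colnames(b))
  vp <- blood_variable_probes(b, sheet)
  expect_identical(vp$probe_id, "cg0003")
  expect_equal(vp$q_lo, 0.17)
  expect_equal(vp$q_hi, 0.73)
  expect_equal(vp$range, 0.56)
  # boundary probe: q90 - q10 is exactly 0.05
  q <- apply(vals[2, , drop = FALSE], 1, quantile, probs = c(0.1, 0.9), type = 7)
  expect_equal(unname(diff(q[, 1])), 0.05)
  # quantiles match the h = (n-1)p interpolation oracle
  set.seed(9)
  x <- runif(8)
  bq <- blood_variable_probes(blood_matrix(matrix(x, 1)), sheet,
                              analysis_config(variability_range_min = 0))
  expect_equal(bq$q_lo, oracle_quantile_type7(x, 0.1), tolerance = 1e-12)
  expect_equal(bq$q_hi, oracle_quantile_type7(x, 0.9), tolerance = 1e-12)
  expect_error(blood_variable_probes(b[, 1, drop = FALSE],
                                     sheet[1, , drop = FALSE]),
               "at least 2 blood samples")
})

test_that("enlarging the variability threshold never grows the selected set", {
  sim <- simulate_dataset(sim_config(n_probes = 400, seed = 14))
  prev <- NULL
  for (thr in c(0.02, 0.05, 0.1, 0.2)) {
    vp <- blood_variable_probes(sim$beta, sim$sample_sheet,
                                analysis_config(variability_range_min = thr))
    if (!is.null(prev)) expect_true(all(vp$probe_id %in% prev))
    prev <- vp$probe_id
  }
})

test_that("matched correlation reproduces closed-form anchor values", {
  donors <- sprintf("d%d", 1:8)
  ids <- c(paste0(donors, "_blood"), paste0(donors, "_retina"))
  base <- seq(0.1, 0.8, by = 0.1)
  b <- hand_beta(rbind(c(base, base),                    # identical: rho 1
                       c(base, rev(base))),              # reversed: rho -1
                 sample_ids = ids)
  sheet <- sheet_from_ids(ids)
  mc <- matched_probe_correlation(b, sheet, rownames(b), "retina")
  expect_equal(mc$rho, c(1, -1))
  expect_equal(mc$p_value, c(0, 0))
  expect_true(all(mc$selected))
  expect_identical(attr(mc, "p_method"), "t_approximation")
})

test_that("t-approximation p matches the incomplete-beta oracle", {
  # anchor: n = 8, rho = 0.5 -> t = 1.4142, p = 0.2070
  p <- oculoconcord:::spearman_p_t(0.5, 8L)
  expect_equal(0.5 * sqrt(6 / 0.75), sqrt(2), tolerance = 1e-12)
  expect_equal(p, 0.2070312, tolerance = 1e-6)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    rho <- runif(1, -0.99, 0.99)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    expect_equal(oculoconcord:::spearman_p_t(rho, n),
                 oracle_t_twosided_p(tt, n - 2), tolerance = 1e-10)
  }
})

test_that("exact permutation p agrees with cor.test on untied data", {
  set.seed(7)
  donors <- sprintf("d%d", 1:7)
  ids <- c(paste0(donors, "_blood"), paste0(donors, "_retina"))
  sheet <- sheet_from_ids(ids)
  for (i in 1:20) {
    x <- runif(7); y <- runif(7)
    b <- hand_beta(matrix(c(x, y), 1), sample_ids = ids)
    mc <- matched_probe_correlation(b, sheet, "cg0001", "retina", exact_p = TRUE)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(mc$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mc$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("donors lacking a matched pair are dropped with a warning", {
  ids <- c(sprintf("d%d_blood", 1:6), sprintf("d%d_retina", 1:5))
  set.seed(2)
  b <- hand_beta(matrix(runif(2 * 11), 2), sample_ids = ids)
  sheet <- sheet_from_ids(ids)
  expect_warning(mc <- matched_probe_correlation(b, sheet, rownames(b), "retina"),
                 "d6")
  expect_equal(unique(mc$n), 5L)
  expect_error(
    suppressWarnings(matched_probe_correlation(b[, -(8:11)], sheet[-(8:11), ],
                                               rownames(b), "retina")),
    "fewer than 4 donors")
})

test_that("permutation null is seeded, identity-free and centred", {
  sim <- simulate_dataset(sim_config(n_probes = 500, f_individual = 0,
                                     f_tissue = 0, seed = 50))
  vp <- blood_variable_probes(sim$beta, sim$sample_sheet)
  cfg <- analysis_config(n_null_permutations = 30, rng_seed = 123)
  n1 <- permutation_null(sim$beta, sim$sample_sheet, vp, "retina", cfg)
  n2 <- permutation_null(sim$beta, sim$sample_sheet, vp, "retina", cfg)
  expect_identical(n1$values, n2$values)
  expect_identical(length(n1$values), n1$n_probes * 30L)
  expect_lt(abs(mean(n1$values)), 0.05)
  # a different seed gives a different draw
  n3 <- permutation_null(sim$beta, sim$sample_sheet, vp, "retina",
                         analysis_config(n_null_permutations = 30, rng_seed = 124))
  expect_false(identical(n1$values, n3$values))
})

test_that("rank-sum comparison matches stats::wilcox.test", {
  set.seed(61)
  for (i in 1:100) {
    nx <- sample(5:40, 1); ny <- sample(5:40, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny, sample(c(0, 1), 1)), 1)
    got <- compare_to_null(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # equal distributions: p ~ 1; strong shift: p below 1e-15
  z <- rnorm(100)
  expect_gt(compare_to_null(z, z)$p_value, 0.99)
  a <- rnorm(1000); bb <- a + 0.5
  expect_lt(compare_to_null(bb, a)$p_value, 1e-15)
  expect_error(compare_to_null(rep(1, 5), rep(1, 9)), "tied")
})

test_that("common correlated probes are the cross-tissue intersection", {
  mk <- function(ids, sel) data.frame(probe_id = ids, selected = sel)
  r1 <- mk(c("a", "b", "c"), c(TRUE, TRUE, FALSE))
  r2 <- mk(c("a", "b", "c"), c(FALSE, TRUE, TRUE))
  expect_identical(common_correlated_probes(list(r1, r2)), "b")
  expect_identical(common_correlated_probes(list(r1, r1)), c("a", "b"))
  r3 <- mk(c("a", "b", "c"), c(FALSE, FALSE, TRUE))
  expect_length(common_correlated_probes(list(r1, r3)), 0)
})

test_that("paired similarity reproduces the paired-t oracle and flags", {
  donors <- sprintf("d%d", 1:8)
  ids <- c(paste0(donors, "_blood"), paste0(donors, "_retina"))
  sheet <- sheet_from_ids(ids)
  set.seed(71)
  A <- matrix(runif(100 * 8, 0.2, 0.8), 100)
  shift <- matrix(rnorm(100 * 8, 0, 0.01), 100)
  B <- pmin(pmax(A + shift, 0), 1)
  b <- hand_beta(cbind(A, B), sample_ids = ids)
  ps <- paired_similarity(b, sheet, "blood", "retina")
  for (i in sample(100, 25)) {
    expect_equal(ps$t[i], oracle_paired_t(A[i, ], B[i, ]), tolerance = 1e-12)
    expect_equal(ps$p_value[i],
                 oracle_t_twosided_p(oracle_paired_t(A[i, ], B[i, ]), 7),
                 tolerance = 1e-10)
  }
  expect_equal(ps$adj_p, oracle_bh(ps$p_value), tolerance = 1e-12)

  # identical tissues: zero mean difference, flagged similar
  b2 <- hand_beta(cbind(A[1:5, ], A[1:5, ]), sample_ids = ids)
  ps2 <- paired_similarity(b2, sheet, "blood", "retina")
  expect_true(all(ps2$zero_variance))
  expect_true(all(ps2$similar))
  expect_equal(ps2$mean_diff, rep(0, 5))

  # constant +0.3 shift with small difference sd: dissimilar
  A3 <- matrix(runif(5 * 8, 0.1, 0.3), 5)
  B3 <- A3 + 0.3 + matrix(rnorm(5 * 8, 0, 0.005), 5)
  b3 <- hand_beta(cbind(A3, B3), sample_ids = ids)
  ps3 <- paired_similarity(b3, sheet, "blood", "retina")
  expect_true(all(!ps3$similar))
  expect_true(all(!ps3$equivalent))
})
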