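sim_m <- function(n_probes = 300, seed = 9, ...) {
  sim <- simulate_dataset(sim_config(n_probes = n_probes, seed = seed, ...))
  list(sim = sim, m = beta_to_m(sim$beta))
}

test_that("PCA scores reconstruct the centered matrix and explain all variance", {
  s <- sim_m(200, seed = 13)
  pca <- run_pca(s$m)
  expect_equal(sum(pca$variance_explained), 100, tolerance = 1e-6)
  expect_true(all(diff(pca$variance_explained) <= 1e-9))
  centered <- scale(t(s$m), center = TRUE, scale = FALSE)
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-8,
               ignore_attr = TRUE)
  gram <- crossprod(pca$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in 1:5) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
})

test_that("a single variable probe puts all variance on PC1", {
  m <- hand_beta(rbind(seq(-2, 2, length.out = 6), rep(1, 6), rep(-0.5, 6)))
  pca <- run_pca(m)
  expect_equal(pca$variance_explained[1], 100, tolerance = 1e-9)
  # probes with missing values are dropped with a warning
  m2 <- m; m2[2, 3] <- NA
  expect_warning(p2 <- run_pca(m2), "missing")
  expect_identical(p2$probe_ids, rownames(m)[-2])
  expect_error(run_pca(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("PC-trait association matches the sums-of-squares oracle", {
  s <- sim_m(150, seed = 23)
  pca <- run_pca(s$m)
  assoc <- suppressWarnings(pc_trait_association(pca, s$sim$sample_sheet))
  expect_true(all(assoc$p_value >= 0 & assoc$p_value <= 1))
  expect_identical(unique(assoc$test[assoc$trait == "tissue"]), "anova")
  expect_identical(unique(assoc$test[assoc$trait == "age_at_death"]),
                   "linear_regression")
  for (comp in 1:4) {
    f_oracle <- oracle_anova_f(pca$scores[, comp], s$sim$sample_sheet$tissue)
    got <- assoc$statistic[assoc$component == comp & assoc$trait == "tissue"]
    expect_equal(got, f_oracle, tolerance = 1e-10)
  }
  # tissue separates PC1 essentially perfectly
  expect_lt(assoc$p_value[assoc$component == 1 & assoc$trait == "tissue"], 1e-20)
  # single-level traits are skipped with a warning
  sheet1 <- s$sim$sample_sheet
  sheet1$cause_of_death <- "cardiac"
  expect_warning(pc_trait_association(pca, sheet1, traits = c("tissue", "cause_of_death")),
                 "single level")
})

test_that("regression F p-values are calibrated under a pure-noise null", {
  set.seed(37)
  n <- 32
  hits <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    y <- rnorm(n)
    g <- sample(rep(letters[1:4], 8))
    hits <- hits + (oculoconcord:::oneway_anova(y, g)$p_value < 0.05)
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("exclusive-individual component selection follows its definition", {
  assoc <- data.frame(
    component = c(1, 1, 2, 2, 3, 3),
    trait = rep(c("donor_id", "tissue"), 3),
    test = "anova",
    p_value = c(0.01, 0.001,   # PC1: donor and tissue -> not exclusive
                0.01, 0.20,    # PC2: donor only -> exclusive
                0.30, 0.01))   # PC3: tissue only -> not exclusive
  expect_identical(individual_exclusive_components(assoc), 2)
  # at alpha = 0.25 the tissue p of 0.20 counts as significant, so no
  # component is exclusive
  expect_length(individual_exclusive_components(assoc, alpha = 0.25), 0)
  expect_error(individual_exclusive_components(assoc, individual_trait = "donor"),
               "donor")
})

test_that("probe-component correlation selects aligned probes only", {
  s <- sim_m(100, seed = 29, f_tissue = 0, f_individual = 0)
  pca <- run_pca(s$m)
  sc <- pca$scores[, 1]
  m2 <- rbind(s$m,
              aligned = 0.3 + 0.2 * sc[col(matrix(0, 1, length(sc)))],
              flat = rep(0.5, length(sc)))
  rownames(m2)[101:102] <- c("cg_aligned", "cg_flat")
  ip <- pc_associated_probes(m2, pca, 1)
  expect_true("cg_aligned" %in% ip$probe_id)
  r_aligned <- ip$r[ip$probe_id == "cg_aligned"]
  expect_gt(abs(r_aligned), 0.99)
  expect_false("cg_flat" %in% ip$probe_id)
  expect_identical(attr(ip, "n_zero_variance"), 1L)
})

test_that("moderated F collapses to ordinary ANOVA at d0 = 0 and to the prior at d0 = Inf", {
  s <- sim_m(120, seed = 41)
  sheet <- s$sim$sample_sheet
  plain <- tissue_specific_probes(s$m, sheet, prior_df = 0)
  for (i in sample(120, 20)) {
    expect_equal(plain$F[i], oracle_anova_f(s$m[i, ], sheet$tissue),
                 tolerance = 1e-10)
  }
  moderated <- tissue_specific_probes(s$m, sheet)
  d0 <- attr(moderated, "d0"); s02 <- attr(moderated, "s02")
  expect_gt(d0, 0)
  # full shrinkage: every posterior variance equals the prior, so the
  # moderated F is the between-tissue mean square over s0^2
  full <- tissue_specific_probes(s$m, sheet, prior_df = Inf, prior_var = s02)
  msb <- function(y, g) {
    grand <- mean(y); out <- 0
    for (lev in unique(g)) out <- out + sum(g == lev) * (mean(y[g == lev]) - grand)^2
    out / (length(unique(g)) - 1)
  }
  for (i in sample(120, 10)) {
    expect_equal(full$F[i], msb(s$m[i, ], sheet$tissue) / s02, tolerance = 1e-10)
  }
  # posterior variance interpolates between observed and prior
  s2 <- vapply(seq_len(nrow(s$m)), function(i) {
    y <- s$m[i, ]; g <- sheet$tissue
    sum((y - ave(y, g))^2) / (length(y) - length(unique(g)))
  }, numeric(1))
  post <- (d0 * s02 + 28 * s2) / (d0 + 28)
  expect_true(all(post >= pmin(s2, s02) - 1e-12))
  expect_true(all(post <= pmax(s2, s02) + 1e-12))
  expect_equal(moderated$F, (plain$F * s2) / post, tolerance = 1e-10)
})

test_that("moderated variance shrinkage matches limma's empirical Bayes", {
  s <- sim_m(400, seed = 53)
  sheet <- s$sim$sample_sheet
  got <- tissue_specific_probes(s$m, sheet)
  design <- stats::model.matrix(~ factor(sheet$tissue))
  fit <- limma::lmFit(s$m, design)
  fit <- limma::eBayes(fit)
  expect_equal(attr(got, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(got, "s02"), fit$s2.prior, tolerance = 1e-6)
  # limma's F over the tissue contrasts (excluding the intercept)
  tab <- limma::topTable(fit, coef = 2:4, number = Inf, sort.by = "none")
  expect_equal(got$F, unname(tab$F), tolerance = 1e-6)
  expect_equal(got$p_value, unname(tab$P.Value), tolerance = 1e-6)
  # posterior variances lie between the observed and prior variances
  d <- 32 - 4
  s2 <- fit$sigma^2
  post <- (fit$df.prior * fit$s2.prior + d * s2) / (fit$df.prior + d)
  expect_true(all(post >= pmin(s2, fit$s2.prior) - 1e-12))
  expect_true(all(post <= pmax(s2, fit$s2.prior) + 1e-12))
})

test_that("tissue-specific detection is sensitive with controlled FDR", {
  s <- sim_m(3000, seed = 67, f_tissue = 0.1, f_individual = 0)
  res <- tissue_specific_probes(s$m, s$sim$sample_sheet)
  truth <- s$sim$truth$probe_effect_class[res$probe_id]
  sens <- mean(res$significant[truth == "tissue"])
  fdr <- if (any(res$significant)) mean(truth[res$significant] != "tissue") else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})
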