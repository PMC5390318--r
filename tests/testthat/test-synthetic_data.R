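test_that("simulation is deterministic and leaves the session RNG alone", {
  cfg <- sim_config(n_probes = 200, seed = 99)
  set.seed(1); before <- runif(1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$sample_sheet, s2$sample_sheet)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$detection_p, s2$detection_p)
  expect_identical(s1$truth, s2$truth)
  set.seed(1)
  expect_identical(runif(1), before)
  # a different seed changes the data
  expect_false(identical(simulate_dataset(sim_config(n_probes = 200, seed = 100))$beta,
                         s1$beta))
})

test_that("with no variance sources every probe is constant across samples", {
  sim <- simulate_dataset(sim_config(n_probes = 50, f_tissue = 0,
                                     f_individual = 0, noise_sd = 0, seed = 3))
  expect_equal(ncol(sim$beta), 32L)
  rng <- apply(sim$beta, 1, function(x) diff(range(x)))
  expect_equal(rng, setNames(rep(0, 50), rownames(sim$beta)))
  # and per-probe values equal the recorded baseline
  expect_equal(sim$beta[, 1], sim$truth$baseline_beta, tolerance = 1e-12)
})

test_that("effect-class probe counts are exact, disjoint and labelled", {
  sim <- simulate_dataset(sim_config(n_probes = 20000, f_individual = 0.05,
                                     f_tissue = 0.10, seed = 17))
  cls <- sim$truth$probe_effect_class
  expect_identical(sum(cls == "individual"), 1000L)
  expect_identical(sum(cls == "tissue"), 2000L)
  # effect arrays are nonzero only for their class
  de <- sim$truth$donor_effects
  expect_true(all(de[cls != "individual", ] == 0))
  expect_true(all(rowSums(de[cls == "individual", ] != 0) > 0))
  te <- sim$truth$tissue_effects
  expect_true(all(te[cls != "tissue", ] == 0))
})

test_that("invalid simulation configs are rejected before sampling", {
  expect_error(sim_config(f_tissue = 0.7, f_individual = 0.5), "disjoint")
  expect_error(sim_config(f_snp = -0.1), "f_snp")
  expect_error(sim_config(class_weights = c(0.5, 0.5, 0.5)), "class_weights")
  D <- default_tissue_distance()
  D[1, 2] <- 99  # asymmetric
  expect_error(sim_config(tissue_distance = D), "symmetric")
})

test_that("detection failures and QC flags appear at the configured exact rates", {
  sim <- simulate_dataset(sim_config(n_probes = 1000, f_detection_fail = 0.01,
                                     f_cross_reactive = 0.05, f_snp = 0.02,
                                     seed = 5))
  expect_identical(sum(sim$annotation$cross_reactive), 50L)
  expect_identical(sum(sim$annotation$snp_flag), 20L)
  expect_identical(sum(sim$annotation$cross_reactive & sim$annotation$snp_flag), 0L)
  n_fail <- sum(sim$detection_p > 0.01)
  expect_equal(n_fail, round(0.01 * length(sim$detection_p)))
})

test_that("donor-shared effects raise matched blood-eye covariation monotonically", {
  rho_at <- function(f, seed) {
    sim <- simulate_dataset(sim_config(n_probes = 600, f_tissue = 0,
                                       f_individual = f, seed = seed))
    cls <- sim$truth$probe_effect_class
    ids <- names(cls)[cls == "individual"]
    if (!length(ids)) ids <- rownames(sim$beta)
    mc <- matched_probe_correlation(sim$beta, sim$sample_sheet, ids, "retina")
    mean(mc$rho, na.rm = TRUE)
  }
  for (seed in c(21, 22)) {
    lo <- rho_at(0.02, seed)
    hi <- rho_at(0.20, seed)
    null <- {
      sim <- simulate_dataset(sim_config(n_probes = 600, f_tissue = 0,
                                         f_individual = 0, seed = seed))
      mc <- matched_probe_correlation(sim$beta, sim$sample_sheet,
                                      rownames(sim$beta), "retina")
      mean(mc$rho, na.rm = TRUE)
    }
    expect_lt(abs(null), 0.1)
    expect_gt(lo, null)
    expect_gt(hi, 0.5)
  }
})

test_that("fixture bundles round-trip through disk and feed the pipeline", {
  sim <- simulate_dataset(sim_config(n_probes = 120, f_detection_fail = 0.005,
                                     seed = 8))
  dir <- withr::local_tempdir()
  write_fixture_bundle(sim, dir)
  prov <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  expect_identical(prov$seed, 8L)
  back <- read_fixture_bundle(dir)
  expect_equal(back$beta, sim$beta, tolerance = 1e-12)
  expect_equal(back$sample_sheet, sim$sample_sheet)
  expect_equal(back$annotation, sim$annotation)
  expect_equal(back$truth$donor_effects, sim$truth$donor_effects, tolerance = 1e-12)
  expect_identical(back$truth$probe_effect_class, sim$truth$probe_effect_class)
  expect_identical(unclass(back$config)[names(unclass(sim$config))],
                   unclass(sim$config))

  # the bundle drives a pipeline run through the inputs: section
  run <- suppressWarnings(suppressMessages(run_pipeline(
    list(seed = 8,
         inputs = list(beta = file.path(dir, "beta.tsv"),
                       sample_sheet = file.path(dir, "sample_sheet.csv"),
                       annotation = file.path(dir, "probe_annotation.tsv"),
                       detection_p = file.path(dir, "detection_p.tsv")),
         analysis = list(n_null_permutations = 5),
         stages = c("filter", "categories")),
    output_dir = withr::local_tempdir())))
  expect_identical(sort(run$stages_run), sort(c("load", "filter", "categories")))
  expect_length(run$errors, 0)
})

test_that("empirical tissue separations follow the configured distance ordering", {
  sim <- simulate_dataset(sim_config(n_probes = 4000, seed = 31))
  scm <- sample_pairwise_spearman(sim$beta)
  summ <- tissue_pair_summary(scm, sim$sample_sheet)
  cross <- summ[summ$tissue_a != summ$tissue_b, ]
  D <- sim$config$tissue_distance
  cross$dist <- mapply(function(a, b) D[a, b], cross$tissue_a, cross$tissue_b)
  # larger configured separation => lower between-tissue correlation
  expect_identical(order(cross$median_rho), order(-cross$dist))
  # blood is the most distinct tissue; rpe_choroid-optic_nerve the closest pair
  blood <- cross[cross$tissue_a == "blood" | cross$tissue_b == "blood", ]
  other <- cross[cross$tissue_a != "blood" & cross$tissue_b != "blood", ]
  expect_lt(max(blood$median_rho), min(other$median_rho))
  closest <- cross[which.max(cross$median_rho), ]
  expect_setequal(c(closest$tissue_a, closest$tissue_b),
                  c("rpe_choroid", "optic_nerve"))
})
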