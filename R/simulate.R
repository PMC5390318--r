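#' Default tissue effect-separation matrix
#'
#' Symmetric logit-scale separation between tissue methylation profiles used
#' by the simulator. The defaults encode the structure reported for matched
#' blood/eye methylation: blood is the most distinct tissue, blood resembles
#' RPE/choroid more than optic nerve and retina least, and RPE/choroid and
#' optic nerve are the most similar pair.
#'
#' @param tissues Tissue names; defaults beyond the four standard tissues get
#'   a generic separation of 2 from everything.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
default_tissue_distance <- function(tissues = c("blood", "retina",
                                                "rpe_choroid", "optic_nerve")) {
  d <- matrix(2, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  known <- rbind(
    c("blood", "retina", 4.0),
    c("blood", "optic_nerve", 3.2),
    c("blood", "rpe_choroid", 2.6),
    c("retina", "optic_nerve", 1.8),
    c("retina", "rpe_choroid", 1.4),
    c("rpe_choroid", "optic_nerve", 0.7))
  for (k in seq_len(nrow(known))) {
    a <- known[k, 1]; b <- known[k, 2]
    if (a %in% tissues && b %in% tissues) {
      d[a, b] <- d[b, a] <- as.numeric(known[k, 3])
    }
  }
  diag(d) <- 0
  d
}

#' Simulation configuration
#'
#' Defines the generative model for a matched multi-tissue methylation study:
#' per-probe bimodal baselines, a disjoint split of probes into tissue-effect
#' and donor-shared (mQTL-like) effect classes, logit-scale technical noise,
#' chip assignment and QC flag rates. Defaults emulate an 8-donor,
#' 4-tissue post-mortem design.
#'
#' @param n_probes Number of probes.
#' @param n_donors Number of donors (default 8).
#' @param tissues Ordered tissue names (default blood, retina, rpe_choroid,
#'   optic_nerve; blood must be present for downstream surrogate analyses).
#' @param class_weights Probabilities of the (hypo, intermediate, hyper)
#'   baseline mixture (default 0.4/0.2/0.4, a bimodal beta landscape).
#' @param f_tissue Fraction of probes with tissue effects; the count is exact
#'   (`round(f_tissue * n_probes)`), not binomial.
#' @param tissue_distance Symmetric matrix of expected logit-scale effect
#'   separations between tissues; see [default_tissue_distance()].
#' @param f_individual Fraction of probes with donor-shared effects (exact
#'   count); disjoint from the tissue-effect class.
#' @param individual_effect_sd Logit-scale standard deviation of donor-shared
#'   effects.
#' @param trimodal_genotype If `TRUE`, donor effects take mQTL-like trimodal
#'   levels `{-delta, 0, +delta}` with Hardy-Weinberg-like weights
#'   (0.25, 0.5, 0.25), `delta` scaled so the marginal sd equals
#'   `individual_effect_sd`; if `FALSE` (default) effects are Gaussian.
#' @param noise_sd Logit-scale sd of independent per-sample technical noise
#'   (default 0.3).
#' @param n_chips Number of chips; donors are assigned round-robin.
#' @param f_detection_fail Fraction of matrix cells given a failing detection
#'   p-value drawn uniformly from (0.01, 1].
#' @param f_cross_reactive,f_snp Fractions of probes flagged cross-reactive /
#'   SNP-affected (exact counts, disjoint sets when feasible). Defaults
#'   mirror the removal proportions typical for HM450K QC blacklists.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000,
                       n_donors = 8,
                       tissues = c("blood", "retina", "rpe_choroid", "optic_nerve"),
                       class_weights = c(hypo = 0.4, intermediate = 0.2, hyper = 0.4),
                       f_tissue = 0.10,
                       tissue_distance = default_tissue_distance(tissues),
                       f_individual = 0.05,
                       individual_effect_sd = 1.5,
                       trimodal_genotype = FALSE,
                       noise_sd = 0.3,
                       n_chips = 3,
                       f_detection_fail = 0,
                       f_cross_reactive = 0.057,
                       f_snp = 0.017,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_donors = as.integer(n_donors),
              tissues = as.character(tissues),
              class_weights = as.numeric(class_weights),
              f_tissue = as.numeric(f_tissue),
              tissue_distance = tissue_distance,
              f_individual = as.numeric(f_individual),
              individual_effect_sd = as.numeric(individual_effect_sd),
              trimodal_genotype = isTRUE(trimodal_genotype),
              noise_sd = as.numeric(noise_sd),
              n_chips = as.integer(n_chips),
              f_detection_fail = as.numeric(f_detection_fail),
              f_cross_reactive = as.numeric(f_cross_reactive),
              f_snp = as.numeric(f_snp),
              seed = as.integer(seed))
  names(cfg$class_weights) <- c("hypo", "intermediate", "hyper")
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_probes < 1L) stop("n_probes must be >= 1", call. = FALSE)
  if (cfg$n_donors < 1L) stop("n_donors must be >= 1", call. = FALSE)
  if (anyDuplicated(cfg$tissues) || !length(cfg$tissues)) {
    stop("tissues must be a non-empty vector of unique names", call. = FALSE)
  }
  if (length(cfg$class_weights) != 3L || any(cfg$class_weights < 0) ||
      abs(sum(cfg$class_weights) - 1) > 1e-8) {
    stop("class_weights must be 3 nonnegative proportions summing to 1",
         call. = FALSE)
  }
  for (nm in c("f_tissue", "f_individual", "f_detection_fail",
               "f_cross_reactive", "f_snp")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("%s must lie in [0,1]", nm), call. = FALSE)
    }
  }
  if (cfg$f_tissue + cfg$f_individual > 1) {
    stop("f_tissue + f_individual must not exceed 1 (effect classes are disjoint)",
         call. = FALSE)
  }
  D <- cfg$tissue_distance
  Tn <- length(cfg$tissues)
  if (!is.matrix(D) || nrow(D) != Tn || ncol(D) != Tn) {
    stop("tissue_distance must be a square matrix over the tissues", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0) || any(D < 0)) {
    stop("tissue_distance must be symmetric, nonnegative, with zero diagonal",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$individual_effect_sd < 0) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  if (cfg$n_chips < 1L) stop("n_chips must be >= 1", call. = FALSE)
  invisible(cfg)
}

# Baseline beta draws per methylation class: hypo concentrated below 0.1,
# hyper above 0.9, intermediate strictly inside (0.2, 0.8).
draw_baseline_beta <- function(class) {
  n <- length(class)
  b <- numeric(n)
  hy <- class == "hypo"; hr <- class == "hyper"; im <- class == "intermediate"
  b[hy] <- stats::rbeta(sum(hy), 2, 40)
  b[hr] <- stats::rbeta(sum(hr), 40, 2)
  b[im] <- 0.2 + 0.6 * stats::rbeta(sum(im), 2, 2)
  b
}

# Low-dimensional tissue coordinates whose pairwise euclidean distances
# approximate the target separation matrix (classical MDS embedding).
tissue_coordinates <- function(D) {
  Tn <- nrow(D)
  if (Tn == 1L) return(matrix(0, 1, 1, dimnames = list(rownames(D), NULL)))
  # degenerate (low-rank) separation matrices are expected; keep the
  # positive-eigenvalue coordinates silently
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = Tn - 1L,
                                          eig = TRUE))
  keep <- mds$eig[seq_len(ncol(mds$points))] > 1e-9 * max(mds$eig)
  xy <- mds$points[, keep, drop = FALSE]
  rownames(xy) <- rownames(D)
  xy
}

#' Simulate a matched multi-tissue methylation dataset
#'
#' Generative model (all effects on the logit scale, inverse-logit back to
#' beta): each probe draws a baseline class and baseline beta; a fixed,
#' disjoint subset of probes receives per-tissue offsets whose pairwise
#' separations scale with `tissue_distance` (random direction through a
#' low-dimensional tissue embedding); another fixed subset receives a donor
#' offset identical across that donor's tissues (Gaussian or mQTL-like
#' trimodal); independent Gaussian technical noise is added per sample.
#' Donors are assigned to chips round-robin; the detection p-value matrix is
#' near zero except for a configured fraction of failing cells; annotation
#' flags and genomic-context categories are drawn from fixed categorical
#' distributions. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `meth_simulation`: a list with elements
#'   `beta` (probes x samples matrix), `sample_sheet`, `annotation`,
#'   `detection_p` (same shape as `beta`), `truth` (ground-truth labels:
#'   `probe_effect_class`, `baseline_class`, `baseline_beta`,
#'   `tissue_effects`, `donor_effects`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_probes
    tissues <- cfg$tissues
    Tn <- length(tissues)
    donors <- sprintf("D%02d", seq_len(cfg$n_donors))
    probe_ids <- sprintf("cg%08d", seq_len(n))

    baseline_class <- sample(METH_CLASSES, n, replace = TRUE,
                             prob = cfg$class_weights)
    baseline_beta <- draw_baseline_beta(baseline_class)
    baseline_logit <- logit(baseline_beta)

    # exact effect-class counts, disjoint by construction
    n_tis <- round(cfg$f_tissue * n)
    n_ind <- round(cfg$f_individual * n)
    shuffled <- sample.int(n)
    tissue_idx <- sort(shuffled[seq_len(n_tis)])
    indiv_idx <- sort(shuffled[n_tis + seq_len(n_ind)])
    probe_effect_class <- rep("none", n)
    probe_effect_class[tissue_idx] <- "tissue"
    probe_effect_class[indiv_idx] <- "individual"

    tissue_effects <- matrix(0, n, Tn, dimnames = list(probe_ids, tissues))
    if (n_tis > 0 && Tn > 1) {
      coords <- tissue_coordinates(cfg$tissue_distance)
      d <- ncol(coords)
      U <- matrix(stats::rnorm(n_tis * d), n_tis, d)
      U <- U / sqrt(rowSums(U^2))
      mag <- 0.5 + stats::rgamma(n_tis, shape = 4, rate = 4)
      off <- (U %*% t(coords)) * mag
      off <- off - rowMeans(off)
      tissue_effects[tissue_idx, ] <- off
    }

    donor_effects <- matrix(0, n, cfg$n_donors,
                            dimnames = list(probe_ids, donors))
    if (n_ind > 0) {
      if (cfg$trimodal_genotype) {
        delta <- cfg$individual_effect_sd * sqrt(2)
        eff <- sample(c(-delta, 0, delta), n_ind * cfg$n_donors,
                      replace = TRUE, prob = c(0.25, 0.5, 0.25))
      } else {
        eff <- stats::rnorm(n_ind * cfg$n_donors, sd = cfg$individual_effect_sd)
      }
      donor_effects[indiv_idx, ] <- matrix(eff, n_ind, cfg$n_donors)
    }

    sample_donor <- rep(donors, times = Tn)
    sample_tissue <- rep(tissues, each = cfg$n_donors)
    sample_ids <- paste(sample_donor, sample_tissue, sep = "_")

    L <- matrix(baseline_logit, n, length(sample_ids))
    L <- L + tissue_effects[, sample_tissue, drop = FALSE]
    L <- L + donor_effects[, sample_donor, drop = FALSE]
    if (cfg$noise_sd > 0) {
      L <- L + matrix(stats::rnorm(length(L), sd = cfg$noise_sd), nrow(L))
    }
    beta <- inv_logit(L)
    dimnames(beta) <- list(probe_ids, sample_ids)

    detp <- matrix(stats::runif(length(beta), 0, 1e-4), nrow(beta),
                   dimnames = dimnames(beta))
    n_fail <- round(cfg$f_detection_fail * length(beta))
    if (n_fail > 0) {
      cells <- sample.int(length(beta), n_fail)
      detp[cells] <- stats::runif(n_fail, 0.01, 1)
    }

    # annotation: fixed categorical distributions loosely matching HM450K
    feature_class <- sample(FEATURE_CLASSES, n, replace = TRUE,
                            prob = c(0.10, 0.14, 0.12, 0.05, 0.34, 0.05, 0.20))
    island_relation <- sample(ISLAND_RELATIONS, n, replace = TRUE,
                              prob = c(0.31, 0.23, 0.10, 0.36))
    chromosome <- sample(CHROMOSOMES, n, replace = TRUE,
                         prob = c(rep(0.97 / 22, 22), 0.025, 0.005))
    n_cr <- round(cfg$f_cross_reactive * n)
    n_snp <- round(cfg$f_snp * n)
    cross_reactive <- rep(FALSE, n)
    snp_flag <- rep(FALSE, n)
    flag_pool <- sample.int(n)
    cross_reactive[flag_pool[seq_len(n_cr)]] <- TRUE
    if (n_cr + n_snp <= n) {
      snp_flag[flag_pool[n_cr + seq_len(n_snp)]] <- TRUE
    } else {
      snp_flag[sample.int(n, n_snp)] <- TRUE
    }
    annotation <- data.frame(probe_id = probe_ids, chromosome = chromosome,
                             feature_class = feature_class,
                             island_relation = island_relation,
                             cross_reactive = cross_reactive,
                             snp_flag = snp_flag,
                             stringsAsFactors = FALSE)

    age <- pmin(pmax(round(stats::rnorm(cfg$n_donors, 60.6, 11.3)), 37), 76)
    cod <- sample(c("cardiac", "cerebrovascular", "respiratory", "trauma"),
                  cfg$n_donors, replace = TRUE)
    pres <- round(stats::runif(cfg$n_donors, 2, 12), 1)
    chip <- sprintf("chip%02d", ((seq_len(cfg$n_donors) - 1L) %% cfg$n_chips) + 1L)
    sheet <- data.frame(sample_id = sample_ids, donor_id = sample_donor,
                        tissue = sample_tissue,
                        chip = chip[match(sample_donor, donors)],
                        age_at_death = age[match(sample_donor, donors)],
                        cause_of_death = cod[match(sample_donor, donors)],
                        preservation_interval = pres[match(sample_donor, donors)],
                        stringsAsFactors = FALSE)

    validate_beta_matrix(beta)
    validate_sample_sheet(sheet)
    validate_probe_annotation(annotation)

    structure(list(
      beta = beta,
      sample_sheet = sheet,
      annotation = annotation,
      detection_p = detp,
      truth = list(probe_effect_class = stats::setNames(probe_effect_class, probe_ids),
                   baseline_class = stats::setNames(baseline_class, probe_ids),
                   baseline_beta = stats::setNames(baseline_beta, probe_ids),
                   tissue_effects = tissue_effects,
                   donor_effects = donor_effects),
      config = cfg), class = "meth_simulation")
  })
}

#' @export
print.meth_simulation <- function(x, ...) {
  cat(sprintf("Simulated methylation dataset: %d probes x %d samples (%d donors, %d tissues)\n",
              nrow(x$beta), ncol(x$beta), x$config$n_donors,
              length(x$config$tissues)))
  cat(sprintf("  effect classes: %d tissue, %d individual, %d none; seed %d\n",
              sum(x$truth$probe_effect_class == "tissue"),
              sum(x$truth$probe_effect_class == "individual"),
              sum(x$truth$probe_effect_class == "none"), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Writes the beta matrix, detection p-value matrix, sample sheet, probe
#' annotation and ground-truth tables as TSV/CSV into `dir`, plus a
#' `provenance.yaml` recording the full simulation configuration (including
#' the seed). Every file is re-readable by the package's readers.
#'
#' @param sim A `meth_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named list of file paths written.
#' @seealso [read_fixture_bundle()]
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- config_hash(sim_config_as_list(sim$config))
  meta <- list(config_hash = hash, seed = sim$config$seed)
  paths <- list(
    beta = file.path(dir, "beta.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    annotation = file.path(dir, "probe_annotation.tsv"),
    truth_probes = file.path(dir, "truth_probes.tsv"),
    truth_tissue_effects = file.path(dir, "truth_tissue_effects.tsv"),
    truth_donor_effects = file.path(dir, "truth_donor_effects.tsv"),
    provenance = file.path(dir, "provenance.yaml"))
  write_beta_matrix(sim$beta, paths$beta, meta = meta)
  write_beta_matrix(sim$detection_p, paths$detection_p, meta = meta)
  write_sample_sheet(sim$sample_sheet, paths$sample_sheet, meta = meta)
  write_probe_annotation(sim$annotation, paths$annotation, meta = meta)
  tp <- data.frame(probe_id = rownames(sim$beta),
                   effect_class = unname(sim$truth$probe_effect_class),
                   baseline_class = unname(sim$truth$baseline_class),
                   baseline_beta = unname(sim$truth$baseline_beta),
                   stringsAsFactors = FALSE)
  write_tsv_report(tp, paths$truth_probes, meta = meta)
  write_tsv_report(cbind(data.frame(probe_id = rownames(sim$truth$tissue_effects)),
                         as.data.frame(sim$truth$tissue_effects)),
                   paths$truth_tissue_effects, meta = meta)
  write_tsv_report(cbind(data.frame(probe_id = rownames(sim$truth$donor_effects)),
                         as.data.frame(sim$truth$donor_effects)),
                   paths$truth_donor_effects, meta = meta)
  yaml::write_yaml(sim_config_as_list(sim$config), paths$provenance)
  invisible(paths)
}

sim_config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$tissue_distance <- apply(out$tissue_distance, 1, as.list, simplify = FALSE)
  out
}

sim_config_from_list <- function(lst) {
  if (!is.null(lst$tissue_distance) && !is.matrix(lst$tissue_distance)) {
    tis <- as.character(lst$tissues)
    D <- matrix(unlist(lst$tissue_distance), length(tis), length(tis),
                byrow = TRUE, dimnames = list(tis, tis))
    lst$tissue_distance <- D
  }
  do.call(sim_config, lst)
}

#' Read back a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `meth_simulation` list reconstructed from disk.
#' @export
read_fixture_bundle <- function(dir) {
  beta <- read_beta_matrix(file.path(dir, "beta.tsv"))
  detp <- read_beta_matrix(file.path(dir, "detection_p.tsv"))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  ann <- read_probe_annotation(file.path(dir, "probe_annotation.tsv"))
  tp <- read_tsv_report(file.path(dir, "truth_probes.tsv"))
  te <- read_tsv_report(file.path(dir, "truth_tissue_effects.tsv"))
  de <- read_tsv_report(file.path(dir, "truth_donor_effects.tsv"))
  cfg <- sim_config_from_list(yaml::read_yaml(file.path(dir, "provenance.yaml")))
  tem <- as.matrix(te[, -1, drop = FALSE]); rownames(tem) <- te$probe_id
  dem <- as.matrix(de[, -1, drop = FALSE]); rownames(dem) <- de$probe_id
  structure(list(
    beta = beta, sample_sheet = sheet, annotation = ann, detection_p = detp,
    truth = list(probe_effect_class = stats::setNames(tp$effect_class, tp$probe_id),
                 baseline_class = stats::setNames(tp$baseline_class, tp$probe_id),
                 baseline_beta = stats::setNames(tp$baseline_beta, tp$probe_id),
                 tissue_effects = tem, donor_effects = dem),
    config = cfg), class = "meth_simulation")
}
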