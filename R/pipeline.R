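# End-to-end orchestration: one YAML config drives simulate -> filter ->
# categories -> concordance -> surrogate -> structure -> enrich, with
# provenance (config hash + seed) stamped on every output file.

PIPELINE_STAGES <- c("simulate", "filter", "categories", "concordance",
                     "surrogate", "structure", "enrich")

# Validate a raw config list and fill defaults; errors here fire before any
# computation or sampling.
normalize_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list", call. = FALSE)
  known <- c("seed", "output_dir", "stages", "eye_tissues", "blood_tissue",
             "retain_sex", "exact_p", "simulate", "inputs", "analysis",
             "pc_alpha", "screen_traits")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s", unknown[1]), call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  ana <- config$analysis %||% list()
  if (is.null(ana$rng_seed)) ana$rng_seed <- seed
  cfg <- tryCatch(do.call(analysis_config, ana), error = function(e)
    stop(sprintf("invalid analysis config: %s", conditionMessage(e)), call. = FALSE))
  sim <- NULL
  if (is.null(config$inputs)) {
    simlist <- config$simulate %||% list()
    if (is.null(simlist$seed)) simlist$seed <- seed
    sim <- tryCatch(sim_config_from_list(simlist), error = function(e)
      stop(sprintf("invalid simulate config: %s", conditionMessage(e)), call. = FALSE))
  } else {
    req <- c("beta", "sample_sheet", "annotation")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss)) {
      stop(sprintf("inputs missing '%s'", miss[1]), call. = FALSE)
    }
  }
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1]), call. = FALSE)
  if (!is.null(config$inputs)) stages <- setdiff(stages, "simulate")
  list(seed = seed,
       output_dir = config$output_dir,
       stages = stages,
       eye_tissues = config$eye_tissues %||%
         c("retina", "rpe_choroid", "optic_nerve"),
       blood_tissue = config$blood_tissue %||% "blood",
       retain_sex = config$retain_sex %||% TRUE,
       exact_p = config$exact_p %||% FALSE,
       pc_alpha = config$pc_alpha %||% 0.05,
       screen_traits = config$screen_traits %||% c("donor_id", "tissue", "chip"),
       analysis = cfg, simulate = sim, inputs = config$inputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full concordance pipeline from one configuration
#'
#' Executes the requested stages in dependency order on either a simulated
#' dataset (`simulate:` section) or user-supplied files (`inputs:` section
#' with `beta`, `sample_sheet`, `annotation` and optional `detection_p`
#' paths). All thresholds come from the `analysis:` section (see
#' [analysis_config()]); every output file records the configuration hash
#' and seed in `#` header comments, so a rerun with the same configuration
#' reproduces the outputs byte for byte. A failing stage is recorded in the
#' error manifest and its dependents are skipped; completed outputs are
#' kept.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#' @param output_dir Output directory (overrides `output_dir` in the
#'   config; required in one of the two places).
#' @param stages Subset of stages to run (default: those in the config, or
#'   all).
#' @return Object of class `pipeline_run`: list with `config`,
#'   `config_hash`, `seed`, `outputs` (named file paths), `results`
#'   (in-memory stage results), `errors` and `stages_run`.
#' @export
run_pipeline <- function(config, output_dir = NULL, stages = NULL) {
  pc <- normalize_pipeline_config(config)
  if (!is.null(output_dir)) pc$output_dir <- output_dir
  if (is.null(pc$output_dir)) stop("output_dir must be given", call. = FALSE)
  if (!is.null(stages)) {
    bad <- setdiff(stages, PIPELINE_STAGES)
    if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1]), call. = FALSE)
    pc$stages <- intersect(PIPELINE_STAGES, union(stages, "simulate"[is.null(pc$inputs)]))
  }
  dir.create(pc$output_dir, recursive = TRUE, showWarnings = FALSE)
  hashable <- pc[c("seed", "stages", "eye_tissues", "blood_tissue",
                   "retain_sex", "exact_p", "pc_alpha", "screen_traits")]
  hashable$analysis <- unclass(pc$analysis)
  if (!is.null(pc$simulate)) hashable$simulate <- sim_config_as_list(pc$simulate)
  hash <- config_hash(hashable)
  meta <- list(config_hash = hash, seed = pc$seed)

  run <- list(config = pc, config_hash = hash, seed = pc$seed,
              outputs = list(), results = list(), errors = list(),
              stages_run = character(0))
  log_msg <- function(...) message(sprintf(...))
  out_path <- function(name) file.path(pc$output_dir, name)
  try_stage <- function(name, deps, fun) {
    if (!name %in% pc$stages && !name %in% c("load")) return()
    missing_dep <- deps[!deps %in% names(run$results)]
    if (length(missing_dep)) {
      run$errors[[name]] <<- sprintf("skipped: dependency '%s' unavailable",
                                     missing_dep[1])
      return()
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      run$errors[[name]] <<- conditionMessage(res)
      log_msg("stage %s FAILED: %s", name, conditionMessage(res))
    } else {
      run$results[[name]] <<- res
      run$stages_run <<- c(run$stages_run, name)
      log_msg("stage %s done", name)
    }
  }

  # data acquisition -------------------------------------------------------
  if (is.null(pc$inputs)) {
    try_stage("simulate", character(0), function() {
      sim <- simulate_dataset(pc$simulate)
      write_fixture_bundle(sim, out_path("dataset"))
      run$outputs$dataset <<- out_path("dataset")
      sim
    })
    data_dep <- "simulate"
  } else {
    try_stage("load", character(0), function() {
      list(beta = read_beta_matrix(pc$inputs$beta),
           sample_sheet = read_sample_sheet(pc$inputs$sample_sheet),
           annotation = read_probe_annotation(pc$inputs$annotation),
           detection_p = if (!is.null(pc$inputs$detection_p))
             read_beta_matrix(pc$inputs$detection_p))
    })
    data_dep <- "load"
  }
  get_data <- function() run$results[[data_dep]]

  try_stage("filter", data_dep, function() {
    dat <- get_data()
    fl <- filter_probes(dat$beta, dat$annotation, dat$detection_p,
                        pc$analysis, retain_sex = pc$retain_sex)
    p <- out_path("filter_summary.tsv")
    write_tsv_report(summarize_filtering(fl$report), p, meta = meta)
    run$outputs$filter_summary <<- p
    p2 <- out_path("beta_filtered.tsv")
    write_beta_matrix(fl$beta, p2, meta = meta)
    run$outputs$beta_filtered <<- p2
    fl
  })

  try_stage("categories", "filter", function() {
    dat <- get_data()
    b <- run$results$filter$beta
    means <- tissue_mean_beta(b, dat$sample_sheet)
    ct <- categorize_probes(means, pc$analysis)
    p <- out_path("category_table.tsv")
    write_tsv_report(as.data.frame(ct), p, meta = meta)
    run$outputs$category_table <<- p
    overlaps <- list()
    for (cls in METH_CLASSES) {
      oc <- intersection_counts(ct, cls)
      p <- out_path(sprintf("overlap_%s.tsv", cls))
      write_tsv_report(oc, p, meta = meta)
      run$outputs[[sprintf("overlap_%s", cls)]] <<- p
      overlaps[[cls]] <- oc
    }
    joints <- list()
    for (tis in pc$eye_tissues) {
      jt <- joint_blood_eye_classes(ct, tis, dat$annotation,
                                    blood_tissue = pc$blood_tissue)
      p <- out_path(sprintf("joint_classes_%s.tsv", tis))
      write_tsv_report(jt, p, meta = meta)
      run$outputs[[sprintf("joint_classes_%s", tis)]] <<- p
      joints[[tis]] <- jt
    }
    list(category_table = ct, overlaps = overlaps, joint = joints)
  })

  try_stage("concordance", "filter", function() {
    dat <- get_data()
    b <- run$results$filter$beta
    scm <- sample_pairwise_spearman(b)
    p <- out_path("sample_correlation.tsv")
    write_tsv_report(cbind(data.frame(sample_id = rownames(scm)),
                           as.data.frame(scm)), p, meta = meta)
    run$outputs$sample_correlation <<- p
    summ <- tissue_pair_summary(scm, dat$sample_sheet)
    p <- out_path("tissue_pair_summary.tsv")
    write_tsv_report(summ, p, meta = meta)
    run$outputs$tissue_pair_summary <<- p
    dend <- hierarchical_cluster(scm)
    p <- out_path("sample_dendrogram.nwk")
    writeLines(dend$newick, p)
    run$outputs$sample_dendrogram <<- p
    list(correlation = scm, summary = summ, dendrogram = dend)
  })

  try_stage("surrogate", "filter", function() {
    dat <- get_data()
    b <- run$results$filter$beta
    vp <- blood_variable_probes(b, dat$sample_sheet, pc$analysis,
                                blood_tissue = pc$blood_tissue)
    p <- out_path("blood_variable_probes.tsv")
    write_tsv_report(vp, p, meta = meta)
    run$outputs$blood_variable_probes <<- p
    matched <- list(); nulls <- list(); tests <- list(); sims <- list()
    for (tis in pc$eye_tissues) {
      mc <- matched_probe_correlation(b, dat$sample_sheet, vp, tis,
                                      pc$analysis, exact_p = pc$exact_p,
                                      blood_tissue = pc$blood_tissue)
      p <- out_path(sprintf("matched_correlation_%s.tsv", tis))
      write_tsv_report(mc, p, meta = meta)
      run$outputs[[sprintf("matched_correlation_%s", tis)]] <<- p
      nd <- permutation_null(b, dat$sample_sheet, vp, tis, pc$analysis,
                             blood_tissue = pc$blood_tissue)
      tst <- compare_to_null(mc, nd)
      matched[[tis]] <- mc; nulls[[tis]] <- nd; tests[[tis]] <- tst
      ps <- paired_similarity(b, dat$sample_sheet, pc$blood_tissue, tis,
                              pc$analysis)
      p <- out_path(sprintf("paired_similarity_%s.tsv", tis))
      write_tsv_report(ps, p, meta = meta)
      run$outputs[[sprintf("paired_similarity_%s", tis)]] <<- p
      sims[[tis]] <- ps
    }
    nt <- data.frame(tissue = names(tests),
                     n_matched = vapply(matched, nrow, integer(1)),
                     n_null = vapply(nulls, function(x) length(x$values), integer(1)),
                     U = vapply(tests, function(x) x$statistic, numeric(1)),
                     z = vapply(tests, function(x) x$z, numeric(1)),
                     p_value = vapply(tests, function(x) x$p_value, numeric(1)),
                     stringsAsFactors = FALSE)
    p <- out_path("null_comparison.tsv")
    write_tsv_report(nt, p, meta = meta)
    run$outputs$null_comparison <<- p
    common <- common_correlated_probes(matched)
    p <- out_path("common_correlated_probes.tsv")
    write_tsv_report(data.frame(probe_id = common, stringsAsFactors = FALSE),
                     p, meta = meta)
    run$outputs$common_correlated_probes <<- p
    list(variable = vp, matched = matched, nulls = nulls,
         null_tests = tests, paired = sims, common = common)
  })

  try_stage("structure", "filter", function() {
    dat <- get_data()
    b <- run$results$filter$beta
    m <- beta_to_m(b)
    pca <- run_pca(m)
    scree <- data.frame(component = seq_along(pca$variance_explained),
                        variance_explained = pca$variance_explained)
    p <- out_path("scree.tsv")
    write_tsv_report(scree, p, meta = meta)
    run$outputs$scree <<- p
    assoc <- pc_trait_association(pca, dat$sample_sheet)
    p <- out_path("pc_trait_association.tsv")
    write_tsv_report(assoc, p, meta = meta)
    run$outputs$pc_trait_association <<- p
    # exclusivity is screened against genome-wide traits only; donor-level
    # phenotypes are aliased with donor at n = 8 and reported separately
    excl <- individual_exclusive_components(
      assoc[assoc$trait %in% union(pc$screen_traits, "donor_id"), , drop = FALSE],
      alpha = pc$pc_alpha)
    indiv_probes <- list()
    for (comp in excl) {
      ip <- pc_associated_probes(m, pca, comp, pc$analysis)
      p <- out_path(sprintf("pc%d_probes.tsv", comp))
      write_tsv_report(ip, p, meta = meta)
      run$outputs[[sprintf("pc%d_probes", comp)]] <<- p
      indiv_probes[[as.character(comp)]] <- ip
    }
    tsp <- tissue_specific_probes(m, dat$sample_sheet, pc$analysis)
    p <- out_path("tissue_specific_probes.tsv")
    write_tsv_report(tsp, p, meta = meta)
    run$outputs$tissue_specific_probes <<- p
    list(pca = pca, association = assoc, exclusive_components = excl,
         individual_probes = indiv_probes, tissue_specific = tsp)
  })

  try_stage("enrich", c("filter", "surrogate"), function() {
    dat <- get_data()
    background <- rownames(run$results$filter$beta)
    sur <- run$results$surrogate
    subsets <- list(blood_variable = sur$variable$probe_id)
    for (tis in names(sur$matched)) {
      subsets[[sprintf("correlated_%s", tis)]] <-
        sur$matched[[tis]]$probe_id[sur$matched[[tis]]$selected]
    }
    if (length(sur$common)) subsets$common_correlated <- sur$common
    if (!is.null(run$results$structure)) {
      for (comp in names(run$results$structure$individual_probes)) {
        subsets[[sprintf("pc%s_probes", comp)]] <-
          run$results$structure$individual_probes[[comp]]$probe_id
      }
    }
    tabs <- list()
    for (nm in names(subsets)) {
      ids <- subsets[[nm]]
      if (!length(ids)) next
      et <- enrichment_test(ids, background, dat$annotation)
      et <- cbind(data.frame(subset = nm, stringsAsFactors = FALSE), et)
      tabs[[nm]] <- et
    }
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    p <- out_path("enrichment.tsv")
    write_tsv_report(tab, p, meta = meta)
    run$outputs$enrichment <<- p
    tab
  })

  manifest <- list(config_hash = hash, seed = pc$seed,
                   stages_requested = pc$stages,
                   stages_completed = run$stages_run,
                   outputs = lapply(run$outputs, as.character),
                   errors = run$errors)
  jsonlite::write_json(manifest, file.path(pc$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(run$errors)) {
    jsonlite::write_json(run$errors, file.path(pc$output_dir, "errors.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(run, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  cat("  completed:", paste(x$stages_run, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("  errors:\n")
    for (nm in names(x$errors)) cat(sprintf("    %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}
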