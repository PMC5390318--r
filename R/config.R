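#' Analysis configuration
#'
#' Bundles every threshold the pipeline uses into one validated structure so
#' that a whole run is reproducible from a single object: the beta-value class
#' boundaries, the blood-variability range rule, the matched-correlation
#' selection thresholds, the detection p-value cutoff, the false-discovery
#' cutoff and the permutation-null settings.
#'
#' @param hypo_max Upper beta bound (inclusive) for the hypomethylated class.
#' @param hyper_min Lower beta bound (inclusive) for the hypermethylated class.
#' @param variability_range_min Minimum inter-donor beta range (exclusive) for
#'   a probe to count as "blood variable"; the default 0.05 encodes the
#'   ">5 percent methylation range" rule.
#' @param variability_quantiles Length-2 vector of the lower/upper quantiles
#'   whose difference defines the variability range (default 10th and 90th
#'   percentiles).
#' @param corr_r_min Absolute Spearman correlation threshold for calling a
#'   probe correlated between blood and an eye tissue.
#' @param corr_p_max Per-probe p-value threshold accompanying `corr_r_min`.
#' @param detection_p_max Detection p-value above which (strictly) a probe is
#'   considered failed in a sample.
#' @param fdr_q Benjamini-Hochberg adjusted-p cutoff.
#' @param equivalence_delta Absolute mean beta difference below which two
#'   tissues are considered equivalently methylated at a probe in
#'   [paired_similarity()].
#' @param n_null_permutations Number of random non-identity donor permutations
#'   pooled into the permutation null.
#' @param rng_seed Integer seed governing every stochastic step downstream of
#'   this configuration.
#'
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$hypo_max
#' @export
analysis_config <- function(hypo_max = 0.2,
                            hyper_min = 0.8,
                            variability_range_min = 0.05,
                            variability_quantiles = c(0.10, 0.90),
                            corr_r_min = 0.5,
                            corr_p_max = 0.05,
                            detection_p_max = 0.01,
                            fdr_q = 0.05,
                            equivalence_delta = 0.05,
                            n_null_permutations = 100L,
                            rng_seed = 1L) {
  cfg <- list(
    hypo_max = as.numeric(hypo_max),
    hyper_min = as.numeric(hyper_min),
    variability_range_min = as.numeric(variability_range_min),
    variability_quantiles = as.numeric(variability_quantiles),
    corr_r_min = as.numeric(corr_r_min),
    corr_p_max = as.numeric(corr_p_max),
    detection_p_max = as.numeric(detection_p_max),
    fdr_q = as.numeric(fdr_q),
    equivalence_delta = as.numeric(equivalence_delta),
    n_null_permutations = as.integer(n_null_permutations),
    rng_seed = as.integer(rng_seed)
  )
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!(is.numeric(hypo_max) && is.numeric(hyper_min) &&
          hypo_max >= 0 && hypo_max < hyper_min && hyper_min <= 1)) {
      stop("invalid beta class bounds: need 0 <= hypo_max < hyper_min <= 1",
           call. = FALSE)
    }
    if (length(variability_quantiles) != 2L ||
        variability_quantiles[1] < 0 ||
        variability_quantiles[1] >= variability_quantiles[2] ||
        variability_quantiles[2] > 1) {
      stop("variability_quantiles must satisfy 0 <= lo < hi <= 1", call. = FALSE)
    }
    if (variability_range_min < 0 || variability_range_min > 1) {
      stop("variability_range_min must lie in [0,1]", call. = FALSE)
    }
    if (corr_r_min < 0 || corr_r_min > 1) {
      stop("corr_r_min must lie in [0,1]", call. = FALSE)
    }
    for (nm in c("corr_p_max", "detection_p_max", "fdr_q")) {
      v <- get(nm)
      if (!is.numeric(v) || v <= 0 || v >= 1) {
        stop(sprintf("%s must lie in (0,1)", nm), call. = FALSE)
      }
    }
    if (equivalence_delta < 0 || equivalence_delta > 1) {
      stop("equivalence_delta must lie in [0,1]", call. = FALSE)
    }
    if (is.na(n_null_permutations) || n_null_permutations < 1L) {
      stop("n_null_permutations must be a positive integer", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
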