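# Blood-as-surrogate covariation: blood-variable probe selection, per-probe
# matched blood-eye Spearman correlation, permutation null of unmatched
# pairings, distribution comparison, cross-tissue intersection and paired-t
# similarity screening.

#' Select blood-variable probes
#'
#' A probe is "blood variable" when the spread of its blood beta values
#' across donors — the difference between the upper and lower variability
#' quantiles (default 90th and 10th percentiles, linear interpolation with
#' `h = (n-1)p`, i.e. `quantile(type = 7)`) — strictly exceeds
#' `cfg$variability_range_min` (default 0.05, the ">5% methylation range"
#' rule).
#'
#' @param b Beta matrix.
#' @param sheet Sample sheet; at least 2 blood samples are required.
#' @param cfg An [analysis_config()].
#' @param blood_tissue Tissue label identifying blood samples.
#' @return Data frame of the included probes with columns `probe_id`, `q_lo`,
#'   `q_hi`, `range`; attributes `quantiles` and `range_min`.
#' @export
blood_variable_probes <- function(b, sheet, cfg = analysis_config(),
                                  blood_tissue = "blood") {
  validate_beta_matrix(b)
  sheet <- align_sheet(sheet, b)
  blood <- sheet$sample_id[sheet$tissue == blood_tissue]
  if (length(blood) < 2L) {
    stop("at least 2 blood samples required to define variability", call. = FALSE)
  }
  qs <- cfg$variability_quantiles
  qq <- apply(b[, blood, drop = FALSE], 1, stats::quantile,
              probs = qs, na.rm = TRUE, type = 7, names = FALSE)
  rng <- qq[2, ] - qq[1, ]
  keep <- !is.na(rng) & rng > cfg$variability_range_min
  out <- data.frame(probe_id = rownames(b)[keep], q_lo = qq[1, keep],
                    q_hi = qq[2, keep], range = rng[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "quantiles") <- qs
  attr(out, "range_min") <- cfg$variability_range_min
  out
}

# Row-wise Spearman correlation between aligned matrices (columns = donors).
# Rows containing missing values fall back to a pairwise-complete loop.
row_spearman <- function(X, Y) {
  n <- nrow(X)
  rho <- rep(NA_real_, n)
  npairs <- rep(ncol(X), n)
  has_na <- rowSums(is.na(X) | is.na(Y)) > 0
  if (any(!has_na)) {
    RX <- t(apply(X[!has_na, , drop = FALSE], 1, rank))
    RY <- t(apply(Y[!has_na, , drop = FALSE], 1, rank))
    RX <- RX - rowMeans(RX); RY <- RY - rowMeans(RY)
    den <- sqrt(rowSums(RX^2) * rowSums(RY^2))
    val <- rowSums(RX * RY) / den
    val[den == 0] <- NA_real_
    rho[!has_na] <- val
  }
  for (i in which(has_na)) {
    ok <- !is.na(X[i, ]) & !is.na(Y[i, ])
    npairs[i] <- sum(ok)
    if (npairs[i] >= 3L) {
      rho[i] <- tryCatch(spearman_rho(X[i, ok], Y[i, ok]),
                         error = function(e) NA_real_)
    }
  }
  list(rho = rho, n = npairs)
}

# Two-sided p for Spearman's rho via the t approximation
# t = rho * sqrt((n-2)/(1-rho^2)), df = n-2.
spearman_p_t <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho) & n > 2
  r <- pmin(pmax(rho[ok], -1), 1)
  tt <- ifelse(abs(r) >= 1, Inf, r * sqrt((n[ok] - 2) / (1 - r^2)))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 2)
  pmin(p, 1)
}

# Cache of exact Spearman null |rho| distributions (distinct ranks, all n!
# orderings), keyed by n.
.spearman_null_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(v) {
    rest <- seq_len(n)[-v]
    cbind(v, matrix(rest[sub], nrow(sub)))
  }))
}

spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]])) return(.spearman_null_cache[[key]])
  if (n > 8L) stop("exact Spearman p supported only for n <= 8", call. = FALSE)
  perms <- all_permutations(n)
  idx <- seq_len(n)
  rho <- 1 - 6 * rowSums((perms - matrix(idx, nrow(perms), n, byrow = TRUE))^2) /
    (n * (n^2 - 1))
  .spearman_null_cache[[key]] <- sort(abs(rho))
  .spearman_null_cache[[key]]
}

# Exact two-sided permutation p assuming untied ranks.
spearman_p_exact <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  for (nn in unique(n[!is.na(rho)])) {
    null_abs <- spearman_exact_null(nn)
    sel <- which(n == nn & !is.na(rho))
    p[sel] <- vapply(abs(rho[sel]), function(a)
      mean(null_abs >= a - 1e-12), numeric(1))
  }
  p
}

# Donors having both a blood and an eye sample; returns aligned sample-id
# vectors in donor order.
matched_donor_samples <- function(sheet, eye_tissue, blood_tissue = "blood",
                                  min_donors = 4L) {
  validate_sample_sheet(sheet)
  bl <- sheet[sheet$tissue == blood_tissue, ]
  ey <- sheet[sheet$tissue == eye_tissue, ]
  donors <- intersect(bl$donor_id, ey$donor_id)
  dropped <- setdiff(union(bl$donor_id, ey$donor_id), donors)
  if (length(dropped)) {
    warning(sprintf("dropping %d donor(s) lacking a matched %s/%s pair: %s",
                    length(dropped), blood_tissue, eye_tissue,
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (length(donors) < min_donors) {
    stop(sprintf("fewer than %d donors with matched %s and %s samples",
                 min_donors, blood_tissue, eye_tissue), call. = FALSE)
  }
  donors <- sort(donors)
  list(donors = donors,
       blood = bl$sample_id[match(donors, bl$donor_id)],
       eye = ey$sample_id[match(donors, ey$donor_id)])
}

#' Per-probe matched blood-eye correlation
#'
#' For each blood-variable probe, Spearman's rho between the donor-ordered
#' blood beta vector and the same donors' eye-tissue vector, with a
#' two-sided p-value from the t approximation (default) or from the exact
#' rank-permutation distribution (`exact_p = TRUE`, n <= 8). A probe is
#' `selected` when `|rho| > cfg$corr_r_min` and `p < cfg$corr_p_max`.
#'
#' @param b Beta matrix.
#' @param sheet Sample sheet; donors lacking either tissue are dropped with a
#'   warning and at least 4 matched donors are required.
#' @param probes Result of [blood_variable_probes()] (or a character vector
#'   of probe ids).
#' @param eye_tissue Eye tissue to correlate against blood.
#' @param cfg An [analysis_config()].
#' @param exact_p Use the exact permutation p-value (untied ranks, n <= 8).
#' @param blood_tissue Blood tissue label.
#' @return Data frame with columns `probe_id`, `tissue`, `n`, `rho`,
#'   `p_value`, `selected`; attribute `p_method`.
#' @export
matched_probe_correlation <- function(b, sheet, probes, eye_tissue,
                                      cfg = analysis_config(),
                                      exact_p = FALSE,
                                      blood_tissue = "blood") {
  validate_beta_matrix(b)
  ids <- if (is.data.frame(probes)) probes$probe_id else as.character(probes)
  miss <- setdiff(ids, rownames(b))
  if (length(miss)) stop(sprintf("probe '%s' not in beta matrix", miss[1]),
                         call. = FALSE)
  ms <- matched_donor_samples(sheet, eye_tissue, blood_tissue)
  B <- b[ids, ms$blood, drop = FALSE]
  E <- b[ids, ms$eye, drop = FALSE]
  rs <- row_spearman(B, E)
  p <- if (exact_p) spearman_p_exact(rs$rho, rs$n) else spearman_p_t(rs$rho, rs$n)
  out <- data.frame(probe_id = ids, tissue = eye_tissue, n = rs$n,
                    rho = rs$rho, p_value = p,
                    selected = !is.na(rs$rho) & !is.na(p) &
                      abs(rs$rho) > cfg$corr_r_min & p < cfg$corr_p_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "p_method") <- if (exact_p) "exact_permutation" else "t_approximation"
  out
}

#' Permutation null of unmatched blood-eye correlations
#'
#' Re-pairs the eye samples with the blood samples of the wrong donors —
#' `cfg$n_null_permutations` random non-identity donor permutations — and
#' pools the per-probe Spearman correlations of all permutations into one
#' empirical null distribution. Probes with missing values in the matched
#' matrices are excluded from the pooling. Reproducible given
#' `cfg$rng_seed`.
#'
#' @inheritParams matched_probe_correlation
#' @return Object of class `null_distribution`: list with `values` (pooled
#'   correlations), `n_permutations`, `n_probes`, `n_donors`, `seed`.
#' @export
permutation_null <- function(b, sheet, probes, eye_tissue,
                             cfg = analysis_config(),
                             blood_tissue = "blood") {
  validate_beta_matrix(b)
  ids <- if (is.data.frame(probes)) probes$probe_id else as.character(probes)
  ms <- matched_donor_samples(sheet, eye_tissue, blood_tissue, min_donors = 3L)
  nd <- length(ms$donors)
  B <- b[ids, ms$blood, drop = FALSE]
  E <- b[ids, ms$eye, drop = FALSE]
  ok <- rowSums(is.na(B) | is.na(E)) == 0
  B <- B[ok, , drop = FALSE]; E <- E[ok, , drop = FALSE]
  if (!nrow(B)) stop("no complete probes available for the null", call. = FALSE)
  RB <- t(apply(B, 1, rank)); RE <- t(apply(E, 1, rank))
  RB <- RB - rowMeans(RB); RE <- RE - rowMeans(RE)
  den <- sqrt(rowSums(RB^2) * rowSums(RE^2))
  usable <- den > 0
  with_seed(cfg$rng_seed, {
    vals <- vector("list", cfg$n_null_permutations)
    for (k in seq_len(cfg$n_null_permutations)) {
      repeat {
        perm <- sample.int(nd)
        if (!identical(perm, seq_len(nd))) break
      }
      rho <- rowSums(RB * RE[, perm, drop = FALSE]) / den
      vals[[k]] <- rho[usable]
    }
    structure(list(values = unlist(vals, use.names = FALSE),
                   n_permutations = cfg$n_null_permutations,
                   n_probes = sum(usable), n_donors = nd,
                   seed = cfg$rng_seed),
              class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null: %d pooled correlations (%d probes x %d permutations, %d donors, seed %d)\n",
              length(x$values), x$n_probes, x$n_permutations, x$n_donors, x$seed))
  cat(sprintf("  mean %.4f, sd %.4f\n", mean(x$values), stats::sd(x$values)))
  invisible(x)
}

# Two-sided Mann-Whitney/Wilcoxon rank-sum test, normal approximation with
# tie correction and no continuity correction.
ranksum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) {
    stop("all values tied: rank-sum test undefined", call. = FALSE)
  }
  z <- (U - mu) / sqrt(sigma2)
  list(statistic = U, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare the matched correlation distribution to its permutation null
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of the matched per-probe
#' correlations against the pooled null values (normal approximation with
#' tie correction).
#'
#' @param matched Result of [matched_probe_correlation()] (its `rho` column
#'   is used) or a numeric vector of correlations.
#' @param null A `null_distribution` from [permutation_null()] or a numeric
#'   vector.
#' @return List with `statistic` (Mann-Whitney U), `z` and `p_value`.
#' @export
compare_to_null <- function(matched, null) {
  x <- if (is.data.frame(matched)) matched$rho else as.numeric(matched)
  y <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  ranksum_test(x, y)
}

#' Probes correlated with blood in every eye tissue
#'
#' Intersection of the `selected` probe sets across the supplied per-tissue
#' matched-correlation results.
#'
#' @param results List of data frames from [matched_probe_correlation()],
#'   one per eye tissue, over the same probe universe.
#' @return Character vector of commonly correlated probe ids.
#' @export
common_correlated_probes <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  sets <- lapply(results, function(r) r$probe_id[r$selected])
  Reduce(intersect, sets)
}

#' Paired-t similarity screen between two tissues
#'
#' Per probe, a paired t-test on the donor-wise beta differences between two
#' tissues, Benjamini-Hochberg adjusted across probes. A probe is flagged
#' `similar` when the adjusted p is not below `cfg$fdr_q` (no detectable
#' difference) AND the absolute mean difference is below
#' `cfg$equivalence_delta`; both ingredients are also returned separately so
#' either definition of "most similarly methylated" can be reproduced.
#' Probes with zero-variance differences have an undefined t and are treated
#' as similar when the mean difference is below the equivalence bound.
#'
#' @param b Beta matrix.
#' @param sheet Sample sheet; at least 3 donors with both tissues required.
#' @param tissue_a,tissue_b The two tissues to compare.
#' @param cfg An [analysis_config()].
#' @return Data frame with columns `probe_id`, `n`, `mean_diff`, `t`,
#'   `p_value`, `adj_p`, `zero_variance`, `nonsignificant`, `equivalent`,
#'   `similar`, sorted in input probe order.
#' @export
paired_similarity <- function(b, sheet, tissue_a, tissue_b,
                              cfg = analysis_config()) {
  validate_beta_matrix(b)
  ms <- matched_donor_samples(sheet, tissue_b, blood_tissue = tissue_a,
                              min_donors = 3L)
  A <- b[, ms$blood, drop = FALSE]
  B <- b[, ms$eye, drop = FALSE]
  D <- A - B
  n <- rowSums(!is.na(D))
  mean_diff <- rowMeans(D, na.rm = TRUE)
  sd_diff <- apply(D, 1, stats::sd, na.rm = TRUE)
  tstat <- rep(NA_real_, nrow(D))
  ok <- n >= 2 & !is.na(sd_diff) & sd_diff > 0
  tstat[ok] <- mean_diff[ok] / (sd_diff[ok] / sqrt(n[ok]))
  p <- rep(NA_real_, nrow(D))
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = n[ok] - 1)
  adj <- stats::p.adjust(p, method = "BH")
  zero_var <- !is.na(sd_diff) & sd_diff == 0
  nonsig <- (!is.na(adj) & adj >= cfg$fdr_q) | zero_var
  equiv <- abs(mean_diff) < cfg$equivalence_delta
  data.frame(probe_id = rownames(b), n = n, mean_diff = mean_diff,
             t = tstat, p_value = p, adj_p = adj,
             zero_variance = zero_var, nonsignificant = nonsig,
             equivalent = equiv, similar = nonsig & equiv,
             row.names = NULL, stringsAsFactors = FALSE)
}
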