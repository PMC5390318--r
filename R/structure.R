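# Variation structure: PCA on M-values, PC-trait association, selection of
# individual-associated components and probes, and moderated-F detection of
# tissue-specific probes.

#' Principal components analysis of an M-value matrix
#'
#' Samples are the observations: each probe is centered across samples and
#' the centered matrix decomposed by SVD. Probes containing missing values
#' are dropped with a warning. The sign of each component is fixed so its
#' largest-magnitude probe loading is positive, making results reproducible.
#'
#' @param m M-value matrix (probes x samples), e.g. from [beta_to_m()].
#' @return Object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (probes x components), `variance_explained`
#'   (percentages, descending, summing to 100), `sample_ids`, `probe_ids`,
#'   `n_dropped`.
#' @export
run_pca <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix",
                                            call. = FALSE)
  if (ncol(m) < 2L) stop("at least 2 samples required for PCA", call. = FALSE)
  drop <- rowSums(is.na(m)) > 0
  if (any(drop)) {
    warning(sprintf("dropping %d probe(s) with missing values before PCA",
                    sum(drop)), call. = FALSE)
    m <- m[!drop, , drop = FALSE]
  }
  if (!nrow(m)) stop("no complete probes available for PCA", call. = FALSE)
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- pr$x
  loadings <- pr$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve,
                 sample_ids = colnames(m), probe_ids = rownames(m),
                 n_dropped = sum(drop)), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d probes, %d components\n",
              length(x$sample_ids), length(x$probe_ids), ncol(x$scores)))
  k <- min(5L, length(x$variance_explained))
  cat("  variance explained (%):",
      paste(sprintf("PC%d=%.2f", seq_len(k), x$variance_explained[seq_len(k)]),
            collapse = ", "), "...\n")
  invisible(x)
}

# One-way ANOVA of y on a categorical grouping; returns F and p.
oneway_anova <- function(y, g) {
  g <- factor(g)
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  list(statistic = a[1, "F value"], p_value = a[1, "Pr(>F)"])
}

# Simple linear regression F test of y on continuous x.
regression_f <- function(y, x) {
  fit <- stats::lm(y ~ x)
  a <- stats::anova(fit)
  list(statistic = a[1, "F value"], p_value = a[1, "Pr(>F)"])
}

#' Associate principal components with sample traits
#'
#' For each component and each trait: one-way ANOVA of the component scores
#' across trait levels for categorical traits, a simple linear-regression F
#' test for continuous traits. Traits with a single observed level are
#' skipped with a warning.
#'
#' @param pca A `pca_result`.
#' @param sheet Sample sheet covering the scored samples.
#' @param traits Trait column names to test (default: donor, tissue, chip
#'   and the continuous covariates present in the sheet).
#' @param n_components How many leading components to test (default: all
#'   with positive variance).
#' @return Data frame with columns `component`, `trait`, `test`,
#'   `statistic`, `p_value`.
#' @export
pc_trait_association <- function(pca, sheet,
                                 traits = intersect(
                                   c("donor_id", "tissue", "chip",
                                     "age_at_death", "cause_of_death",
                                     "preservation_interval"), names(sheet)),
                                 n_components = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  validate_sample_sheet(sheet)
  ids <- rownames(pca$scores)
  miss <- setdiff(ids, sheet$sample_id)
  if (length(miss)) stop(sprintf("sample '%s' missing from sheet", miss[1]),
                         call. = FALSE)
  sheet <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  bad <- setdiff(traits, names(sheet))
  if (length(bad)) stop(sprintf("trait '%s' not in sample sheet", bad[1]),
                        call. = FALSE)
  if (is.null(n_components)) {
    n_components <- sum(pca$variance_explained > 1e-9)
  }
  n_components <- min(n_components, ncol(pca$scores))
  rows <- list()
  for (trait in traits) {
    v <- sheet[[trait]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning(sprintf("trait '%s' has a single level; skipped", trait),
              call. = FALSE)
      next
    }
    continuous <- is.numeric(v)
    for (comp in seq_len(n_components)) {
      res <- if (continuous) regression_f(pca$scores[, comp], v)
             else oneway_anova(pca$scores[, comp], v)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, trait = trait,
        test = if (continuous) "linear_regression" else "anova",
        statistic = res$statistic, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Components associated exclusively with individuals
#'
#' Returns the components whose individual (donor) association is below
#' `alpha` while every other tested trait is non-significant at `alpha` —
#' the screen used to isolate inter-individual methylation variation from
#' tissue, batch and phenotype effects.
#'
#' @param assoc Data frame from [pc_trait_association()].
#' @param alpha Significance threshold (default 0.05; 0.10 reproduces a more
#'   permissive screen).
#' @param individual_trait Name of the donor trait (default `"donor_id"`).
#' @return Integer vector of component indices.
#' @export
individual_exclusive_components <- function(assoc, alpha = 0.05,
                                            individual_trait = "donor_id") {
  stopifnot(all(c("component", "trait", "p_value") %in% names(assoc)))
  if (!individual_trait %in% assoc$trait) {
    stop(sprintf("no associations found for trait '%s'", individual_trait),
         call. = FALSE)
  }
  comps <- sort(unique(assoc$component))
  keep <- vapply(comps, function(k) {
    a <- assoc[assoc$component == k, ]
    ind <- a$p_value[a$trait == individual_trait]
    oth <- a$p_value[a$trait != individual_trait]
    length(ind) == 1L && !is.na(ind) && ind < alpha &&
      all(is.na(oth) | oth >= alpha)
  }, logical(1))
  comps[keep]
}

#' Probes highly associated with a principal component
#'
#' Pearson correlation of each probe's M-values (across samples) with the
#' component's score vector; probes with `|r| > cfg$corr_r_min` are
#' returned. Zero-variance probes have undefined correlation and are
#' excluded (their count is reported in an attribute).
#'
#' @param m M-value matrix used for the PCA.
#' @param pca A `pca_result`.
#' @param component Component index.
#' @param cfg An [analysis_config()].
#' @return Data frame with columns `probe_id` and `r` for the selected
#'   probes; attribute `n_zero_variance`.
#' @export
pc_associated_probes <- function(m, pca, component, cfg = analysis_config()) {
  stopifnot(inherits(pca, "pca_result"))
  if (length(component) != 1L || component < 1 || component > ncol(pca$scores)) {
    stop("invalid component index", call. = FALSE)
  }
  m <- m[, rownames(pca$scores), drop = FALSE]
  s <- pca$scores[, component]
  keep <- rowSums(is.na(m)) == 0
  mm <- m[keep, , drop = FALSE]
  sds <- apply(mm, 1, stats::sd)
  zero <- sds == 0
  r <- rep(NA_real_, nrow(mm))
  r[!zero] <- as.vector(stats::cor(t(mm[!zero, , drop = FALSE]), s))
  sel <- !is.na(r) & abs(r) > cfg$corr_r_min
  out <- data.frame(probe_id = rownames(mm)[sel], r = r[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_zero_variance") <- sum(zero)
  out
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigamma_inverse <- function(x) {
  out <- x
  pos <- !is.na(x) & x > 0
  y <- 0.5 + 1 / x[pos]
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-12) break
  }
  out[pos] <- y
  out[!is.na(x) & x <= 0] <- Inf
  out
}

# Empirical-Bayes hyperparameters (prior df d0 and prior variance s0^2) by
# moment matching on log s^2: if s^2 ~ s0^2 * F(d, d0) then
# e = log(s^2) - digamma(d/2) + log(d/2) has mean log(s0^2) - digamma(d0/2)
# + log(d0/2) and variance trigamma(d/2) + trigamma(d0/2).
estimate_variance_prior <- function(s2, df) {
  ok <- !is.na(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s02 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Moderated-F test for tissue-specific probes
#'
#' Per probe, a one-way linear model of M-values on the tissue factor. The
#' residual variances are shrunk toward a common prior by empirical Bayes:
#' hyperparameters (prior df `d0`, prior variance `s0^2`) are estimated by
#' moment matching on the log residual variances, the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)`, and the moderated F is the between-tissue
#' mean square over the posterior variance, referred to an F distribution on
#' `(k - 1, d0 + d)` degrees of freedom, with Benjamini-Hochberg adjustment
#' across probes.
#'
#' @param m M-value matrix.
#' @param sheet Sample sheet; at least 2 tissues and positive total residual
#'   degrees of freedom are required.
#' @param cfg An [analysis_config()]; `fdr_q` sets the significance cutoff
#'   reported in `significant`.
#' @param prior_df,prior_var Optional fixed hyperparameters overriding the
#'   empirical-Bayes estimates; `prior_df = 0` reproduces the ordinary
#'   per-probe ANOVA F, `prior_df = Inf` fully shrinks every variance to the
#'   prior.
#' @return Data frame with columns `probe_id`, `F`, `p_value`, `adj_p`,
#'   `significant`; attributes `d0`, `s02`, `df1`, `df_residual`.
#' @export
tissue_specific_probes <- function(m, sheet, cfg = analysis_config(),
                                   prior_df = NULL, prior_var = NULL) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix",
                                            call. = FALSE)
  sheet <- align_sheet(sheet, m)
  g <- factor(sheet$tissue)
  k <- nlevels(g)
  if (k < 2L) stop("at least 2 tissues required", call. = FALSE)
  n_g <- as.vector(table(g))
  N <- ncol(m)
  d <- N - k
  if (d < 1L) stop("zero residual degrees of freedom", call. = FALSE)
  keep <- rowSums(is.na(m)) == 0
  if (!all(keep)) {
    warning(sprintf("dropping %d probe(s) with missing values", sum(!keep)),
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  means <- t(rowsum(t(m), g) / n_g)          # probes x tissues
  fitted <- means[, as.integer(g), drop = FALSE]
  ssw <- rowSums((m - fitted)^2)
  grand <- rowMeans(m)
  ssb <- as.vector((means - grand)^2 %*% n_g)
  s2 <- ssw / d
  msb <- ssb / (k - 1)

  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, d)
  } else {
    prior <- list(d0 = prior_df,
                  s02 = if (is.null(prior_var)) estimate_variance_prior(s2, d)$s02
                        else prior_var)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  Fmod <- msb / s2_post
  df2 <- d0 + d
  p <- stats::pf(Fmod, df1 = k - 1, df2 = df2, lower.tail = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(probe_id = rownames(m), F = Fmod, p_value = p,
                    adj_p = adj, significant = !is.na(adj) & adj < cfg$fdr_q,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df1") <- k - 1
  attr(out, "df_residual") <- d
  out
}
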