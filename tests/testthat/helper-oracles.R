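# Independent brute-force oracles and small hand fixtures used across the
# suite. Oracles are written from first principles (sums, enumeration) and
# never call the code paths they check.

# Mid-ranks computed by explicit comparison counting (ties -> average rank).
oracle_rank <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    less <- sum(x < x[i])
    tied <- sum(x == x[i])
    less + (tied + 1) / 2
  }, numeric(1))
}

# Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# Two-sided t-distribution tail via the incomplete beta function, an
# independent route to Student-t p-values.
oracle_t_twosided_p <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 1 / 2)
}

# Paired t statistic from the difference vector.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  dbar <- mean(d)
  s <- sqrt(sum((d - dbar)^2) / (n - 1))
  dbar / (s / sqrt(n))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  ssb <- 0; ssw <- 0
  for (lev in unique(g)) {
    yi <- y[g == lev]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  k <- length(unique(g)); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Benjamini-Hochberg adjustment by the step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins that are no more
# probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Quantile by linear interpolation between order statistics, h = (n-1)p.
oracle_quantile_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# Hand-construct a small beta matrix with donor/tissue structure.
hand_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probe_ids %||% sprintf("cg%04d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal sheet for constructed matrices: samples named <donor>_<tissue>,
# donor ids contain no underscore.
sheet_from_ids <- function(sample_ids) {
  data.frame(sample_id = sample_ids,
             donor_id = sub("_.*$", "", sample_ids),
             tissue = sub("^[^_]*_", "", sample_ids),
             chip = "chip01", stringsAsFactors = FALSE)
}
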