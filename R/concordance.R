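#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), computed
#' pairwise-complete. At least 3 complete pairs and nonzero rank variance in
#' both vectors are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("fewer than 3 complete pairs: Spearman correlation undefined",
         call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in ranks: Spearman correlation undefined", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Pairwise Spearman correlation between all samples
#'
#' Spearman's rho over probes for every unordered sample pair,
#' pairwise-complete over missing values.
#'
#' @param b Beta matrix with at least 2 samples.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_pairwise_spearman <- function(b) {
  validate_beta_matrix(b)
  if (ncol(b) < 2L) stop("at least 2 samples required", call. = FALSE)
  scm <- stats::cor(b, method = "spearman", use = "pairwise.complete.obs")
  scm <- (scm + t(scm)) / 2
  diag(scm) <- 1
  scm
}

#' Summarise sample correlations by tissue pair
#'
#' Median (midpoint convention), minimum and maximum of the sample-level
#' Spearman correlations, for every unordered cross-tissue pair and for the
#' within-tissue pairs of each tissue.
#'
#' @param scm Sample correlation matrix from [sample_pairwise_spearman()].
#' @param sheet Sample sheet assigning tissues.
#' @return Data frame with columns `tissue_a`, `tissue_b` (equal for
#'   within-tissue rows), `n_pairs`, `median_rho`, `min_rho`, `max_rho`.
#' @export
tissue_pair_summary <- function(scm, sheet) {
  validate_sample_sheet(sheet)
  ids <- colnames(scm)
  miss <- setdiff(ids, sheet$sample_id)
  if (length(miss)) stop(sprintf("sample '%s' missing from sheet", miss[1]),
                         call. = FALSE)
  tis <- sheet$tissue[match(ids, sheet$sample_id)]
  tissues <- unique(sheet$tissue[sheet$sample_id %in% ids])
  rows <- list()
  for (i in seq_along(tissues)) {
    for (j in i:length(tissues)) {
      a <- tissues[i]; b <- tissues[j]
      if (a == b) {
        sel <- which(tis == a)
        if (length(sel) < 2L) next
        vals <- scm[sel, sel][upper.tri(matrix(0, length(sel), length(sel)))]
      } else {
        vals <- as.vector(scm[tis == a, tis == b, drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tissue_a = a, tissue_b = b, n_pairs = length(vals),
        median_rho = stats::median(vals), min_rho = min(vals),
        max_rho = max(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering on the correlation distance `d = 1 - rho` with
#' average linkage. Samples are pre-sorted lexicographically so the merge
#' order (and hence any tie-break) is deterministic. The dendrogram is
#' emitted as a Newick string with branch lengths.
#'
#' @param scm Sample correlation matrix.
#' @return Object of class `concordance_dendrogram`: list with `newick`
#'   (string), `hclust` and `phylo` representations.
#' @export
hierarchical_cluster <- function(scm) {
  if (!is.matrix(scm) || ncol(scm) < 2L) {
    stop("at least 2 samples required", call. = FALSE)
  }
  ord <- radix_order(colnames(scm))
  scm <- scm[ord, ord]
  d <- stats::as.dist(1 - scm)
  h <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(h)
  structure(list(newick = ape::write.tree(phy), hclust = h, phylo = phy),
            class = "concordance_dendrogram")
}

#' @export
print.concordance_dendrogram <- function(x, ...) {
  cat(x$newick, "\n")
  invisible(x)
}

#' Test whether a set of samples forms one clade of the dendrogram
#'
#' @param dend A `concordance_dendrogram`.
#' @param samples Character vector of tip labels.
#' @return `TRUE` when the smallest clade containing `samples` contains no
#'   other tips.
#' @export
is_clade <- function(dend, samples) {
  stopifnot(inherits(dend, "concordance_dendrogram"))
  phy <- dend$phylo
  samples <- unique(samples)
  if (!all(samples %in% phy$tip.label)) {
    stop("unknown sample id among requested tips", call. = FALSE)
  }
  if (length(samples) == 1L) return(TRUE)
  node <- ape::getMRCA(phy, samples)
  tips <- ape::extract.clade(phy, node)$tip.label
  setequal(tips, samples)
}
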