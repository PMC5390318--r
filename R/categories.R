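#' Per-probe, per-tissue mean beta
#'
#' Arithmetic mean of beta over the samples of each tissue,
#' pairwise-complete over missing values.
#'
#' @param b Beta matrix.
#' @param sheet Sample sheet assigning every sample in `b` to a tissue.
#' @return Numeric matrix, probes x tissues (tissue order = first appearance
#'   in the sheet).
#' @export
tissue_mean_beta <- function(b, sheet) {
  validate_beta_matrix(b)
  sheet <- align_sheet(sheet, b)
  tissues <- unique(sheet$tissue)
  out <- matrix(NA_real_, nrow(b), length(tissues),
                dimnames = list(rownames(b), tissues))
  for (tis in tissues) {
    cols <- sheet$sample_id[sheet$tissue == tis]
    if (!length(cols)) stop(sprintf("tissue '%s' has zero samples", tis),
                            call. = FALSE)
    out[, tis] <- rowMeans(b[, cols, drop = FALSE], na.rm = TRUE)
  }
  out
}

# Three-class assignment with closed boundaries: hypo iff beta <= hypo_max,
# hyper iff beta >= hyper_min, else intermediate.
classify_beta <- function(x, cfg = analysis_config()) {
  cls <- rep(NA_character_, length(x))
  cls[!is.na(x) & x <= cfg$hypo_max] <- "hypo"
  cls[!is.na(x) & x >= cfg$hyper_min] <- "hyper"
  cls[!is.na(x) & is.na(cls)] <- "intermediate"
  if (!is.null(dim(x))) cls <- array(cls, dim(x), dimnames(x))
  cls
}

#' Categorise probes into methylation classes per tissue
#'
#' Assigns each (probe, tissue) mean beta to hypomethylated
#' (`beta <= hypo_max`), intermediate, or hypermethylated
#' (`beta >= hyper_min`), with closed boundaries on both thresholds.
#'
#' @param means Probes x tissues mean beta matrix from [tissue_mean_beta()].
#' @param cfg An [analysis_config()] supplying the 0.2/0.8 boundaries.
#' @return An object of class `category_table`: list with `probe_ids`,
#'   `tissues`, `mean_beta` (matrix) and `class` (character matrix with
#'   values `"hypo"`, `"intermediate"`, `"hyper"`).
#' @export
categorize_probes <- function(means, cfg = analysis_config()) {
  if (!is.matrix(means)) means <- as.matrix(means)
  if (any(!is.na(means) & (means < 0 | means > 1))) {
    stop("mean beta values must lie in [0,1]", call. = FALSE)
  }
  structure(list(probe_ids = rownames(means), tissues = colnames(means),
                 mean_beta = means, class = classify_beta(means, cfg)),
            class = "category_table")
}

#' @export
as.data.frame.category_table <- function(x, ...) {
  df <- data.frame(probe_id = x$probe_ids, stringsAsFactors = FALSE)
  for (tis in x$tissues) {
    df[[paste0("mean_", tis)]] <- x$mean_beta[, tis]
    df[[paste0("class_", tis)]] <- x$class[, tis]
  }
  df
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("Methylation category table: %d probes x %d tissues\n",
              length(x$probe_ids), length(x$tissues)))
  print(apply(x$class, 2, function(cl) table(factor(cl, METH_CLASSES))))
  invisible(x)
}

#' UpSet-style disjoint intersection counts for one methylation class
#'
#' For every nonempty subset S of the tissues, counts the probes whose class
#' equals `cls` in exactly the tissues of S (and not in any tissue outside
#' S). The 2^T - 1 cells are disjoint and, together with the probes in the
#' class for no tissue, partition the probe set.
#'
#' @param ct A `category_table`.
#' @param cls One of `"hypo"`, `"intermediate"`, `"hyper"`.
#' @return Data frame with columns `subset` (tissue names joined by `+`),
#'   `degree`, `count`, covering all nonempty subsets (zeros included);
#'   attributes `class`, `n_none` (probes in the class for no tissue) and
#'   `n_total`.
#' @export
intersection_counts <- function(ct, cls) {
  stopifnot(inherits(ct, "category_table"))
  if (!cls %in% METH_CLASSES) {
    stop(sprintf("unknown methylation class '%s'", cls), call. = FALSE)
  }
  tissues <- ct$tissues
  Tn <- length(tissues)
  if (Tn < 1L) stop("at least one tissue required", call. = FALSE)
  M <- !is.na(ct$class) & ct$class == cls
  code <- as.integer(M %*% 2^(seq_len(Tn) - 1L))
  counts <- tabulate(code + 1L, nbins = 2L^Tn)
  subsets <- seq_len(2L^Tn - 1L)
  members <- lapply(subsets, function(s) tissues[bitwAnd(s, 2L^(seq_len(Tn) - 1L)) > 0])
  out <- data.frame(
    subset = vapply(members, paste, character(1), collapse = "+"),
    degree = lengths(members),
    count = counts[subsets + 1L],
    stringsAsFactors = FALSE)
  attr(out, "class_label") <- cls
  attr(out, "n_none") <- counts[1L]
  attr(out, "n_total") <- length(ct$probe_ids)
  out
}

#' Joint blood/eye methylation-class composition by genomic context
#'
#' For each genomic feature class and, separately, each CpG-island relation,
#' tabulates the percentage of probes falling in each joint (blood class,
#' eye class) cell — the B1..B3 x E1..E3 decomposition, where class 1 is
#' hypomethylated, 2 intermediate and 3 hypermethylated. Percentages within
#' each (scheme, category) panel sum to 100.
#'
#' @param ct A `category_table` containing blood and `eye_tissue`.
#' @param eye_tissue Name of the eye tissue to compare against blood.
#' @param ann Probe annotation covering all probes in `ct`.
#' @param blood_tissue Name of the blood tissue column (default `"blood"`).
#' @return Data frame with columns `scheme`, `category`, `blood_class`,
#'   `eye_class`, `count`, `percent`.
#' @export
joint_blood_eye_classes <- function(ct, eye_tissue, ann,
                                    blood_tissue = "blood") {
  stopifnot(inherits(ct, "category_table"))
  for (tis in c(blood_tissue, eye_tissue)) {
    if (!tis %in% ct$tissues) {
      stop(sprintf("tissue '%s' not present in category table", tis),
           call. = FALSE)
    }
  }
  validate_probe_annotation(ann)
  miss <- setdiff(ct$probe_ids, ann$probe_id)
  if (length(miss)) {
    stop(sprintf("probe '%s' missing from annotation", miss[1]), call. = FALSE)
  }
  ann <- ann[match(ct$probe_ids, ann$probe_id), , drop = FALSE]
  bcls <- factor(ct$class[, blood_tissue], METH_CLASSES)
  ecls <- factor(ct$class[, eye_tissue], METH_CLASSES)
  out <- list()
  for (scheme in c("feature_class", "island_relation")) {
    lvls <- if (scheme == "feature_class") FEATURE_CLASSES else ISLAND_RELATIONS
    for (lev in lvls) {
      sel <- ann[[scheme]] == lev
      if (!any(sel)) next
      tab <- table(blood = bcls[sel], eye = ecls[sel])
      cnt <- as.data.frame(tab, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        scheme = scheme, category = lev,
        blood_class = cnt$blood, eye_class = cnt$eye, count = cnt$Freq,
        percent = 100 * cnt$Freq / sum(cnt$Freq),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
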