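# Genomic-context enrichment of probe subsets against a background set.

#' Genomic-context distribution of a probe set
#'
#' Counts and proportions of probes per genomic feature class and,
#' separately, per CpG-island relation. Proportions sum to 1 within each
#' scheme.
#'
#' @param probes Character vector of probe ids.
#' @param ann Probe annotation covering every probe.
#' @return Data frame with columns `scheme`, `category`, `count`,
#'   `proportion`.
#' @export
category_distribution <- function(probes, ann) {
  validate_probe_annotation(ann)
  probes <- unique(as.character(probes))
  miss <- setdiff(probes, ann$probe_id)
  if (length(miss)) stop(sprintf("probe '%s' missing from annotation", miss[1]),
                         call. = FALSE)
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]
  rows <- list()
  for (scheme in c("feature_class", "island_relation")) {
    lvls <- if (scheme == "feature_class") FEATURE_CLASSES else ISLAND_RELATIONS
    cnt <- table(factor(ann[[scheme]], lvls))
    rows[[scheme]] <- data.frame(scheme = scheme, category = lvls,
                                 count = as.integer(cnt),
                                 proportion = as.numeric(cnt) / length(probes),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic-context enrichment of a probe subset
#'
#' For each feature class and island relation, a 2x2 table of (in subset vs
#' rest of background) x (in category vs not) is tested with the two-sided
#' Fisher exact test; the cross-product odds ratio is reported (infinite for
#' zero cells) and p-values are Benjamini-Hochberg adjusted within each
#' annotation scheme.
#'
#' @param subset Character vector of probe ids; must be a subset of
#'   `background` and nonempty.
#' @param background Character vector of background probe ids (typically all
#'   post-QC probes).
#' @param ann Probe annotation covering the background.
#' @return Data frame with columns `scheme`, `category`, `subset_count`,
#'   `subset_proportion`, `background_count`, `background_proportion`,
#'   `odds_ratio`, `p_value`, `adj_p`.
#' @export
enrichment_test <- function(subset, background, ann) {
  validate_probe_annotation(ann)
  subset <- unique(as.character(subset))
  background <- unique(as.character(background))
  if (!length(subset)) stop("subset must be nonempty", call. = FALSE)
  if (length(setdiff(subset, background))) {
    stop("subset must be contained in background", call. = FALSE)
  }
  miss <- setdiff(background, ann$probe_id)
  if (length(miss)) stop(sprintf("probe '%s' missing from annotation", miss[1]),
                         call. = FALSE)
  ann_bg <- ann[match(background, ann$probe_id), , drop = FALSE]
  in_sub <- background %in% subset
  n_sub <- sum(in_sub)
  n_rest <- length(background) - n_sub
  rows <- list()
  for (scheme in c("feature_class", "island_relation")) {
    lvls <- if (scheme == "feature_class") FEATURE_CLASSES else ISLAND_RELATIONS
    sub_rows <- list()
    for (lev in lvls) {
      in_cat <- ann_bg[[scheme]] == lev
      a <- sum(in_sub & in_cat)
      b <- n_sub - a
      cc <- sum(!in_sub & in_cat)
      dd <- n_rest - cc
      or <- if (b == 0 || cc == 0) {
        if (a == 0 || dd == 0) NaN else Inf
      } else (a * dd) / (b * cc)
      pv <- stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE))$p.value
      sub_rows[[lev]] <- data.frame(
        scheme = scheme, category = lev,
        subset_count = a, subset_proportion = a / n_sub,
        background_count = a + cc,
        background_proportion = (a + cc) / length(background),
        odds_ratio = or, p_value = pv, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, sub_rows)
    df$adj_p <- stats::p.adjust(df$p_value, method = "BH")
    rows[[scheme]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
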