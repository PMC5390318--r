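#' Probe-level quality filtering
#'
#' Removes a probe when any of the configured inclusion rules fails:
#' a detection p-value strictly greater than `cfg$detection_p_max` in any
#' sample, a cross-reactive flag, a SNP flag, or (only when
#' `retain_sex = FALSE`) location on a sex chromosome. Probes failing several
#' rules are removed once but listed under every applicable reason, so the
#' report is fully auditable. For all-male matched designs sex-chromosome
#' probes are typically retained (`retain_sex = TRUE`, the default).
#'
#' @param b Beta matrix.
#' @param ann Probe annotation covering every probe in `b`.
#' @param detp Optional detection p-value matrix aligned to `b` (same probes
#'   and samples); `NULL` disables the detection rule.
#' @param cfg An [analysis_config()].
#' @param retain_sex Keep probes on chromosomes X/Y (default `TRUE`).
#' @return A list with elements `beta` (filtered matrix, input probe order
#'   preserved) and `report` (a `filter_report`).
#' @export
filter_probes <- function(b, ann, detp = NULL, cfg = analysis_config(),
                          retain_sex = TRUE) {
  validate_beta_matrix(b)
  validate_probe_annotation(ann)
  probes <- rownames(b)
  miss <- setdiff(probes, ann$probe_id)
  if (length(miss)) {
    stop(sprintf("probe '%s' present in matrix but absent from annotation",
                 miss[1]), call. = FALSE)
  }
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]

  removed <- list(detection = character(0), cross_reactive = character(0),
                  snp = character(0), sex = character(0))
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(b)) ||
        !identical(rownames(detp), probes) ||
        !identical(colnames(detp), colnames(b))) {
      stop("detection p-value matrix must be aligned to the beta matrix",
           call. = FALSE)
    }
    fail <- apply(detp > cfg$detection_p_max, 1, any, na.rm = TRUE)
    removed$detection <- probes[fail]
  }
  removed$cross_reactive <- probes[ann$cross_reactive]
  removed$snp <- probes[ann$snp_flag]
  if (!retain_sex) {
    removed$sex <- probes[ann$chromosome %in% c("X", "Y")]
  }
  removed_union <- unique(unlist(removed, use.names = FALSE))
  keep <- !(probes %in% removed_union)

  report <- structure(list(
    n_input = length(probes),
    n_removed_detection = length(removed$detection),
    n_removed_cross_reactive = length(removed$cross_reactive),
    n_removed_snp = length(removed$snp),
    n_removed_sex = length(removed$sex),
    n_removed_total = length(removed_union),
    n_retained = sum(keep),
    retain_sex = retain_sex,
    removed_ids_by_reason = removed), class = "filter_report")

  list(beta = b[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Probe filter: %d input, %d retained (%d removed)\n",
              x$n_input, x$n_retained, x$n_removed_total))
  cat(sprintf("  detection fail: %d, cross-reactive: %d, SNP: %d, sex: %d%s\n",
              x$n_removed_detection, x$n_removed_cross_reactive,
              x$n_removed_snp, x$n_removed_sex,
              if (x$retain_sex) " (sex probes retained)" else ""))
  invisible(x)
}

#' Summarise a filter report as a table
#'
#' One row per removal reason plus union/retained/input totals, suitable for
#' writing with [write_tsv_report()] and re-parsing.
#'
#' @param r A `filter_report` from [filter_probes()].
#' @return Data frame with columns `reason` and `n_probes`.
#' @export
summarize_filtering <- function(r) {
  stopifnot(inherits(r, "filter_report"))
  data.frame(
    reason = c("input", "removed_detection", "removed_cross_reactive",
               "removed_snp", "removed_sex", "removed_any", "retained"),
    n_probes = c(r$n_input, r$n_removed_detection, r$n_removed_cross_reactive,
                 r$n_removed_snp, r$n_removed_sex, r$n_removed_total,
                 r$n_retained),
    stringsAsFactors = FALSE)
}
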