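#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation proportions with one
#' row per probe (unique rownames) and one column per sample (unique
#' colnames). Missing values (`NA`) are permitted; all non-missing values must
#' lie in `[0, 1]` up to a small numeric tolerance.
#'
#' @param values Numeric matrix with probe rownames and sample colnames.
#' @param tol Tolerance beyond `[0, 1]` before a value is rejected.
#' @return Invisibly, `values`, after validation.
#' @export
validate_beta_matrix <- function(values, tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  pr <- rownames(values)
  sm <- colnames(values)
  if (nrow(values) > 0L && (is.null(pr) || anyNA(pr) || any(pr == ""))) {
    stop("beta matrix must have non-empty probe rownames", call. = FALSE)
  }
  if (is.null(pr)) pr <- character(0)
  if (is.null(sm) || anyNA(sm) || any(sm == "")) {
    stop("beta matrix must have non-empty sample colnames", call. = FALSE)
  }
  if (anyDuplicated(pr)) {
    stop(sprintf("duplicated probe id: %s", pr[duplicated(pr)][1]), call. = FALSE)
  }
  if (anyDuplicated(sm)) {
    stop(sprintf("duplicated sample id: %s", sm[duplicated(sm)][1]), call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < -tol | values > 1 + tol), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("beta value %g out of [0,1] at probe '%s' (row %d), sample '%s' (column %d)",
                 values[i, j], pr[i], i, sm[j], j), call. = FALSE)
  }
  invisible(values)
}

infer_sep <- function(path, dialect = NULL) {
  if (!is.null(dialect)) {
    return(switch(tolower(dialect), csv = ",", tsv = "\t",
                  stop("dialect must be 'tsv' or 'csv'", call. = FALSE)))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a probes-by-samples beta matrix from TSV/CSV
#'
#' The first column holds probe ids, the header row sample ids; `NA` or empty
#' cells are parsed as missing. Lines starting with `#` (provenance headers
#' written by this package) are skipped. Values outside `[0, 1]` and duplicate
#' ids are rejected with the offending coordinates.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`; inferred from the file extension when
#'   `NULL`.
#' @return A validated numeric beta matrix.
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- infer_sep(path, dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = NULL)
  if (ncol(raw) < 1L) stop("malformed matrix file: no columns", call. = FALSE)
  probe_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(probe_ids)) {
    stop(sprintf("duplicated probe id: %s", probe_ids[duplicated(probe_ids)][1]),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicated sample id: %s", sample_ids[duplicated(sample_ids)][1]),
         call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  is_missing_token <- body == "NA" | body == ""
  bad <- which(is.na(num) & !is_missing_token, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric cell '%s' at row %d (probe '%s'), column %d (sample '%s')",
                 body[i, j], i, probe_ids[i], j, sample_ids[j]), call. = FALSE)
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  validate_beta_matrix(num)
  num
}

#' Write a beta matrix to TSV/CSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces the matrix exactly; missing cells are written as the
#' `NA` token. Optional provenance metadata is written as `#` header comments.
#'
#' @param m Beta matrix (validated before writing).
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`; inferred from the extension when `NULL`.
#' @param meta Optional named list of provenance values (e.g. config hash,
#'   seed) written as header comments.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(m, path, dialect = NULL, meta = NULL) {
  validate_beta_matrix(m)
  sep <- infer_sep(path, dialect)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  writeLines(paste(c("probe_id", colnames(m)), collapse = sep), con)
  if (nrow(m)) {
    chr <- array("NA", dim = dim(m))
    ok <- !is.na(m)
    chr[ok] <- sprintf("%.17g", m[ok])
    writeLines(paste(rownames(m), apply(chr, 1, paste, collapse = sep),
                     sep = sep), con)
  }
  invisible(path)
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into
#' `[clip_eps, 1 - clip_eps]`, so the result is always finite. The transform
#' is strictly monotone on the clipped range and missing values stay missing.
#'
#' @param b Beta matrix (or numeric vector/matrix of proportions).
#' @param clip_eps Clipping bound in `(0, 0.5)`; default 0.001 perturbs only
#'   boundary values.
#' @return Matrix (or vector) of finite M-values, same dimnames as `b`.
#' @export
beta_to_m <- function(b, clip_eps = 0.001) {
  if (!is.numeric(clip_eps) || length(clip_eps) != 1L ||
      clip_eps <= 0 || clip_eps >= 0.5) {
    stop("clip_eps must lie in (0, 0.5)", call. = FALSE)
  }
  if (is.matrix(b)) validate_beta_matrix(b)
  x <- pmin(pmax(b, clip_eps), 1 - clip_eps)
  log2(x / (1 - x))
}

#' Convert M-values back to beta values
#'
#' beta = 2^M / (1 + 2^M); inverse of [beta_to_m()] on the unclipped range.
#'
#' @param m Numeric matrix or vector of finite M-values.
#' @return Beta values in `(0, 1)`, same dimnames as `m`.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m) & !is.na(m))) {
    stop("M-values must be finite", call. = FALSE)
  }
  e <- 2^m
  e / (1 + e)
}

#' Select the k most variable probes
#'
#' Ranks probes by their across-sample standard deviation of beta (missing
#' values dropped per probe) and returns the top `k` probe ids. Ties are
#' broken by lexicographic probe id so the selection is deterministic.
#'
#' @param b Beta matrix.
#' @param k Number of probes to return; must not exceed `nrow(b)`.
#' @return Character vector of `k` probe ids, most variable first.
#' @export
select_top_variable <- function(b, k) {
  validate_beta_matrix(b)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > nrow(b)) {
    stop(sprintf("k must lie in [0, %d]", nrow(b)), call. = FALSE)
  }
  sds <- apply(b, 1, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  ord <- order(-sds, rownames(b), method = "radix")
  rownames(b)[ord][seq_len(k)]
}
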