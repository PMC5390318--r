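# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# session RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic lexicographic (C locale) ordering.
radix_order <- function(...) order(..., method = "radix")

# Inverse logit on the natural-log scale.
inv_logit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# Canonical yaml serialisation + md5, used to stamp outputs with a config hash.
config_hash <- function(x) {
  txt <- yaml::as.yaml(x)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

# Header-comment lines ("# key: value") written above TSV outputs.
meta_header <- function(meta) {
  if (is.null(meta) || !length(meta)) return(character(0))
  sprintf("# %s: %s", names(meta), vapply(meta, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)))
}

#' Write a data frame as TSV with provenance header comments
#'
#' All tabular pipeline outputs go through this writer so that every file
#' records the configuration hash and seed that produced it as `#`-prefixed
#' header comments, which the package's readers skip.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param meta Optional named list written as `# name: value` header lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#'
#' @param path Input path.
#' @return A data frame; `#` header comments are skipped.
#' @export
read_tsv_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, na.strings = "NA")
}
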