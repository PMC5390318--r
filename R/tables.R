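# Sample-sheet and probe-annotation tables: validation and plain-text I/O.

FEATURE_CLASSES <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body",
                     "UTR3", "Intergenic")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
CHROMOSOMES <- c(as.character(1:22), "X", "Y")
METH_CLASSES <- c("hypo", "intermediate", "hyper")

#' Validate a sample sheet
#'
#' Per-sample traits for a matched multi-tissue study: sample id, donor id,
#' tissue, chip (batch label), age at death (years), cause of death and
#' post-mortem preservation interval (hours). Sample ids and (donor, tissue)
#' pairs must be unique.
#'
#' @param sheet Data frame with at least columns `sample_id`, `donor_id`,
#'   `tissue`, `chip`; optional `age_at_death`, `cause_of_death`,
#'   `preservation_interval`.
#' @return Invisibly, `sheet`.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "donor_id", "tissue", "chip")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) {
    stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop(sprintf("duplicated sample_id: %s",
                 sheet$sample_id[duplicated(sheet$sample_id)][1]), call. = FALSE)
  }
  key <- paste(sheet$donor_id, sheet$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicated (donor_id, tissue) pair: (%s, %s)",
                 sheet$donor_id[d], sheet$tissue[d]), call. = FALSE)
  }
  if ("age_at_death" %in% names(sheet) &&
      any(!is.na(sheet$age_at_death) & sheet$age_at_death < 0)) {
    stop("age_at_death must be nonnegative", call. = FALSE)
  }
  if ("preservation_interval" %in% names(sheet) &&
      any(!is.na(sheet$preservation_interval) & sheet$preservation_interval < 0)) {
    stop("preservation_interval must be nonnegative", call. = FALSE)
  }
  invisible(sheet)
}

#' Validate a probe annotation table
#'
#' Illumina-manifest-like per-probe annotation: chromosome, one genomic
#' feature class, one CpG-island relation and QC flags. Probes carrying
#' multiple manifest feature annotations are expected to have been collapsed
#' to a single class already (see the package vignette for the fixed
#' priority rule used by the simulator).
#'
#' @param ann Data frame with columns `probe_id`, `chromosome`,
#'   `feature_class`, `island_relation`, `cross_reactive`, `snp_flag`.
#' @return Invisibly, `ann`.
#' @export
validate_probe_annotation <- function(ann) {
  req <- c("probe_id", "chromosome", "feature_class", "island_relation",
           "cross_reactive", "snp_flag")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop(sprintf("probe annotation missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) {
    stop(sprintf("duplicated probe_id: %s",
                 ann$probe_id[duplicated(ann$probe_id)][1]), call. = FALSE)
  }
  bad <- setdiff(unique(ann$chromosome), CHROMOSOMES)
  if (length(bad)) stop(sprintf("unknown chromosome: %s", bad[1]), call. = FALSE)
  bad <- setdiff(unique(ann$feature_class), FEATURE_CLASSES)
  if (length(bad)) stop(sprintf("unknown feature_class: %s", bad[1]), call. = FALSE)
  bad <- setdiff(unique(ann$island_relation), ISLAND_RELATIONS)
  if (length(bad)) stop(sprintf("unknown island_relation: %s", bad[1]), call. = FALSE)
  if (!is.logical(ann$cross_reactive) || !is.logical(ann$snp_flag)) {
    stop("cross_reactive and snp_flag must be logical", call. = FALSE)
  }
  invisible(ann)
}

#' Collapse multiple feature annotations to a single class
#'
#' HM450K manifest rows can list several gene-feature annotations per probe;
#' downstream tables use exactly one. This collapses by the fixed priority
#' TSS200 > TSS1500 > UTR5 > FirstExon > Body > UTR3 > Intergenic.
#'
#' @param classes Character vector (or semicolon-separated string) of feature
#'   classes for one probe.
#' @return The single highest-priority class.
#' @export
collapse_feature_classes <- function(classes) {
  if (length(classes) == 1L && grepl(";", classes)) {
    classes <- strsplit(classes, ";", fixed = TRUE)[[1]]
  }
  classes <- unique(classes)
  bad <- setdiff(classes, FEATURE_CLASSES)
  if (length(bad)) stop(sprintf("unknown feature_class: %s", bad[1]), call. = FALSE)
  FEATURE_CLASSES[min(match(classes, FEATURE_CLASSES))]
}

#' Read a sample sheet (CSV)
#' @param path File path; `#` header comments are skipped.
#' @return Validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE,
                           colClasses = c(sample_id = "character",
                                          donor_id = "character",
                                          tissue = "character",
                                          chip = "character"))
  validate_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet (CSV)
#' @param sheet Validated sample sheet.
#' @param path Output path.
#' @param meta Optional provenance header comments.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path, meta = NULL) {
  validate_sample_sheet(sheet)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(sheet, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a probe annotation table (TSV)
#' @param path File path; `#` header comments are skipped.
#' @return Validated probe annotation data frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(probe_id = "character",
                                          chromosome = "character"))
  ann$cross_reactive <- as.logical(ann$cross_reactive)
  ann$snp_flag <- as.logical(ann$snp_flag)
  validate_probe_annotation(ann)
  ann
}

#' Write a probe annotation table (TSV)
#' @param ann Validated probe annotation.
#' @param path Output path.
#' @param meta Optional provenance header comments.
#' @return Invisibly, `path`.
#' @export
write_probe_annotation <- function(ann, path, meta = NULL) {
  validate_probe_annotation(ann)
  write_tsv_report(ann, path, meta = meta)
}

# Align a sample sheet to the columns of a beta matrix; every sample in the
# matrix must appear exactly once in the sheet.
align_sheet <- function(sheet, b) {
  validate_sample_sheet(sheet)
  miss <- setdiff(colnames(b), sheet$sample_id)
  if (length(miss)) {
    stop(sprintf("sample '%s' missing from sample sheet", miss[1]), call. = FALSE)
  }
  sheet[match(colnames(b), sheet$sample_id), , drop = FALSE]
}
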