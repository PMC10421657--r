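## AIRR Rearrangement I/O ---------------------------------------------------

# Stable column order for AIRR export; junction_aa/junction carry the CDR3
# with its conserved C...W anchors, following the AIRR Rearrangement schema.
AIRR_COLUMNS <- c("sequence_id", "sample_id", "junction_aa", "junction",
                  "v_call", "d_call", "j_call", "c_call",
                  "duplicate_count", "frequency")

#' Read clonotype tables in AIRR Rearrangement TSV format
#'
#' Reads a tab-separated clonotype table (one row per clonotype per sample)
#' plus a sample metadata table and assembles a validated [bcr_cohort].
#' The isotype of each record is derived from the constant-region call
#' (`c_call` starting with "IGHG" maps to IGHG, "IGHM" to IGHM). Rows sharing
#' a clonotype key within a (sample, isotype) are merged by summing counts,
#' and frequencies are recomputed as count over the (sample, isotype) total,
#' whether or not a frequency column is present.
#'
#' @param path AIRR TSV with at least columns `sample_id`, `junction_aa`,
#'   `v_call`, `j_call`, `duplicate_count`; optional `sequence_id`,
#'   `junction`, `d_call`, `c_call`, `frequency`.
#' @param metadata_path TSV with columns `sample_id`, `group` (one of
#'   [GROUP_LEVELS]); an optional `isotype` column is ignored on read since
#'   isotype is a record-level attribute.
#' @return a [bcr_cohort]
#' @export
read_airr <- function(path, metadata_path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c("", "NA"), quote = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("sample_id", "junction_aa", "v_call", "j_call",
                "duplicate_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("format error: AIRR file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            check.names = FALSE, fileEncoding = "UTF-8")

  if (nrow(tab) == 0) {
    records <- data.frame(sample_id = character(), isotype = character(),
                          cdr3_aa = character(), v_call = character(),
                          j_call = character(), count = integer(),
                          stringsAsFactors = FALSE)
    return(bcr_cohort(records, meta))
  }

  count <- suppressWarnings(as.integer(tab$duplicate_count))
  if (any(is.na(count))) {
    stop("validation error: non-integer duplicate_count")
  }
  if (any(count < 1)) {
    stop("validation error: zero or negative duplicate_count row(s) present")
  }
  c_call <- if ("c_call" %in% names(tab)) tab$c_call else NA_character_
  records <- data.frame(
    sequence_id = if ("sequence_id" %in% names(tab)) tab$sequence_id
                  else NA_character_,
    sample_id = tab$sample_id,
    isotype = isotype_from_c_call(c_call),
    c_call = c_call,
    cdr3_aa = tab$junction_aa,
    cdr3_nt = if ("junction" %in% names(tab)) tab$junction else NA_character_,
    v_call = tab$v_call,
    d_call = if ("d_call" %in% names(tab)) tab$d_call else NA_character_,
    j_call = tab$j_call,
    count = count,
    stringsAsFactors = FALSE
  )
  bcr_cohort(records, meta)
}

# "IGHG1", "IGHG3/4" -> IGHG; "IGHM" -> IGHM; missing c_call is an error
# because isotype drives frequency normalization.
isotype_from_c_call <- function(c_call) {
  iso <- rep(NA_character_, length(c_call))
  iso[grepl("^IGHG", c_call)] <- "IGHG"
  iso[grepl("^IGHM", c_call)] <- "IGHM"
  if (any(is.na(iso))) {
    stop("validation error: cannot derive isotype from c_call value(s): ",
         paste(utils::head(unique(c_call[is.na(iso)]), 3), collapse = ", "))
  }
  iso
}

#' Write a cohort to AIRR Rearrangement TSV plus metadata TSV
#'
#' Columns are written in a stable order so that identical cohorts produce
#' byte-identical files; `read_airr(write_airr(x))` round-trips exactly.
#'
#' @param cohort a [bcr_cohort]
#' @param path output AIRR TSV path
#' @param metadata_path output metadata TSV path; default replaces the file
#'   extension of `path` with `_metadata.tsv`
#' @return invisibly, the paths written
#' @export
write_airr <- function(cohort, path,
                       metadata_path = sub("\\.tsv$", "_metadata.tsv", path)) {
  stopifnot(inherits(cohort, "bcr_cohort"))
  rec <- cohort$records
  out <- data.frame(
    sequence_id = if (nrow(rec)) ifelse(is.na(rec$sequence_id),
                                        sprintf("seq%06d", seq_len(nrow(rec))),
                                        rec$sequence_id) else character(),
    sample_id = rec$sample_id,
    junction_aa = rec$cdr3_aa,
    junction = rec$cdr3_nt,
    v_call = rec$v_call,
    d_call = rec$d_call,
    j_call = rec$j_call,
    c_call = if (nrow(rec)) ifelse(is.na(rec$c_call), rec$isotype, rec$c_call)
             else character(),
    duplicate_count = rec$count,
    frequency = if (nrow(rec)) format_frequency(rec$frequency) else character(),
    stringsAsFactors = FALSE
  )
  write_tsv(out[, AIRR_COLUMNS, drop = FALSE], path)
  write_tsv(cohort$metadata, metadata_path)
  invisible(c(path, metadata_path))
}

format_frequency <- function(f) formatC(f, digits = 12, format = "g")

# Plain TSV writer: UTF-8, '.' decimal separator, no quoting, NA as empty.
write_tsv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Filter a repertoire sample by clonotype frequency
#'
#' Retains clonotypes with frequency strictly greater than `min_frequency`
#' (the strict inequality matches the "frequency > 0.001" rule used before
#' IGHG beta diversity). Frequencies are not renormalized unless asked.
#'
#' @param sample a `repertoire_sample` from [repertoire_samples()]
#' @param min_frequency threshold in `[0, 1)`
#' @param renormalize if `TRUE`, rescale retained frequencies to sum to 1
#' @return a filtered `repertoire_sample`
#' @export
filter_by_frequency <- function(sample, min_frequency, renormalize = FALSE) {
  stopifnot(inherits(sample, "repertoire_sample"),
            is.numeric(min_frequency), length(min_frequency) == 1,
            min_frequency >= 0, min_frequency < 1)
  keep <- sample$records$frequency > min_frequency
  sample$records <- sample$records[keep, , drop = FALSE]
  if (renormalize && nrow(sample$records) > 0) {
    sample$records$frequency <-
      sample$records$frequency / sum(sample$records$frequency)
  }
  sample$total_migs <- sum(sample$records$count)
  sample
}
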