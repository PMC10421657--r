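#' @keywords internal
"_PACKAGE"

## Study design constants --------------------------------------------------

#' Cohort group levels
#'
#' The five study groups: pemphigus foliaceus patients without treatment,
#' under immunosuppressive treatment, in remission, healthy controls from the
#' endemic area, and healthy controls from outside the endemic area.
#'
#' @export
GROUP_LEVELS <- c("nontreated", "treated", "remission",
                  "endemic_control", "nonendemic_control")

#' Groups counted as patients (pemphigus foliaceus cases)
#' @export
PATIENT_GROUPS <- c("nontreated", "treated", "remission")

#' Groups sampled in the endemic area
#' @export
ENDEMIC_GROUPS <- c("nontreated", "treated", "remission", "endemic_control")

#' Isotype levels analyzed
#' @export
ISOTYPE_LEVELS <- c("IGHM", "IGHG")

#' Twenty-letter amino-acid alphabet
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Cohort container ---------------------------------------------------------

#' Construct a clonotype cohort
#'
#' A cohort bundles a clonotype record table (one row per clonotype per
#' sample per isotype) with sample-level metadata. Records are aggregated by
#' clonotype key and frequencies are normalized per (sample, isotype) so the
#' container always satisfies its invariants.
#'
#' @param records data.frame with columns `sample_id`, `isotype`, `cdr3_aa`,
#'   `v_call`, `j_call`, `count`, and optionally `sequence_id`, `cdr3_nt`,
#'   `d_call`, `c_call`, `frequency`.
#' @param metadata data.frame with columns `sample_id`, `group`; `group` must
#'   be one of [GROUP_LEVELS].
#' @return An object of class `bcr_cohort`: a list with elements `records`
#'   (the validated, aggregated record table, including a `group` column) and
#'   `metadata`.
#' @export
bcr_cohort <- function(records, metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata error: metadata must have columns sample_id and group")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  bad <- setdiff(unique(metadata$group), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("metadata error: unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata error: duplicated sample_id in metadata")
  }

  records <- normalize_records(records)
  unknown <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(unknown) > 0) {
    stop("metadata error: samples absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  records$group <- metadata$group[match(records$sample_id, metadata$sample_id)]
  records <- aggregate_clonotypes(records)
  records <- recompute_frequencies(records)

  structure(list(records = records, metadata = metadata),
            class = "bcr_cohort")
}

# Coerce a raw record table to canonical columns and types; validates
# sequences and counts.
normalize_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("sample_id", "isotype", "cdr3_aa", "v_call", "j_call", "count")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("sequence_id", "cdr3_nt", "d_call", "c_call")) {
    if (!col %in% names(records)) {
      records[[col]] <- rep(NA_character_, nrow(records))
    }
  }
  if (!"frequency" %in% names(records)) {
    records$frequency <- rep(NA_real_, nrow(records))
  }

  records$sample_id <- as.character(records$sample_id)
  records$isotype <- as.character(records$isotype)
  records$cdr3_aa <- toupper(as.character(records$cdr3_aa))
  records$count <- as.integer(records$count)

  if (nrow(records) > 0) {
    bad_iso <- setdiff(unique(records$isotype), ISOTYPE_LEVELS)
    if (length(bad_iso) > 0) {
      stop("validation error: unknown isotype(s): ",
           paste(bad_iso, collapse = ", "))
    }
    if (any(is.na(records$count) | records$count < 1)) {
      stop("validation error: every clonotype needs count >= 1 (zero or ",
           "missing counts found)")
    }
    if (any(is.na(records$cdr3_aa) | nchar(records$cdr3_aa) == 0)) {
      stop("validation error: empty cdr3_aa sequence")
    }
    check_aa(records$cdr3_aa)
    has_nt <- !is.na(records$cdr3_nt) & nzchar(records$cdr3_nt)
    if (any(has_nt)) {
      nt <- toupper(records$cdr3_nt[has_nt])
      if (any(nchar(nt) != 3L * nchar(records$cdr3_aa[has_nt]))) {
        stop("validation error: cdr3_nt length must be 3 x cdr3_aa length")
      }
      if (any(grepl("[^ACGT]", nt))) {
        stop("validation error: cdr3_nt contains characters outside {A,C,G,T}")
      }
      records$cdr3_nt[has_nt] <- nt
    }
  }
  records
}

check_aa <- function(seqs) {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs[i])
    stop(sprintf(
      "validation error: invalid residue '%s' at position %d of sequence '%s'",
      substr(seqs[i], pos, pos), as.integer(pos), seqs[i]))
  }
  invisible(TRUE)
}

#' Clonotype identity key
#'
#' Clonotypes are keyed by (CDR3 nucleotide sequence if present, else amino
#' acid sequence) together with the V and J gene calls, within a
#' (sample, isotype). This mirrors MiXCR-style aggregation and degrades
#' gracefully when nucleotide data is absent.
#'
#' @param records clonotype record data.frame
#' @return character vector of keys, one per row
#' @export
clonotype_key <- function(records) {
  seq_key <- ifelse(!is.na(records$cdr3_nt) & nzchar(records$cdr3_nt),
                    records$cdr3_nt, records$cdr3_aa)
  paste(records$sample_id, records$isotype, seq_key,
        records$v_call, records$j_call, sep = "\r")
}

# Merge rows sharing a clonotype key: counts summed, first row's annotations
# kept.
aggregate_clonotypes <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- clonotype_key(records)
  if (!anyDuplicated(key)) return(records)
  counts <- rowsum(records$count, key, reorder = FALSE)
  first <- records[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(counts[match(unique(key), rownames(counts)), 1])
  rownames(first) <- NULL
  first
}

# frequency = count / total count within each (sample, isotype)
recompute_frequencies <- function(records) {
  if (nrow(records) == 0) return(records)
  unit <- paste(records$sample_id, records$isotype, sep = "\r")
  totals <- rowsum(as.numeric(records$count), unit)
  records$frequency <- records$count / totals[match(unit, rownames(totals)), 1]
  records
}

#' @export
print.bcr_cohort <- function(x, ...) {
  cat(sprintf("bcr_cohort: %d clonotype records, %d samples, %d groups\n",
              nrow(x$records), nrow(x$metadata),
              length(unique(x$metadata$group))))
  tab <- table(x$metadata$group)
  for (g in names(tab)) cat(sprintf("  %-20s n = %d\n", g, tab[[g]]))
  invisible(x)
}

#' Split a cohort into repertoire samples
#'
#' @param cohort a [bcr_cohort]
#' @param isotype optional isotype ("IGHM" or "IGHG") to restrict to
#' @return named list of `repertoire_sample` objects, one per
#'   (sample, isotype) present, each a list with `sample_id`, `group`,
#'   `isotype`, `records` (data.frame) and `total_migs`.
#' @export
repertoire_samples <- function(cohort, isotype = NULL) {
  stopifnot(inherits(cohort, "bcr_cohort"))
  rec <- cohort$records
  if (!is.null(isotype)) {
    isotype <- match.arg(isotype, ISOTYPE_LEVELS)
    rec <- rec[rec$isotype == isotype, , drop = FALSE]
  }
  if (nrow(rec) == 0) return(list())
  unit <- paste(rec$sample_id, rec$isotype, sep = ".")
  lapply(split(rec, unit), function(r) {
    structure(list(sample_id = r$sample_id[1],
                   group = r$group[1],
                   isotype = r$isotype[1],
                   records = r,
                   total_migs = sum(r$count)),
              class = "repertoire_sample")
  })
}

#' Validate cohort invariants
#'
#' Checks that per-(sample, isotype) frequencies sum to 1, clonotype keys are
#' unique, counts are positive, and all samples appear in the metadata.
#'
#' @param cohort a [bcr_cohort]
#' @param tol frequency-sum tolerance
#' @return `TRUE` invisibly; otherwise an error
#' @export
validate_cohort <- function(cohort, tol = 1e-9) {
  stopifnot(inherits(cohort, "bcr_cohort"))
  rec <- cohort$records
  if (nrow(rec) > 0) {
    if (anyDuplicated(clonotype_key(rec))) {
      stop("invariant violated: duplicated clonotype key within a sample")
    }
    unit <- paste(rec$sample_id, rec$isotype, sep = "\r")
    sums <- rowsum(rec$frequency, unit)
    if (any(abs(sums - 1) > tol)) {
      stop("invariant violated: frequencies do not sum to 1 per (sample, isotype)")
    }
    if (any(rec$count < 1)) stop("invariant violated: count < 1")
    if (!all(rec$sample_id %in% cohort$metadata$sample_id)) {
      stop("invariant violated: record sample missing from metadata")
    }
  }
  invisible(TRUE)
}
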