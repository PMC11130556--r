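# Codon-aware detection of clade-diagnostic in-frame deletions:
# reading-frame inference and translation under the invertebrate
# mitochondrial genetic code, then shared-gap reporting against a
# full-length reference.

# NCBI genetic codes as 64-codon strings, codon order TTT, TTC, TTA,
# TTG, TCT, ... (bases cycling T, C, A, G; base 3 fastest).
.CODE_STRINGS <- list(
  `1` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `5` = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"
)

.codon_table <- function(table = 5L) {
  code <- .CODE_STRINGS[[as.character(table)]]
  if (is.null(code)) stop("unsupported translation table: ", table)
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(code, "", fixed = TRUE)[[1L]]
  names(aa) <- codons
  aa
}

.mask_bases <- function(mask) c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]

# translate one codon (3 IUPAC chars); ambiguity resolving to a unique
# amino acid is translated, anything else gives "X"
.translate_codon <- function(chars, tab) {
  masks <- unname(.IUPAC_MASK[chars])
  if (any(masks == 0L)) return("X")  # gap inside a codon
  combos <- expand.grid(.mask_bases(masks[1L]), .mask_bases(masks[2L]),
                        .mask_bases(masks[3L]), stringsAsFactors = FALSE)
  aas <- unique(tab[paste0(combos[[1L]], combos[[2L]], combos[[3L]])])
  if (length(aas) == 1L) aas else "X"
}

#' Translate a nucleotide sequence under a mitochondrial genetic code
#'
#' Defaults to NCBI translation table 5 (invertebrate mitochondrial:
#' ATA = Met, TGA = Trp, AGA/AGG = Ser). Codons containing ambiguity
#' codes are translated when every resolution gives the same amino acid,
#' otherwise `X`; stops print as `*`; a trailing partial codon is
#' dropped.
#'
#' @param seq gap-free IUPAC string.
#' @param offset reading-frame offset in `{0, 1, 2}`.
#' @param table NCBI translation table number (5 or 1).
#' @return amino-acid string.
#' @export
translate_mito <- function(seq, offset = 0L, table = 5L) {
  if (!offset %in% 0:2) stop("`offset` must be 0, 1 or 2")
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be gap-free")
  tab <- .codon_table(table)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (offset > 0L) chars <- chars[-seq_len(offset)]
  ncod <- length(chars) %/% 3L
  if (ncod == 0L) return("")
  aa <- vapply(seq_len(ncod), function(k)
    .translate_codon(chars[(3L * k - 2L):(3L * k)], tab), character(1L))
  paste(aa, collapse = "")
}

#' Infer the reading frame of a protein-coding barcode
#'
#' Returns the frame offset (0, 1 or 2) minimising the number of internal
#' stop codons under the chosen code; a correct CO1 barcode has exactly
#' one stop-free frame. Codons containing ambiguity codes are skipped in
#' stop counting; ties go to the smallest offset.
#'
#' @param seq gap-free IUPAC string of length >= 30.
#' @param table NCBI translation table number (default 5).
#' @return integer offset in `{0, 1, 2}`.
#' @export
detect_reading_frame <- function(seq, table = 5L) {
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be gap-free")
  if (nchar(seq) < 30L) stop("sequence shorter than 30 bp")
  stops <- vapply(0:2, function(off) {
    aa <- strsplit(translate_mito(seq, off, table), "", fixed = TRUE)[[1L]]
    sum(aa == "*")
  }, integer(1L))
  which.min(stops) - 1L  # which.min takes the first (smallest offset) on ties
}

#' Count internal stop codons per reading frame
#' @inheritParams detect_reading_frame
#' @return integer vector of stop counts for offsets 0, 1, 2.
#' @export
stop_counts <- function(seq, table = 5L) {
  vapply(0:2, function(off) {
    aa <- strsplit(translate_mito(seq, off, table), "", fixed = TRUE)[[1L]]
    sum(aa == "*")
  }, integer(1L))
}

#' Detect deletions shared across an alignment relative to a reference
#'
#' Finds maximal runs of alignment columns that are gaps in at least
#' `min_share` of the non-reference records while the reference carries a
#' base, and reports each with its reading-frame context (frame taken
#' from the ungapped reference).
#'
#' @param aln a `barcode_alignment` containing the reference record.
#' @param reference_id id of the full-length (gap-free over the reported
#'   runs) reference record.
#' @param min_share fraction of non-reference records that must carry the
#'   gap (default 1, i.e. a diagnostic character universal in the
#'   ingroup).
#' @param table NCBI translation table for frame inference (default 5).
#' @return list of objects of class `"indel_report"`, each a list with
#'   `column_start` (1-based alignment column), `length_bp`,
#'   `frame_preserving` (length divisible by 3), `aa_deleted`
#'   (`length_bp / 3`, `NA` when frame-breaking), `shared_by` (record
#'   ids carrying the whole gap) and `reference_id`.
#' @export
detect_shared_deletions <- function(aln, reference_id, min_share = 1.0,
                                    table = 5L) {
  if (!reference_id %in% aln$ids) stop("reference record not found: ", reference_id)
  if (min_share <= 0 || min_share > 1) stop("`min_share` must be in (0, 1]")
  others <- setdiff(aln$ids, reference_id)
  if (length(others) == 0L) stop("alignment holds only the reference")
  gap <- do.call(rbind, lapply(aln$seqs[others], function(s)
    strsplit(s, "", fixed = TRUE)[[1L]] == "-"))
  ref_gap <- strsplit(aln$seqs[[reference_id]], "", fixed = TRUE)[[1L]] == "-"
  share <- colMeans(gap)
  candidate <- share >= min_share & !ref_gap
  if (!any(candidate)) return(list())
  runs <- rle(candidate)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  lapply(keep, function(k) {
    cols <- starts[k]:ends[k]
    len <- length(cols)
    carriers <- others[rowSums(gap[, cols, drop = FALSE]) == len]
    structure(
      list(column_start = starts[k],
           length_bp = len,
           frame_preserving = len %% 3L == 0L,
           aa_deleted = if (len %% 3L == 0L) len %/% 3L else NA_integer_,
           shared_by = carriers,
           reference_id = reference_id),
      class = "indel_report"
    )
  })
}

#' @export
print.indel_report <- function(x, ...) {
  cat(sprintf("Shared deletion: columns %d-%d (%d bp, %s), carried by %d record(s)\n",
              x$column_start, x$column_start + x$length_bp - 1L, x$length_bp,
              if (x$frame_preserving)
                sprintf("in-frame, %d aa", x$aa_deleted) else "frame-breaking",
              length(x$shared_by)))
  invisible(x)
}

#' Test an alignment for a clade-diagnostic in-frame deletion
#'
#' Verdict is positive iff exactly one deletion of `expected_length`
#' overlapping `expected_region` is shared by *all* non-reference
#' records. The expected region is a window rather than a point because
#' the flanking sites of such gaps are typically too variable to pin the
#' position to a single column.
#'
#' @param aln a `barcode_alignment`.
#' @param reference_id full-length reference record id.
#' @param expected_length expected gap length in bp (default 6).
#' @param expected_region two alignment columns bounding the expected
#'   location (default `c(450, 510)`).
#' @param table NCBI translation table (default 5).
#' @return object of class `"genus_diagnosis"`: list with `positive`,
#'   `report` (the matching `indel_report` or `NULL`), `missing` (record
#'   ids lacking the gap) and `message`.
#' @export
diagnose_genus <- function(aln, reference_id, expected_length = 6L,
                           expected_region = c(450L, 510L), table = 5L) {
  others <- setdiff(aln$ids, reference_id)
  # relaxed share so near-universal gaps are still reported with the
  # records that lack them
  reports <- detect_shared_deletions(aln, reference_id,
                                     min_share = 0.5, table = table)
  in_region <- Filter(function(r) {
    r$length_bp == expected_length &&
      r$column_start <= expected_region[2L] &&
      (r$column_start + r$length_bp - 1L) >= expected_region[1L]
  }, reports)
  if (length(in_region) != 1L) {
    msg <- if (length(in_region) == 0L)
      sprintf("no shared %d bp deletion found in columns %d-%d",
              expected_length, expected_region[1L], expected_region[2L])
    else sprintf("%d distinct candidate deletions found in the expected region",
                 length(in_region))
    return(structure(list(positive = FALSE, report = NULL,
                          missing = others, message = msg),
                     class = "genus_diagnosis"))
  }
  rep1 <- in_region[[1L]]
  missing <- setdiff(others, rep1$shared_by)
  positive <- length(missing) == 0L
  msg <- if (positive)
    sprintf("diagnostic %d bp in-frame deletion (%d aa) at column %d shared by all %d records",
            rep1$length_bp, rep1$aa_deleted, rep1$column_start, length(others))
  else sprintf("deletion at column %d absent from: %s",
               rep1$column_start, paste(missing, collapse = ", "))
  structure(list(positive = positive, report = rep1,
                 missing = missing, message = msg),
            class = "genus_diagnosis")
}

#' @export
print.genus_diagnosis <- function(x, ...) {
  cat(sprintf("Diagnostic-indel verdict: %s\n",
              if (x$positive) "POSITIVE" else "negative"))
  cat(x$message, "\n")
  invisible(x)
}

#' Diagnostic report as a data frame / TSV
#'
#' @param reports list of `indel_report` objects from
#'   [detect_shared_deletions()].
#' @param path optional TSV output path.
#' @return data.frame with one row per reported deletion.
#' @export
indel_table <- function(reports, path = NULL) {
  tab <- data.frame(
    column_start = vapply(reports, `[[`, integer(1L), "column_start"),
    length_bp = vapply(reports, `[[`, integer(1L), "length_bp"),
    frame_preserving = vapply(reports, `[[`, logical(1L), "frame_preserving"),
    aa_deleted = vapply(reports, `[[`, integer(1L), "aa_deleted"),
    n_carriers = vapply(reports, function(r) length(r$shared_by), integer(1L)),
    carriers = vapply(reports, function(r) paste(r$shared_by, collapse = ","),
                      character(1L)),
    reference_id = vapply(reports, `[[`, character(1L), "reference_id"),
    row.names = NULL
  )
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
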