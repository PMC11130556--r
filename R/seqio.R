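# Reading, normalising and writing aligned barcode data.

#' Normalise a raw nucleotide string to the IUPAC alphabet
#'
#' Uppercases, maps U to T, strips whitespace and digits (as found in
#' formatted GenBank-style sequence blocks), and validates that every
#' remaining character is an IUPAC nucleotide code or the gap `-`.
#'
#' @param raw a single character string.
#' @return the normalised sequence string.
#' @examples
#' normalize_sequence("atgu-")      # "ATGT-"
#' normalize_sequence("AC GT\n12")  # "ACGT"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single character string")
  s <- toupper(raw)
  s <- gsub("[[:space:][:digit:]]", "", s)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) == 0L) stop("sequence is empty after normalisation")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!is_iupac_char(chars))
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at position %d (not an IUPAC nucleotide code)",
                 chars[bad[1L]], bad[1L]))
  s
}

#' Construct a barcode alignment object
#'
#' The container used throughout the package: equal-length normalised IUPAC
#' sequences with record ids, species labels and optional per-record
#' metadata.
#'
#' @param seqs named character vector of sequences (names = record ids),
#'   or an unnamed vector together with `ids`.
#' @param ids optional character vector of record ids.
#' @param species optional character vector of species labels (recycled
#'   `"unassigned"` when absent).
#' @param metadata optional named list of per-record metadata lists.
#' @param normalize normalise sequences first (default `TRUE`).
#' @return an object of class `"barcode_alignment"`: a list with elements
#'   `ids`, `seqs`, `species`, `length`, `metadata`.
#' @export
barcode_alignment <- function(seqs, ids = names(seqs), species = NULL,
                              metadata = NULL, normalize = TRUE) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(seqs) == 0L) stop("alignment must contain at least one record")
  seqs <- as.character(seqs)
  if (normalize) seqs <- vapply(seqs, normalize_sequence, character(1L))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences differ in length (not an alignment): ",
         paste(sprintf("%s (%d bp)", ids, lens), collapse = ", "))
  }
  if (is.null(species)) species <- rep("unassigned", length(ids))
  species <- as.character(species)
  names(species) <- ids
  structure(
    list(ids = ids, seqs = seqs, species = species,
         length = unname(lens[1L]), metadata = metadata),
    class = "barcode_alignment"
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("Barcode alignment: %d records x %d columns\n",
              length(x$ids), x$length))
  sp <- unique(x$species)
  cat(sprintf("Species labels: %d (%s)\n", length(sp),
              paste(utils::head(sp, 5L), collapse = ", ")))
  invisible(x)
}

#' Number of non-gap characters in each record
#'
#' @param aln a `barcode_alignment`.
#' @return named integer vector of ungapped sequence lengths.
#' @export
ungapped_lengths <- function(aln) {
  vapply(aln$seqs, function(s) nchar(gsub("-", "", s, fixed = TRUE)), integer(1L))
}

#' Read a species label table
#'
#' Tab-separated, two columns `record_id` and `species`; lines starting
#' with `#` are comments; an optional header line naming the two columns
#' is recognised and skipped.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping record id to species.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("labels file must have two tab-separated columns")
  if (tolower(tab[1L, 1L]) == "record_id") tab <- tab[-1L, , drop = FALSE]
  labels <- tab[[2L]]
  names(labels) <- tab[[1L]]
  if (anyDuplicated(names(labels)))
    stop("duplicate record ids in labels file: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  labels
}

#' Read an aligned FASTA file into a barcode alignment
#'
#' Sequences are normalised ([normalize_sequence()]). Species labels are
#' taken from the labels TSV when given; otherwise, when a record id
#' contains `|`, the token after the final `|` is used as the species and
#' the part before it as the record id; otherwise the species is
#' `"unassigned"`.
#'
#' @param fasta_path path to the aligned FASTA file.
#' @param labels_path optional path to a labels TSV
#'   (`record_id<TAB>species`).
#' @return a `barcode_alignment`.
#' @export
read_alignment <- function(fasta_path, labels_path = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  recs <- seqinr::read.fasta(fasta_path, as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1L))
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1L))

  species <- rep("unassigned", length(ids))
  has_pipe <- grepl("|", ids, fixed = TRUE)
  species[has_pipe] <- sub(".*\\|", "", ids[has_pipe])
  ids[has_pipe] <- sub("\\|[^|]*$", "", ids[has_pipe])

  if (!is.null(labels_path)) {
    labels <- read_labels(labels_path)
    unknown <- setdiff(names(labels), ids)
    if (length(unknown) > 0L)
      warning("labels reference unknown record ids: ",
              paste(unknown, collapse = ", "))
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0L)
      warning("records without a label (left 'unassigned'): ",
              paste(missing, collapse = ", "))
    hit <- ids %in% names(labels)
    species[hit] <- unname(labels[ids[hit]])
  }
  barcode_alignment(seqs, ids = ids, species = species)
}

#' Write a barcode alignment to FASTA
#'
#' Headers are `record_id` (species labels travel in a separate TSV, see
#' [write_labels()]). Lines wrap at 80 columns.
#'
#' @param aln a `barcode_alignment`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names = aln$ids,
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' Write a species label table
#' @param labels named character vector (record id -> species) or a
#'   `barcode_alignment` (its `species` field is used).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "barcode_alignment")) labels <- labels$species
  utils::write.table(
    data.frame(record_id = names(labels), species = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# round half away from zero to `digits` decimals (sprintf/round use
# half-to-even, which disagrees with how the reported percentages behave)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a distance matrix as a labelled percent CSV
#'
#' Square CSV with record ids as header row and first column; cells are
#' percentages to one decimal (half-away-from-zero rounding); diagonal is
#' `0.0`. The file round-trips through [read_distance_csv()] to within
#' 0.05 percentage points.
#'
#' @param m a `barcode_dist` (see [distance_matrix()]) or a square numeric
#'   matrix of fractional distances with dimnames.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_distance_csv <- function(m, path) {
  d <- if (inherits(m, "barcode_dist")) m$d else m
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  pct <- matrix(sprintf("%.1f", round_half_up(100 * d, 1L)),
                nrow = nrow(d), dimnames = dimnames(d))
  pct[is.na(d)] <- "NA"
  out <- cbind(record_id = rownames(d), as.data.frame(pct, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a percent distance CSV back into a fractional matrix
#'
#' Accepts the layout written by [write_distance_csv()]: ids in the first
#' column and the header row, percentage cells.
#'
#' @param path CSV path.
#' @return square numeric matrix of fractions with id dimnames.
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stop("distance CSV not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- tab[[1L]]
  d <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(d) <- "double"
  d <- d / 100
  rownames(d) <- ids
  if (!identical(colnames(d), ids))
    stop("distance CSV is not square with matching row/column ids")
  d
}
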