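# Per-species molecular characterisation: sample size, maximum
# intraspecific distance, minimum interspecific distance with nearest
# species, and an IUPAC majority consensus barcode.

.species_ids <- function(labels, sp) {
  if (!sp %in% labels) stop("unknown species: ", sp)
  names(labels)[labels == sp]
}

#' Maximum intraspecific barcode distance
#'
#' @param m a `barcode_dist`.
#' @param labels named character vector, record id -> species.
#' @param sp species name.
#' @return the maximum pairwise distance among the species' records as a
#'   fraction, or `NA` ("not applicable") when the species has a single
#'   record.
#' @export
max_intraspecific <- function(m, labels, sp) {
  ids <- intersect(.species_ids(labels, sp), m$ids)
  if (length(ids) == 0L) stop("species has no records in the matrix: ", sp)
  if (length(ids) == 1L) return(NA_real_)
  sub <- m$d[ids, ids]
  max(sub[upper.tri(sub)])
}

#' Minimum interspecific barcode distance and nearest species
#'
#' The minimum distance from any record of `sp` to any record of another
#' species. Ties between species are broken lexicographically by species
#' name.
#'
#' @inheritParams max_intraspecific
#' @return list with `distance` (fraction) and `nearest_species`.
#' @export
min_interspecific <- function(m, labels, sp) {
  ids <- intersect(.species_ids(labels, sp), m$ids)
  other <- m$ids[m$ids %in% names(labels) & labels[m$ids] != sp]
  if (length(other) == 0L) stop("only one species present; no interspecific distance")
  cross <- m$d[ids, other, drop = FALSE]
  dmin <- min(cross, na.rm = TRUE)
  hits <- which(cross <= dmin + 1e-15, arr.ind = TRUE)
  cand <- sort(unique(unname(labels[other[hits[, "col"]]])))
  list(distance = dmin, nearest_species = cand[1L])
}

#' IUPAC majority-rule consensus of aligned sequences
#'
#' Per column: gaps are ignored (a column that is all-gap is dropped);
#' input ambiguity codes contribute their base sets; if a single most
#' frequent base (counting plain A/C/G/T calls only) reaches the majority
#' threshold it is emitted, otherwise the minimal IUPAC code covering all
#' observed bases is emitted. A tie for the most frequent base therefore
#' always yields an ambiguity code (e.g. an even C/T column gives Y).
#'
#' @param seqs character vector of equal-length IUPAC strings.
#' @param majority fraction in \[0.5, 1\] a base must reach to be called
#'   (default 0.5).
#' @return consensus IUPAC string (gap-free).
#' @export
consensus_sequence <- function(seqs, majority = 0.5) {
  if (length(seqs) == 0L) stop("no sequences given")
  if (majority < 0.5 || majority > 1)
    stop("`majority` must be between 0.5 and 1")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  if (length(seqs) == 1L) return(gsub("-", "", seqs[[1L]], fixed = TRUE))
  masks <- do.call(rbind, lapply(seqs, seq_to_mask))  # records x columns
  out <- character(ncol(masks))
  for (col in seq_len(ncol(masks))) {
    mk <- masks[, col]
    mk <- mk[mk > 0L]                     # ignore gaps
    if (length(mk) == 0L) { out[col] <- ""; next }  # all-gap column dropped
    plain <- mk[.is_plain_base(mk)]
    if (length(plain) > 0L) {
      counts <- tabulate(match(plain, c(1L, 2L, 4L, 8L)), nbins = 4L)
      top <- which(counts == max(counts))
      if (length(top) == 1L && counts[top] / length(plain) >= majority) {
        out[col] <- mask_to_code(c(1L, 2L, 4L, 8L)[top])
        next
      }
    }
    out[col] <- mask_to_code(Reduce(bitwOr, mk))
  }
  paste(out, collapse = "")
}

#' Molecular characterisation of one species
#'
#' Assembles the per-species summary reported in barcode studies: sample
#' size, maximum intraspecific distance, minimum interspecific distance
#' with the nearest species, and the species' consensus barcode.
#'
#' @param aln a `barcode_alignment`.
#' @param sp species name.
#' @param labels record id -> species map (defaults to the alignment's
#'   own labels).
#' @param policy a [distance_policy()].
#' @param majority consensus threshold, see [consensus_sequence()].
#' @param m optional precomputed `barcode_dist` for `aln` (avoids
#'   recomputation across species).
#' @return object of class `"species_profile"`: list with `species`, `n`,
#'   `max_intra`, `min_inter`, `nearest_species`, `consensus`.
#' @export
species_profile <- function(aln, sp, labels = aln$species,
                            policy = distance_policy(), majority = 0.5,
                            m = NULL) {
  if (is.null(m)) m <- distance_matrix(aln, policy)
  ids <- .species_ids(labels, sp)
  inter <- min_interspecific(m, labels, sp)
  structure(
    list(species = sp,
         n = length(ids),
         max_intra = max_intraspecific(m, labels, sp),
         min_inter = inter$distance,
         nearest_species = inter$nearest_species,
         consensus = consensus_sequence(unname(aln$seqs[ids]), majority)),
    class = "species_profile"
  )
}

#' Characterise every species in an alignment
#'
#' @inheritParams species_profile
#' @return named list of [species_profile()] objects, one per species
#'   (label `"unassigned"` records are skipped).
#' @export
species_profiles <- function(aln, labels = aln$species,
                             policy = distance_policy(), majority = 0.5) {
  m <- distance_matrix(aln, policy)
  sps <- sort(setdiff(unique(labels), "unassigned"))
  if (length(sps) < 2L) stop("need at least two labelled species")
  out <- lapply(sps, function(sp)
    species_profile(aln, sp, labels, policy, majority, m = m))
  names(out) <- sps
  out
}

#' Format a fractional distance as a report percentage
#'
#' One decimal, half-away-from-zero; values of 10% or more whose decimal
#' is zero print as integers ("12%" rather than "12.0%").
#'
#' @param frac fraction in \[0,1\].
#' @return character, e.g. `"2.5%"`, `"12%"`.
#' @export
format_pct <- function(frac) {
  pct <- round_half_up(100 * frac, 1L)
  ifelse(pct >= 10 & pct == floor(pct),
         sprintf("%d%%", as.integer(pct)),
         sprintf("%.1f%%", pct))
}

#' @export
print.species_profile <- function(x, ...) {
  cat(format_profile(x), sep = "\n")
  invisible(x)
}

format_profile <- function(p) {
  intra <- if (is.na(p$max_intra)) {
    sprintf("Maximum barcode-distance within species: not applicable (%d).", p$n)
  } else {
    sprintf("Maximum barcode-distance within species: %s (%d).",
            format_pct(p$max_intra), p$n)
  }
  c(sprintf("## %s", p$species),
    "",
    intra,
    sprintf("Minimum barcode-distance to closest species: %s (%s).",
            format_pct(p$min_inter), p$nearest_species),
    "",
    sprintf("Consensus barcode sequence (%d bp):", nchar(p$consensus)),
    p$consensus)
}

#' Plain-text characterisation report
#'
#' One block per species, in the layout of a taxonomic "molecular
#' characterisation" section.
#'
#' @param profiles list of [species_profile()] objects.
#' @param path optional output file; when given the report is written
#'   there.
#' @return character vector of report lines, invisibly when `path` is
#'   given.
#' @export
characterisation_report <- function(profiles, path = NULL) {
  if (length(profiles) == 0L) stop("no profiles given")
  lines <- unlist(lapply(profiles, function(p) c(format_profile(p), "")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Species profiles as a data frame / TSV
#'
#' @param profiles list of [species_profile()] objects.
#' @param path optional TSV output path.
#' @return data.frame with columns `species`, `n`, `max_intra_pct`,
#'   `min_inter_pct`, `nearest`, `consensus`.
#' @export
profiles_table <- function(profiles, path = NULL) {
  tab <- data.frame(
    species = vapply(profiles, `[[`, character(1L), "species"),
    n = vapply(profiles, `[[`, integer(1L), "n"),
    max_intra_pct = round_half_up(
      100 * vapply(profiles, `[[`, numeric(1L), "max_intra"), 1L),
    min_inter_pct = round_half_up(
      100 * vapply(profiles, `[[`, numeric(1L), "min_inter"), 1L),
    nearest = vapply(profiles, `[[`, character(1L), "nearest_species"),
    consensus = vapply(profiles, `[[`, character(1L), "consensus"),
    row.names = NULL
  )
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
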