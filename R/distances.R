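# Uncorrected pairwise distances with explicit gap/ambiguity policy.

#' Site-exclusion policy for pairwise distances
#'
#' `pairwise_deletion_strict` (the default) drops an alignment column from
#' a pair whenever either sequence carries a gap or any non-ACGT code, so
#' ambiguity codes never contribute to a distance. `pairwise_deletion_gaps_only`
#' drops only gap columns; a column with ambiguity codes counts as a
#' difference unless the two base sets intersect (Y vs C is a match,
#' Y vs A a difference).
#'
#' @param site_exclusion one of `"pairwise_deletion_strict"`,
#'   `"pairwise_deletion_gaps_only"`.
#' @return an object of class `"distance_policy"`.
#' @export
distance_policy <- function(site_exclusion = c("pairwise_deletion_strict",
                                               "pairwise_deletion_gaps_only")) {
  site_exclusion <- match.arg(site_exclusion)
  structure(list(site_exclusion = site_exclusion), class = "distance_policy")
}

#' @export
print.distance_policy <- function(x, ...) {
  cat("Distance policy:", x$site_exclusion, "\n")
  invisible(x)
}

.is_plain_base <- function(mask) mask == 1L | mask == 2L | mask == 4L | mask == 8L

# per-pair comparable/difference counts from mask vectors
.pair_counts <- function(m1, m2, policy) {
  if (policy$site_exclusion == "pairwise_deletion_strict") {
    keep <- .is_plain_base(m1) & .is_plain_base(m2)
    diff <- keep & (m1 != m2)
  } else {
    keep <- m1 > 0L & m2 > 0L
    diff <- keep & bitwAnd(m1, m2) == 0L
  }
  c(comparable = sum(keep), diff = sum(diff))
}

#' Count alignment columns retained for a sequence pair
#'
#' @param a,b equal-length normalised IUPAC strings.
#' @param policy a [distance_policy()].
#' @return integer count of comparable sites.
#' @export
comparable_sites <- function(a, b, policy = distance_policy()) {
  if (nchar(a) != nchar(b))
    stop(sprintf("sequence lengths differ (%d vs %d)", nchar(a), nchar(b)))
  unname(.pair_counts(seq_to_mask(a), seq_to_mask(b), policy)["comparable"])
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the columns retained under the
#' policy; no multiple-hit correction is applied (distances are the raw
#' "barcode distances" of barcode-gap analysis).
#'
#' @inheritParams comparable_sites
#' @return list with elements `distance` (fraction in \[0,1\], `NA` when no
#'   site is comparable) and `comparable` (site count).
#' @export
p_distance <- function(a, b, policy = distance_policy()) {
  if (nchar(a) != nchar(b))
    stop(sprintf("sequence lengths differ (%d vs %d)", nchar(a), nchar(b)))
  ct <- .pair_counts(seq_to_mask(a), seq_to_mask(b), policy)
  if (ct["comparable"] == 0L)
    return(list(distance = NA_real_, comparable = 0L))
  list(distance = unname(ct["diff"] / ct["comparable"]),
       comparable = unname(as.integer(ct["comparable"])))
}

#' Pairwise distance matrix for a barcode alignment
#'
#' @param aln a `barcode_alignment` with at least two records.
#' @param policy a [distance_policy()].
#' @return an object of class `"barcode_dist"`: list with `ids`, `d`
#'   (square symmetric matrix of fractions, zero diagonal, `NA` where a
#'   pair has no comparable site), `comparable` (site counts) and
#'   `policy`.
#' @export
distance_matrix <- function(aln, policy = distance_policy()) {
  n <- length(aln$ids)
  if (n < 2L) stop("distance matrix requires at least two records")
  masks <- lapply(aln$seqs, seq_to_mask)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  comp <- matrix(aln$length, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ct <- .pair_counts(masks[[i]], masks[[j]], policy)
      comp[i, j] <- comp[j, i] <- ct["comparable"]
      d[i, j] <- d[j, i] <-
        if (ct["comparable"] == 0L) NA_real_ else ct["diff"] / ct["comparable"]
    }
  }
  diag(comp) <- vapply(masks, function(m) {
    if (policy$site_exclusion == "pairwise_deletion_strict")
      sum(.is_plain_base(m)) else sum(m > 0L)
  }, numeric(1L))
  structure(list(ids = aln$ids, d = d, comparable = comp, policy = policy),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("Barcode distance matrix: %d records (%s)\n",
              length(x$ids), x$policy$site_exclusion))
  if (all(is.na(off))) {
    cat("all pairwise distances undefined\n")
  } else {
    cat(sprintf("pairwise distances: %.1f%% - %.1f%%\n",
                100 * min(off, na.rm = TRUE), 100 * max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Convert a barcode distance matrix to a `stats::dist`
#' @param m a `barcode_dist`.
#' @return a `dist` object (fractions).
#' @export
as_dist <- function(m) {
  stopifnot(inherits(m, "barcode_dist"))
  stats::as.dist(m$d)
}
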