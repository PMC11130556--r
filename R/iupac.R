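# IUPAC nucleotide machinery shared by all modules.
#
# Codes are represented internally as 4-bit masks (A=1, C=2, G=4, T=8) so
# that set intersection/union of base sets is bit arithmetic. The gap "-"
# maps to mask 0.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L,
  "-" = 0L
)

# inverse lookup: mask (1..15) -> minimal IUPAC code
.MASK_CODE <- character(15L)
.MASK_CODE[.IUPAC_MASK[.IUPAC_MASK > 0L]] <- names(.IUPAC_MASK)[.IUPAC_MASK > 0L]

.IUPAC_CHARS <- names(.IUPAC_MASK)

#' Is a character vector made of valid IUPAC nucleotide codes?
#' @param x character vector of single characters
#' @return logical vector
#' @keywords internal
is_iupac_char <- function(x) x %in% .IUPAC_CHARS

#' Convert a sequence string to its vector of IUPAC bitmasks
#' @param seq a normalised IUPAC string
#' @return integer vector of 4-bit base-set masks (gap = 0)
#' @keywords internal
seq_to_mask <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  unname(.IUPAC_MASK[chars])
}

#' Minimal IUPAC code covering a set of bases
#' @param mask integer bitmask over A=1, C=2, G=4, T=8
#' @return single character
#' @keywords internal
mask_to_code <- function(mask) {
  stopifnot(mask >= 1L, mask <= 15L)
  .MASK_CODE[mask]
}
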