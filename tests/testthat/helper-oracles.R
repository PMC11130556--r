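# Independent brute-force oracles and small fixture builders used across
# the test files. These stay deliberately naive (character-by-character
# scans, boolean matrix closure) so they share no code with the
# implementation they check.

make_aln <- function(seqs, species = NULL, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs)
                           else paste0("r", seq_along(seqs))
  barcode_alignment(seqs, ids = ids, species = species)
}

# naive per-column p-distance under the strict policy
naive_p_strict <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  comp <- 0; diff <- 0
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("A", "C", "G", "T") && cb[i] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1
      if (ca[i] != cb[i]) diff <- diff + 1
    }
  }
  list(distance = if (comp == 0) NA_real_ else diff / comp, comparable = comp)
}

# exhaustive transitive closure of the graph with edges d < t
naive_components <- function(d, t) {
  n <- nrow(d)
  adj <- (d < t) | diag(n) > 0
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  comp
}

# random ACGT alignment with a few gaps/ambiguities
random_aln <- function(n, len, gap_rate = 0.03, amb_rate = 0.02) {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    gaps <- runif(len) < gap_rate
    chars[gaps] <- "-"
    amb <- runif(len) < amb_rate & !gaps
    chars[amb] <- sample(c("R", "Y", "N", "W"), sum(amb), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  make_aln(seqs)
}

# ingroup-only (652 bp, no reference) view of the published fixture
fixture_ingroup <- function() {
  fx <- fixture_paper_dataset(include_reference = FALSE)
  fx$alignment
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
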