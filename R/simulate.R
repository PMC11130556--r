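# Synthetic barcode datasets: Jukes-Cantor sequence evolution over a
# near-star ultrametric species tree, star-shaped intraspecific
# sampling, optional IUPAC ambiguity noise and an optional
# clade-restricted in-frame deletion. Every generated dataset carries a
# complete truth table so downstream stages can be tested against known
# labels.

#' Expected p-distance under the Jukes-Cantor model
#'
#' Closed form `p = 3/4 (1 - exp(-4/3 b))` for a path of `b` expected
#' substitutions per site; saturates at 0.75.
#'
#' @param branch_length expected substitutions per site (>= 0).
#' @return expected proportion of differing sites.
#' @export
jc_expected_distance <- function(branch_length) {
  if (any(branch_length < 0)) stop("branch length must be non-negative")
  0.75 * (1 - exp(-4 / 3 * branch_length))
}

#' Jukes-Cantor branch length giving an expected p-distance
#'
#' Inverse of [jc_expected_distance()].
#'
#' @param p expected p-distance in `[0, 0.75)`.
#' @return expected substitutions per site.
#' @export
jc_branch_length <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop("p must be in [0, 0.75)")
  -0.75 * log(1 - 4 / 3 * p)
}

#' Simulation configuration
#'
#' Defaults emulate a typical single-marker barcoding study of a small
#' genus: a handful of species with a clear barcode gap (about 1%
#' within-species vs 8% between-species divergence over a 658 bp
#' marker), occasional IUPAC ambiguity codes, and optionally a
#' clade-restricted in-frame 6 bp deletion near position 476.
#'
#' @param n_species number of species (>= 2).
#' @param n_per_species records per species; a single integer or one per
#'   species.
#' @param seq_length marker length in bp.
#' @param intra_divergence expected within-species p-distance.
#' @param inter_divergence expected between-species p-distance; must
#'   exceed `intra_divergence` (no barcode gap, nothing to recover).
#' @param ambiguity_rate per-site probability that a record's base is
#'   emitted as a two-base IUPAC code containing it.
#' @param deletion `NULL`, or a list with `clade` (species indices or
#'   names carrying the deletion), `length` (bp, default 6) and
#'   `position` (first deleted column, default 476).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 7L, n_per_species = 5L, seq_length = 658L,
                       intra_divergence = 0.01, inter_divergence = 0.08,
                       ambiguity_rate = 0.001, deletion = NULL) {
  if (n_species < 2L) stop("need at least 2 species")
  if (any(n_per_species < 1L)) stop("need at least 1 record per species")
  if (!length(n_per_species) %in% c(1L, n_species))
    stop("`n_per_species` must be a scalar or one value per species")
  if (intra_divergence >= inter_divergence)
    stop("intra_divergence must be below inter_divergence (no barcode gap otherwise)")
  if (inter_divergence >= 0.75) stop("inter_divergence saturates at 0.75")
  if (!is.null(deletion)) {
    deletion <- utils::modifyList(list(length = 6L, position = 476L), deletion)
    if (is.null(deletion$clade)) stop("deletion needs a `clade` of species")
    if (deletion$length >= seq_length) stop("deletion longer than the sequence")
    if (deletion$position + deletion$length - 1L > seq_length)
      stop("deletion extends past the end of the sequence")
  }
  structure(list(n_species = as.integer(n_species),
                 n_per_species = rep_len(as.integer(n_per_species), n_species),
                 seq_length = as.integer(seq_length),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 ambiguity_rate = ambiguity_rate,
                 deletion = deletion),
            class = "sim_config")
}

#' Simulate a near-star ultrametric species tree
#'
#' A random-ordered caterpillar topology whose internal nodes all sit
#' within 2% of the root depth, so that every leaf pair diverges at
#' (almost) the same depth and the expected pairwise p-distance matches
#' `inter_divergence` under Jukes-Cantor. Branch lengths are in expected
#' substitutions per site.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed (set it for reproducibility; when
#'   `NULL` the current RNG state is used).
#' @return an `ape::phylo` tree with tips `sp01 ... spNN`.
#' @export
simulate_species_tree <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_species
  depth <- jc_branch_length(cfg$inter_divergence) / 2
  tips <- sample(sprintf("sp%02d", seq_len(n)))
  if (n == 2L) {
    nwk <- sprintf("(%s:%.10f,%s:%.10f);", tips[1L], depth, tips[2L], depth)
    return(ape::read.tree(text = nwk))
  }
  # join heights ascending to the root, all within 2% of the depth
  h <- depth * (1 - 0.02 * ((n - 1L):1L - 1L) / (n - 2L))
  clade <- sprintf("(%s:%.10f,%s:%.10f)", tips[1L], h[1L], tips[2L], h[1L])
  for (j in 2L:(n - 1L)) {
    clade <- sprintf("(%s:%.10f,%s:%.10f)",
                     clade, h[j] - h[j - 1L], tips[j + 1L], h[j])
  }
  ape::read.tree(text = paste0(clade, ";"))
}

# evolve an integer-coded sequence (0..3) along a branch under JC
.jc_evolve <- function(seq, branch_length) {
  p <- 0.75 * (1 - exp(-4 / 3 * branch_length))
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit) > 0L)
    seq[hit] <- (seq[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  seq
}

#' Simulate a labelled barcode alignment
#'
#' Sites evolve i.i.d. under Jukes-Cantor: a uniform root sequence is
#' evolved down the species tree, then each record is drawn from its
#' species' ancestral sequence on a star with leg length calibrated so
#' two conspecific records diverge by `intra_divergence` in expectation.
#' Ambiguity codes are injected per site at `ambiguity_rate`; when a
#' deletion is configured, every record of the clade loses those columns
#' (represented as gap columns, keeping the alignment rectangular).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same `cfg` and `seed` reproduce the
#'   dataset exactly.
#' @return list with `alignment` (a `barcode_alignment`) and `truth`
#'   (list with `labels`, `tree`, `indels`).
#' @export
simulate_alignment <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  tree <- simulate_species_tree(cfg, seed = NULL)
  L <- cfg$seq_length
  n_tips <- cfg$n_species

  # evolve ancestral sequences down the tree (preorder over edges)
  root <- n_tips + 1L
  node_seq <- vector("list", max(tree$edge))
  node_seq[[root]] <- sample.int(4L, L, replace = TRUE) - 1L
  # cladewise edge order: every parent is assigned before its children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    node_seq[[child]] <- .jc_evolve(node_seq[[parent]], tree$edge.length[e])
  }
  species <- sprintf("sp%02d", seq_len(n_tips))
  anc <- node_seq[match(species, tree$tip.label)]

  leg <- jc_branch_length(cfg$intra_divergence) / 2
  ids <- character(0); sp_of <- character(0); seq_int <- list()
  for (s in seq_len(n_tips)) {
    for (r in seq_len(cfg$n_per_species[s])) {
      ids <- c(ids, sprintf("%s_r%02d", species[s], r))
      sp_of <- c(sp_of, species[s])
      seq_int[[length(seq_int) + 1L]] <- .jc_evolve(anc[[s]], leg)
    }
  }

  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_int, function(v) paste(bases[v + 1L], collapse = ""),
                 character(1L))

  # ambiguity injection: replace a base with a two-base code containing it
  if (cfg$ambiguity_rate > 0) {
    for (i in seq_along(seqs)) {
      hit <- which(stats::runif(L) < cfg$ambiguity_rate)
      if (length(hit) == 0L) next
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (pos in hit) {
        own <- .IUPAC_MASK[[chars[pos]]]
        other <- sample(setdiff(c(1L, 2L, 4L, 8L), own), 1L)
        chars[pos] <- mask_to_code(bitwOr(own, other))
      }
      seqs[i] <- paste(chars, collapse = "")
    }
  }

  indels <- list()
  if (!is.null(cfg$deletion)) {
    del <- cfg$deletion
    clade <- if (is.numeric(del$clade)) species[del$clade] else del$clade
    if (!all(clade %in% species)) stop("deletion clade names unknown species")
    cols <- del$position:(del$position + del$length - 1L)
    carriers <- which(sp_of %in% clade)
    for (i in carriers) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      chars[cols] <- "-"
      seqs[i] <- paste(chars, collapse = "")
    }
    indels <- list(list(clade = clade, position = del$position,
                        length = del$length))
  }

  labels <- sp_of
  names(labels) <- ids
  aln <- barcode_alignment(seqs, ids = ids, species = sp_of, normalize = FALSE)
  list(alignment = aln,
       truth = list(labels = labels, tree = tree, indels = indels))
}

#' Write a simulated dataset to disk
#'
#' Writes `alignment.fasta`, `labels.tsv`, `truth.tsv` and `tree.nwk`
#' into a directory.
#'
#' @param sim result of [simulate_alignment()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_alignment(sim$alignment, paths["alignment"])
  write_labels(sim$truth$labels, paths["labels"])
  utils::write.table(
    data.frame(record_id = names(sim$truth$labels),
               true_species = unname(sim$truth$labels)),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$tree, paths["tree"])
  invisible(paths)
}

#' The published seven-species barcode fixture
#'
#' Loads the seven full-length (652 bp) species consensus barcodes
#' printed in the source study, labelled by species. When
#' `include_reference = TRUE` the alignment is padded to 658 columns and
#' a synthetic full-length reference is added: the *P. villosa* sequence
#' with six neutral bases re-inserted at alignment position 476,
#' reconstructing the state of relatives that lack the genus-diagnostic
#' 6 bp deletion. The reference is synthetic (no such published
#' sequence); its id says so.
#'
#' @param include_reference add the 658-column synthetic reference and
#'   pad the ingroup with gap columns (default `TRUE`).
#' @return list with `alignment` (a `barcode_alignment`) and `labels`
#'   (record id -> species for the seven ingroup records).
#' @export
fixture_paper_dataset <- function(include_reference = TRUE) {
  fasta <- system.file("extdata", "phaenoglyphis_co1_consensus.fasta",
                       package = "bargap", mustWork = TRUE)
  labfile <- system.file("extdata", "phaenoglyphis_labels.tsv",
                         package = "bargap", mustWork = TRUE)
  aln <- read_alignment(fasta, labfile)
  labels <- aln$species
  if (!include_reference) return(list(alignment = aln, labels = labels))

  insert_at <- 476L
  insert <- "ATTACT"  # two neutral codons; position 476 is a codon start
  villosa <- aln$seqs[["P_villosa"]]
  ref <- paste0(substr(villosa, 1L, insert_at - 1L), insert,
                substr(villosa, insert_at, nchar(villosa)))
  padded <- vapply(aln$seqs, function(s)
    paste0(substr(s, 1L, insert_at - 1L), "------",
           substr(s, insert_at, nchar(s))), character(1L))
  seqs <- c(padded, REF_synthetic_fulllength = ref)
  species <- c(unname(labels), "reference")
  aln8 <- barcode_alignment(seqs, ids = names(seqs), species = species,
                            normalize = FALSE)
  list(alignment = aln8, labels = labels)
}
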