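# Orchestration of the full workflow (distances -> characterisation ->
# delimitation -> congruence -> diagnostics) and a thin command-line
# front end.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the whole barcode-analysis workflow
#'
#' Reads an aligned FASTA and a labels TSV, then writes, in order: the
#' percent distance CSV, the species-profile TSV and characterisation
#' report, the threshold partition TSV, the ranked-partitions report,
#' the congruence report against the labels (and against any supplied
#' external partitions), the diagnostic-indel report when a reference
#' record is named, and a run log.
#'
#' @param alignment_path aligned FASTA path.
#' @param labels_path labels TSV path (`record_id<TAB>species`).
#' @param out_dir output directory (created if needed).
#' @param threshold clustering threshold as a fraction (default 0.03).
#' @param policy a [distance_policy()].
#' @param majority consensus majority threshold (default 0.5).
#' @param reference_id optional full-length reference record for
#'   [diagnose_genus()]; the reference is excluded from
#'   characterisation and clustering.
#' @param expected_length,expected_region diagnostic-indel expectations,
#'   see [diagnose_genus()].
#' @param external_partitions optional named character vector of
#'   partition TSV paths to compare against the labels as well.
#' @param seed optional integer recorded in the run log (the pipeline
#'   itself is deterministic).
#' @return invisible list with the computed objects and an `artifacts`
#'   vector of file paths.
#' @export
run_pipeline <- function(alignment_path, labels_path, out_dir,
                         threshold = 0.03, policy = distance_policy(),
                         majority = 0.5, reference_id = NULL,
                         expected_length = 6L,
                         expected_region = c(450L, 510L),
                         external_partitions = NULL, seed = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("stage 'config': threshold must be in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)

  aln <- .stage("alignment", read_alignment(alignment_path))
  labels <- .stage("labels", read_labels(labels_path))
  known <- intersect(aln$ids, names(labels))
  aln$species[known] <- labels[known]

  ingroup <- aln
  if (!is.null(reference_id)) {
    if (!reference_id %in% aln$ids)
      stop("stage 'diagnose': reference record not found: ", reference_id)
    keep <- setdiff(aln$ids, reference_id)
    ingroup <- barcode_alignment(aln$seqs[keep], ids = keep,
                                 species = aln$species[keep],
                                 normalize = FALSE)
  }

  m <- .stage("distances", distance_matrix(ingroup, policy))
  art["distances"] <- file.path(out_dir, "distances.csv")
  write_distance_csv(m, art["distances"])

  profiles <- .stage("characterise",
                     species_profiles(ingroup, policy = policy,
                                      majority = majority))
  art["profiles"] <- file.path(out_dir, "species_profiles.tsv")
  profiles_table(profiles, art["profiles"])
  art["report"] <- file.path(out_dir, "characterisation.txt")
  characterisation_report(profiles, art["report"])

  part <- .stage("delimit", single_linkage_clusters(m, threshold))
  art["partition"] <- file.path(out_dir, "partition.tsv")
  write_partition_tsv(part, art["partition"])

  ranked <- .stage("delimit", ranked_partitions(m))
  art["ranked"] <- file.path(out_dir, "ranked_partitions.tsv")
  utils::write.table(
    data.frame(rank = vapply(ranked, `[[`, integer(1L), "rank"),
               k = vapply(ranked, function(r) r$partition$k, integer(1L)),
               interval_low = vapply(ranked, function(r) r$interval[1L], numeric(1L)),
               interval_high = vapply(ranked, function(r) r$interval[2L], numeric(1L)),
               gap_score = vapply(ranked, `[[`, numeric(1L), "gap_score")),
    art["ranked"], sep = "\t", quote = FALSE, row.names = FALSE)

  cmp <- .stage("congruence",
                compare_partition(part, ingroup$species))
  art["congruence"] <- file.path(out_dir, "congruence.tsv")
  utils::write.table(cmp$table, art["congruence"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ext_cmp <- list()
  for (nm in names(external_partitions)) {
    p_ext <- .stage("external partition", read_partition_tsv(external_partitions[[nm]]))
    ext_cmp[[nm]] <- compare_partition(p_ext, ingroup$species)
    path <- file.path(out_dir, sprintf("congruence_%s.tsv", nm))
    utils::write.table(ext_cmp[[nm]]$table, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    art[paste0("congruence_", nm)] <- path
  }

  diagnosis <- NULL
  if (!is.null(reference_id)) {
    diagnosis <- .stage("diagnose",
                        diagnose_genus(aln, reference_id, expected_length,
                                       expected_region))
    art["diagnosis"] <- file.path(out_dir, "diagnosis.txt")
    writeLines(c(sprintf("verdict: %s",
                         if (diagnosis$positive) "positive" else "negative"),
                 diagnosis$message), art["diagnosis"])
    if (!is.null(diagnosis$report)) {
      art["indels"] <- file.path(out_dir, "indels.tsv")
      indel_table(list(diagnosis$report), art["indels"])
    }
  }

  art["log"] <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("bargap %s | R %s", utils::packageVersion("bargap"),
            getRversion()),
    sprintf("alignment: %s (%d records x %d columns)", alignment_path,
            length(aln$ids), aln$length),
    sprintf("labels: %s", labels_path),
    sprintf("policy: %s | threshold: %g | majority: %g",
            policy$site_exclusion, threshold, majority),
    sprintf("reference: %s", if (is.null(reference_id)) "none" else reference_id),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), art["log"])

  invisible(list(alignment = aln, matrix = m, profiles = profiles,
                 partition = part, ranked = ranked, comparison = cmp,
                 external_comparisons = ext_cmp, diagnosis = diagnosis,
                 artifacts = art))
}

.cli_usage <- "usage: bargap <command> [options]

commands:
  distances    --alignment F [--labels F] [--policy P] --out FILE
  characterise --alignment F --labels F [--policy P] [--majority X] --out DIR
  delimit      --alignment F [--threshold T] [--policy P] --out FILE
  diagnose     --alignment F --reference ID [--length N] --out FILE
  simulate     --seed N --out DIR [--species N] [--per-species N]
               [--length N] [--intra X] [--inter X] [--deletion-clade a,b]
  run          --alignment F --labels F --out DIR [--threshold T]
               [--policy P] [--majority X] [--reference ID] [--seed N]

options:
  thresholds/divergences accept fractions (0.03) or percentages (3%)
  --policy is 'strict' (default) or 'gaps_only'
  --help prints this message"

#' Parse a threshold given as a fraction or a percentage
#'
#' Accepts `"0.03"` and `"3%"` alike, preventing the 0.03-versus-3
#' ambiguity in threshold flags.
#'
#' @param x a single string.
#' @return numeric fraction.
#' @export
parse_fraction <- function(x) {
  x <- trimws(x)
  if (grepl("%$", x)) as.numeric(sub("%$", "", x)) / 100 else as.numeric(x)
}

.cli_policy <- function(x) {
  distance_policy(switch(x,
    strict = "pairwise_deletion_strict",
    gaps_only = "pairwise_deletion_gaps_only",
    stop("unknown policy '", x, "' (use 'strict' or 'gaps_only')")))
}

# flags -> named list; bare --help allowed
.cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'")
    key <- substring(a, 3L)
    if (key == "help") { out$help <- TRUE; i <- i + 1L; next }
    if (i == length(args)) stop("flag --", key, " needs a value")
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands `distances`, `characterise`, `delimit`, `diagnose`,
#' `simulate` and `run` map onto the package functions; see the usage
#' text (`bargap_cli("--help")`). Results go to files, log messages to
#' standard error.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit status (0 on success), invisibly.
#' @export
bargap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) == 0L || args[1L] %in% c("--help", "help")) {
      cat(.cli_usage, "\n")
      return(0L)
    }
    cmd <- args[1L]
    fl <- .cli_flags(args[-1L])
    if (isTRUE(fl$help)) { cat(.cli_usage, "\n"); return(0L) }
    need <- function(key) {
      if (is.null(fl[[key]])) stop("command '", cmd, "' needs --", key)
      fl[[key]]
    }
    policy <- .cli_policy(if (is.null(fl$policy)) "strict" else fl$policy)
    switch(cmd,
      distances = {
        aln <- read_alignment(need("alignment"), fl$labels)
        write_distance_csv(distance_matrix(aln, policy), need("out"))
      },
      characterise = {
        aln <- read_alignment(need("alignment"), need("labels"))
        out <- need("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        majority <- if (is.null(fl$majority)) 0.5 else parse_fraction(fl$majority)
        profiles <- species_profiles(aln, policy = policy, majority = majority)
        profiles_table(profiles, file.path(out, "species_profiles.tsv"))
        characterisation_report(profiles, file.path(out, "characterisation.txt"))
      },
      delimit = {
        aln <- read_alignment(need("alignment"), fl$labels)
        t <- if (is.null(fl$threshold)) 0.03 else parse_fraction(fl$threshold)
        part <- single_linkage_clusters(distance_matrix(aln, policy), t)
        write_partition_tsv(part, need("out"))
      },
      diagnose = {
        aln <- read_alignment(need("alignment"))
        len <- if (is.null(fl$length)) 6L else as.integer(fl$length)
        dg <- diagnose_genus(aln, need("reference"), expected_length = len)
        writeLines(c(sprintf("verdict: %s",
                             if (dg$positive) "positive" else "negative"),
                     dg$message), need("out"))
      },
      simulate = {
        seed <- as.integer(need("seed"))
        deletion <- NULL
        if (!is.null(fl$`deletion-clade`))
          deletion <- list(clade = strsplit(fl$`deletion-clade`, ",")[[1L]])
        cfg <- sim_config(
          n_species = if (is.null(fl$species)) 7L else as.integer(fl$species),
          n_per_species = if (is.null(fl$`per-species`)) 5L
                          else as.integer(fl$`per-species`),
          seq_length = if (is.null(fl$length)) 658L else as.integer(fl$length),
          intra_divergence = if (is.null(fl$intra)) 0.01
                             else parse_fraction(fl$intra),
          inter_divergence = if (is.null(fl$inter)) 0.08
                             else parse_fraction(fl$inter),
          deletion = deletion)
        write_simulation(simulate_alignment(cfg, seed), need("out"))
      },
      run = {
        run_pipeline(need("alignment"), need("labels"), need("out"),
                     threshold = if (is.null(fl$threshold)) 0.03
                                 else parse_fraction(fl$threshold),
                     policy = policy,
                     majority = if (is.null(fl$majority)) 0.5
                                else parse_fraction(fl$majority),
                     reference_id = fl$reference,
                     seed = if (is.null(fl$seed)) NULL else as.integer(fl$seed))
      },
      stop("unknown command '", cmd, "'")
    )
    0L
  }
  status <- tryCatch(run(), error = function(e) {
    message("bargap: ", conditionMessage(e))
    message(.cli_usage)
    if (grepl("unknown command|unexpected argument|unknown policy", conditionMessage(e)))
      2L else 1L
  })
  invisible(status)
}
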