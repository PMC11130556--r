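test_that("the Jukes-Cantor closed form behaves at its anchors", {
  expect_equal(jc_expected_distance(0), 0)
  # 3/4 (1 - exp(-4/30)) evaluated independently
  expect_equal(jc_expected_distance(0.10), 0.09362, tolerance = 1e-5)
  expect_equal(jc_expected_distance(1e6), 0.75)
  expect_error(jc_expected_distance(-1), "non-negative")
  # inverse round-trips
  for (p in c(0.01, 0.08, 0.3))
    expect_equal(jc_expected_distance(jc_branch_length(p)), p)
})

test_that("configurations with no barcode gap are refused", {
  expect_error(sim_config(intra_divergence = 0.05, inter_divergence = 0.05),
               "barcode gap")
  expect_error(sim_config(n_species = 1), "2 species")
  expect_error(sim_config(deletion = list(clade = "sp01", position = 655,
                                          length = 6)),
               "past the end")
  expect_error(sim_config(deletion = list(length = 6)), "clade")
})

test_that("species trees are near-star ultrametric with the configured size", {
  cfg <- sim_config()
  tr <- simulate_species_tree(cfg, seed = 4)
  expect_equal(ape::Ntip(tr), 7L)
  expect_equal(tr$Nnode, 6L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  depths <- ape::node.depth.edgelength(tr)[seq_len(7)]
  expect_equal(depths, rep(jc_branch_length(0.08) / 2, 7), tolerance = 1e-6)
  # identical seed, identical tree
  expect_equal(ape::write.tree(simulate_species_tree(cfg, seed = 4)),
               ape::write.tree(tr))
  # two species: a single split
  tr2 <- simulate_species_tree(sim_config(n_species = 2), seed = 1)
  expect_equal(ape::Ntip(tr2), 2L)
})

test_that("identical config and seed reproduce the dataset byte for byte", {
  cfg <- sim_config(n_species = 3, n_per_species = 2, seq_length = 300)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_alignment(cfg, seed = 8), d1)
  write_simulation(simulate_alignment(cfg, seed = 8), d2)
  for (f in c("alignment.fasta", "labels.tsv", "truth.tsv", "tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the sequences
  d3 <- withr::local_tempdir()
  write_simulation(simulate_alignment(cfg, seed = 9), d3)
  expect_false(identical(readLines(file.path(d1, "alignment.fasta")),
                         readLines(file.path(d3, "alignment.fasta"))))
})

test_that("simulated divergences calibrate to the JC expectation", {
  cfg <- sim_config(ambiguity_rate = 0)
  sim <- simulate_alignment(cfg, seed = 5)
  m <- distance_matrix(sim$alignment)
  labels <- sim$truth$labels[m$ids]
  same <- outer(labels, labels, "==")
  ut <- upper.tri(m$d)
  intra <- m$d[ut & same]
  inter <- m$d[ut & !same]
  se_intra <- sqrt(0.01 * 0.99 / cfg$seq_length)
  se_inter <- sqrt(0.08 * 0.92 / cfg$seq_length)
  expect_lt(abs(mean(intra) - 0.01), 3 * se_intra)
  expect_lt(abs(mean(inter) - 0.08), 3 * se_inter)
  # the barcode gap survives sampling noise: every species separable
  for (sp in unique(labels)) {
    expect_lt(max_intraspecific(m, labels, sp),
              min_interspecific(m, labels, sp)$distance)
  }
})

test_that("ambiguity codes appear at roughly the configured rate", {
  cfg <- sim_config(n_species = 4, n_per_species = 5, seq_length = 600,
                    ambiguity_rate = 0.01)
  sim <- simulate_alignment(cfg, seed = 6)
  n_amb <- sum(vapply(sim$alignment$seqs, function(s)
    nchar(gsub("[ACGT-]", "", s)), numeric(1)))
  total <- 20 * 600
  expect_gt(n_amb, 0)
  # binomial 3-sigma band around rate * sites
  expect_lt(abs(n_amb - total * 0.01), 3 * sqrt(total * 0.01 * 0.99))
})

test_that("configured deletions shorten carriers and pad the alignment", {
  cfg <- sim_config(deletion = list(clade = sprintf("sp%02d", 1:7),
                                    length = 6, position = 476))
  sim <- simulate_alignment(cfg, seed = 3)
  expect_equal(unname(ungapped_lengths(sim$alignment)),
               rep(652L, length(sim$alignment$ids)))
  expect_equal(sim$alignment$length, 658L)
  expect_equal(sim$truth$indels[[1]]$position, 476L)
  # singleton species downstream: intraspecific distance not applicable
  s1 <- simulate_alignment(sim_config(n_species = 3, n_per_species = 1,
                                      seq_length = 200), seed = 2)
  m1 <- distance_matrix(s1$alignment)
  expect_true(all(is.na(vapply(unique(s1$truth$labels), function(sp)
    max_intraspecific(m1, s1$truth$labels, sp), numeric(1)))))
})

test_that("the pipeline recovers simulated truth end to end", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(deletion = list(clade = c("sp01", "sp02", "sp03"),
                                    length = 6, position = 476))
  sim <- simulate_alignment(cfg, seed = 12)
  aln <- sim$alignment
  # species recovery at the 3% threshold
  p <- single_linkage_clusters(distance_matrix(aln), 0.03)
  expect_equal(mclust::adjustedRandIndex(p$assignment,
                                         sim$truth$labels[names(p$assignment)]), 1)
  # injected deletion recovered at exact position and length from the
  # carrier clade against a non-carrier reference
  carriers <- names(sim$truth$labels)[sim$truth$labels %in% c("sp01", "sp02", "sp03")]
  ref <- setdiff(aln$ids, carriers)[1]
  sub <- barcode_alignment(aln$seqs[c(carriers, ref)], ids = c(carriers, ref),
                           normalize = FALSE)
  reps <- detect_shared_deletions(sub, ref)
  expect_length(reps, 1L)
  expect_equal(reps[[1]]$column_start, 476L)
  expect_equal(reps[[1]]$length_bp, 6L)
  expect_setequal(reps[[1]]$shared_by, carriers)
})

test_that("the published fixture loader reconstructs the full-length reference", {
  fx <- fixture_paper_dataset()
  expect_equal(length(fx$alignment$ids), 8L)
  expect_equal(fx$alignment$length, 658L)
  ung <- ungapped_lengths(fx$alignment)
  expect_equal(unname(ung[setdiff(names(ung), "REF_synthetic_fulllength")]),
               rep(652L, 7))
  expect_equal(unname(ung["REF_synthetic_fulllength"]), 658L)
  # the printed P. salicis consensus carries exactly one Y ambiguity
  sal <- fx$alignment$seqs[["P_salicis"]]
  expect_equal(nchar(gsub("[^Y]", "", sal)), 1L)
})
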