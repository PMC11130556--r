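# forge a barcode_dist directly from a symmetric fraction matrix
dist_obj <- function(d, ids = rownames(d)) {
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, comparable = d * 0 + 100,
                 policy = distance_policy()),
            class = "barcode_dist")
}

chain3 <- dist_obj(matrix(c(0, 0.02, 0.04,
                            0.02, 0, 0.02,
                            0.04, 0.02, 0), 3,
                          dimnames = list(letters[1:3], letters[1:3])))

test_that("threshold clustering is transitive single-linkage with strict d < t", {
  p <- single_linkage_clusters(chain3, 0.03)
  expect_equal(p$k, 1L)  # a-b and b-c below t chain a-c together
  expect_equal(unname(p$assignment), c(1L, 1L, 1L))
  # strict comparison: d exactly at t does not merge
  p2 <- single_linkage_clusters(chain3, 0.02)
  expect_equal(p2$k, 3L)
  # everything above t -> singletons; everything below -> one cluster
  expect_equal(single_linkage_clusters(chain3, 0.001)$k, 3L)
  expect_equal(single_linkage_clusters(chain3, 0.99)$k, 1L)
  bad <- chain3; bad$d[1, 2] <- bad$d[2, 1] <- NA
  expect_error(single_linkage_clusters(bad, 0.03), "undefined")
})

test_that("clustering agrees with the exhaustive closure and hclust oracles", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    aln <- random_aln(n, 60, gap_rate = 0, amb_rate = 0)
    m <- distance_matrix(aln)
    for (t in runif(3, 0.05, 0.6)) {
      mine <- single_linkage_clusters(m, t)$assignment
      expect_true(same_partition(mine, naive_components(m$d, t)))
      hc <- stats::hclust(stats::as.dist(m$d), "single")
      expect_true(same_partition(mine, stats::cutree(hc, h = t - 1e-9)))
    }
  }
})

test_that("cluster count is monotone and partitions refine as t grows", {
  set.seed(31)
  aln <- random_aln(10, 80, gap_rate = 0, amb_rate = 0)
  m <- distance_matrix(aln)
  ts <- sort(runif(8, 0, 0.8))
  parts <- lapply(ts, function(t) single_linkage_clusters(m, t))
  ks <- vapply(parts, `[[`, integer(1), "k")
  expect_true(all(diff(ks) <= 0))
  for (i in seq_len(length(ts) - 1)) {
    fine <- parts[[i]]$assignment; coarse <- parts[[i + 1]]$assignment
    # each fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
})

test_that("merge heights bound the constant-clustering intervals", {
  two <- dist_obj(matrix(c(0, 0.05, 0.05, 0), 2))
  expect_equal(merge_heights(two), 0.05)
  # chained pair: both merges happen at 0.02 under single linkage
  expect_equal(merge_heights(chain3), 0.02)
  tri <- dist_obj(matrix(c(0, 0.01, 0.04,
                           0.01, 0, 0.05,
                           0.04, 0.05, 0), 3))
  expect_equal(merge_heights(tri), c(0.01, 0.04))
  set.seed(41)
  aln <- random_aln(9, 70, gap_rate = 0, amb_rate = 0)
  m <- distance_matrix(aln)
  hh <- merge_heights(m)
  expect_true(all(diff(hh) > 0))
  expect_lte(length(hh), 8L)
  # clustering constant within an interval
  for (i in seq_along(hh)) {
    lo <- single_linkage_clusters(m, hh[i] + 1e-9)$assignment
    hi_t <- if (i < length(hh)) hh[i + 1] else hh[i] + 0.1
    hi <- single_linkage_clusters(m, hi_t)$assignment
    expect_true(same_partition(lo, hi))
  }
})

test_that("ranked partitions put the widest relative gap first", {
  # two tight clusters separated by a wide gap -> rank 1 has k = 2
  d <- matrix(0.10, 6, 6)
  d[1:3, 1:3] <- 0.01; d[4:6, 4:6] <- 0.01
  diag(d) <- 0
  rp <- ranked_partitions(dist_obj(d))
  expect_equal(rp[[1]]$rank, 1L)
  expect_equal(rp[[1]]$partition$k, 2L)
  expect_equal(rp[[1]]$gap_score, (0.10 - 0.01) / 0.10)
  scores <- vapply(rp, `[[`, numeric(1), "gap_score")
  expect_true(all(diff(scores) <= 0))

  # one outlier record
  d2 <- matrix(0, 4, 4); d2[4, 1:3] <- d2[1:3, 4] <- 0.5
  rp2 <- ranked_partitions(dist_obj(d2))
  expect_equal(rp2[[1]]$partition$k, 2L)

  # degenerate matrix: all distances equal -> single candidate, gap 0
  d3 <- matrix(0.1, 3, 3); diag(d3) <- 0
  rp3 <- ranked_partitions(dist_obj(d3))
  expect_length(rp3, 1L)
  expect_equal(rp3[[1]]$gap_score, 0)
})

test_that("rank-1 partition recovers the simulated species", {
  sim <- simulate_alignment(sim_config(), seed = 1)
  m <- distance_matrix(sim$alignment)
  rp <- ranked_partitions(m)
  expect_true(same_partition(rp[[1]]$partition$assignment,
                             sim$truth$labels[names(rp[[1]]$partition$assignment)]))
})

test_that("congruence statuses implement the four-way classification", {
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  part <- function(x) structure(list(assignment = x, threshold = NA, k = length(unique(x))),
                                class = "partition")
  # identical to labels -> all congruent
  p <- part(c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L, c1 = 3L))
  expect_true(all(compare_partition(p, labels)$table$status == "congruent"))
  # B and C merged -> both lumped, A congruent
  p2 <- part(c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L, c1 = 2L))
  cmp2 <- compare_partition(p2, labels)
  st2 <- setNames(cmp2$table$status, cmp2$table$species)
  expect_equal(unname(st2[c("A", "B", "C")]), c("congruent", "lumped", "lumped"))
  # A split into two pure clusters
  p3 <- part(c(a1 = 1L, a2 = 4L, b1 = 2L, b2 = 2L, c1 = 3L))
  st3 <- compare_partition(p3, labels)$table$status
  expect_equal(st3[1], "split")
  # A split with one half shared with B -> mixed
  p4 <- part(c(a1 = 1L, a2 = 2L, b1 = 2L, b2 = 2L, c1 = 3L))
  cmp4 <- compare_partition(p4, labels)
  st4 <- setNames(cmp4$table$status, cmp4$table$species)
  expect_equal(unname(st4["A"]), "mixed")
  expect_equal(sum(cmp4$counts), 3)
  expect_error(compare_partition(p, labels[-1]), "unlabelled")
})

test_that("partition TSVs round-trip through read/write", {
  sim <- simulate_alignment(sim_config(n_species = 3, n_per_species = 2,
                                       seq_length = 200), seed = 2)
  p <- single_linkage_clusters(distance_matrix(sim$alignment), 0.03)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, f)
  back <- read_partition_tsv(f)
  expect_equal(back$assignment, p$assignment)
  expect_equal(back$k, p$k)
})

test_that("clustering at 3% recovers simulated species exactly (ARI 1)", {
  skip_if_not_installed("mclust")
  sim <- simulate_alignment(sim_config(), seed = 11)
  p <- single_linkage_clusters(distance_matrix(sim$alignment), 0.03)
  ari <- mclust::adjustedRandIndex(p$assignment,
                                   sim$truth$labels[names(p$assignment)])
  expect_equal(ari, 1)
})
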