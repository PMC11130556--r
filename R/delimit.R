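# Distance-threshold species delimitation (objective clustering) and
# ranked barcode-gap partitions, plus congruence classification of a
# partition against reference species labels.

#' Objective clustering at a fixed distance threshold
#'
#' Clusters are the connected components of the graph with an edge
#' wherever `d < t` (strict comparison), i.e. single-linkage transitive
#' grouping. Cluster ids are assigned 1, 2, ... in order of each
#' cluster's first-seen record.
#'
#' @param m a `barcode_dist` with no undefined distances.
#' @param t distance threshold as a fraction (the conventional barcode
#'   threshold is 0.03).
#' @return object of class `"partition"`: list with `assignment` (named
#'   integer vector record id -> cluster id), `threshold`, `k`.
#' @export
single_linkage_clusters <- function(m, t = 0.03) {
  stopifnot(inherits(m, "barcode_dist"))
  if (t < 0 || t > 1) stop("`t` must be a fraction in [0, 1]")
  if (anyNA(m$d)) stop("distance matrix contains undefined distances")
  n <- length(m$ids)
  # union-find over records
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (m$d[i, j] < t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  cluster <- match(roots, unique(roots))  # first-seen order
  names(cluster) <- m$ids
  structure(list(assignment = cluster, threshold = t,
                 k = length(unique(cluster))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d records in %d clusters", length(x$assignment), x$k))
  if (!is.null(x$threshold) && !is.na(x$threshold))
    cat(sprintf(" (threshold %.4g)", x$threshold))
  cat("\n")
  invisible(x)
}

#' Single-linkage merge heights of a distance matrix
#'
#' The strictly increasing heights at which single-linkage clusters
#' merge; the clustering of [single_linkage_clusters()] is constant for
#' thresholds within each interval `(h_i, h_{i+1}]`.
#'
#' @param m a `barcode_dist`.
#' @return strictly increasing numeric vector (at most n-1 heights).
#' @export
merge_heights <- function(m) {
  stopifnot(inherits(m, "barcode_dist"))
  if (length(m$ids) < 2L) stop("need at least two records")
  if (anyNA(m$d)) stop("distance matrix contains undefined distances")
  h <- stats::hclust(stats::as.dist(m$d), method = "single")$height
  h <- sort(h)
  # collapse numerically identical heights
  h[c(TRUE, diff(h) > 1e-12)]
}

#' Ranked partitions by relative barcode-gap width
#'
#' A transparent, gap-ranked analogue of automatic hierarchical
#' partitioning: one candidate partition per single-linkage merge-height
#' interval, scored by the relative width of the distance gap above it,
#' `gap_score = (h_next - h) / h_next` (for the shallowest-k candidate the
#' maximum observed distance plays the role of `h_next`). This is *not*
#' the probability-based ASAP score; it ranks partitions purely by how
#' wide a barcode gap separates their clusters.
#'
#' @param m a `barcode_dist` with at least 3 records.
#' @param max_results maximum number of ranked partitions to return.
#' @return list of objects of class `"ranked_partition"`, each a list
#'   with `partition`, `gap_score`, `rank` and `interval` (the threshold
#'   interval realising the partition); sorted by decreasing `gap_score`,
#'   ties broken by smaller cluster count.
#' @export
ranked_partitions <- function(m, max_results = 10L) {
  stopifnot(inherits(m, "barcode_dist"))
  if (length(m$ids) < 3L) stop("ranked partitions require at least 3 records")
  h <- merge_heights(m)
  dmax <- max(m$d, na.rm = TRUE)
  upper <- c(h[-1L], dmax)
  cands <- lapply(seq_along(h), function(i) {
    # clusters for t just above h[i]: edges d <= h[i]
    p <- single_linkage_clusters(m, t = h[i] + 1e-12)
    p$threshold <- NA_real_
    gap <- if (upper[i] > h[i]) (upper[i] - h[i]) / upper[i] else 0
    list(partition = p, gap_score = gap, interval = c(h[i], upper[i]))
  })
  ord <- order(-vapply(cands, `[[`, numeric(1L), "gap_score"),
               vapply(cands, function(x) x$partition$k, integer(1L)))
  cands <- cands[ord]
  cands <- utils::head(cands, max_results)
  for (r in seq_along(cands)) {
    cands[[r]]$rank <- r
    class(cands[[r]]) <- "ranked_partition"
  }
  cands
}

#' @export
print.ranked_partition <- function(x, ...) {
  cat(sprintf("Rank %d: k = %d, gap score %.3f, threshold interval (%.4g, %.4g]\n",
              x$rank, x$partition$k, x$gap_score, x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Congruence of a partition with reference species labels
#'
#' Classifies every reference species as:
#' \describe{
#'   \item{congruent}{its records form exactly one cluster containing no
#'     other species' records;}
#'   \item{split}{its records occupy two or more clusters, none shared
#'     with another species;}
#'   \item{lumped}{all its records share one cluster that also holds
#'     other species' records;}
#'   \item{mixed}{anything else.}
#' }
#'
#' @param p a `"partition"`.
#' @param labels named character vector covering every record in `p`.
#' @return object of class `"partition_comparison"`: list with `table`
#'   (data.frame species/status) and `counts` (named integer vector over
#'   the four statuses).
#' @export
compare_partition <- function(p, labels) {
  ids <- names(p$assignment)
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0L)
    stop("unlabelled records: ", paste(missing, collapse = ", "))
  labels <- labels[ids]
  sps <- sort(unique(unname(labels)))
  status <- vapply(sps, function(sp) {
    own <- p$assignment[names(labels)[labels == sp]]
    clusters <- unique(own)
    shared <- vapply(clusters, function(cl) {
      any(labels[names(p$assignment)[p$assignment == cl]] != sp)
    }, logical(1L))
    if (length(clusters) == 1L && !shared) "congruent"
    else if (length(clusters) >= 2L && !any(shared)) "split"
    else if (length(clusters) == 1L && shared) "lumped"
    else "mixed"
  }, character(1L))
  counts <- table(factor(status, levels = c("congruent", "split", "lumped", "mixed")))
  structure(list(table = data.frame(species = sps, status = unname(status),
                                    row.names = NULL),
                 counts = c(counts)),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("Partition congruence by species:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("congruent %d | split %d | lumped %d | mixed %d\n",
              x$counts["congruent"], x$counts["split"],
              x$counts["lumped"], x$counts["mixed"]))
  invisible(x)
}

#' Write a partition TSV (`record_id<TAB>cluster_id`)
#' @param p a `"partition"`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  utils::write.table(
    data.frame(record_id = names(p$assignment),
               cluster_id = unname(p$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read an externally produced partition TSV
#'
#' Accepts `record_id<TAB>cluster_id` with an optional header and `#`
#' comments, so partitions from external delimitation tools can be fed
#' to [compare_partition()].
#'
#' @param path TSV path.
#' @return a `"partition"` (threshold `NA`).
#' @export
read_partition_tsv <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("partition file must have two tab-separated columns")
  if (tolower(tab[1L, 1L]) == "record_id") tab <- tab[-1L, , drop = FALSE]
  cluster <- match(tab[[2L]], unique(tab[[2L]]))
  names(cluster) <- tab[[1L]]
  if (anyDuplicated(names(cluster)))
    stop("duplicate record ids in partition file")
  structure(list(assignment = cluster, threshold = NA_real_,
                 k = length(unique(cluster))),
            class = "partition")
}
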