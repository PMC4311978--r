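#' Canonicalize a partition
#'
#' A partition assigns each of `N` nodes to exactly one cluster. Cluster
#' labels themselves are arbitrary: the same grouping can be written with any
#' set of ids. The canonical form relabels clusters `1..K` in order of first
#' appearance, so that any relabelling of the same grouping maps to one
#' representative. Canonicalization is idempotent.
#'
#' @param z integer (or integer-like) vector of cluster ids, one per node.
#' @return integer vector of the same length with cluster ids `1..K`, where
#'   `K` is the number of distinct clusters.
#' @examples
#' canonicalize_partition(c(5, 5, 2))   # 1 1 2
#' canonicalize_partition(c(2, 1, 1, 3))
#' @export
canonicalize_partition <- function(z) {
  z <- validate_partition(z)
  match(z, unique(z))
}

validate_partition <- function(z) {
  if (length(z) == 0L) {
    stop("partition is empty", call. = FALSE)
  }
  if (anyNA(z)) {
    stop("partition contains missing cluster ids", call. = FALSE)
  }
  zi <- as.integer(z)
  if (any(zi != z)) {
    stop("cluster ids must be integers", call. = FALSE)
  }
  zi
}

#' Number of clusters and cluster sizes of a partition
#'
#' `n_clusters()` counts the non-empty clusters; `cluster_sizes()` returns the
#' number of nodes per cluster (m_k), ordered by canonical cluster id.
#'
#' @inheritParams canonicalize_partition
#' @return `n_clusters()`: a single integer K. `cluster_sizes()`: an integer
#'   vector of length K summing to the number of nodes.
#' @export
n_clusters <- function(z) {
  length(unique(validate_partition(z)))
}

#' @rdname n_clusters
#' @export
cluster_sizes <- function(z) {
  z <- canonicalize_partition(z)
  tabulate(z, nbins = max(z))
}

#' Write and read partition files
#'
#' Partitions are stored as two-column tab-separated text: region label and
#' cluster id. Cluster ids are written in canonical form (clusters numbered
#' `1..K` by smallest member index), so a write/read round trip reproduces
#' `canonicalize_partition(z)` exactly.
#'
#' @param z cluster assignment vector, one entry per region.
#' @param labels character vector of region names, same length as `z`. For
#'   `write_partition()` defaults to the names of `z` or `r1..rN`.
#' @param path file path.
#' @return `write_partition()` returns `path` invisibly. `read_partition()`
#'   returns a named integer vector of canonical cluster ids with region
#'   labels as names.
#' @export
write_partition <- function(z, path, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(z)
  }
  if (is.null(labels)) {
    labels <- paste0("r", seq_along(z))
  }
  if (length(labels) != length(z)) {
    stop("`labels` and `z` must have the same length", call. = FALSE)
  }
  z <- canonicalize_partition(z)
  utils::write.table(
    data.frame(region = labels, cluster = z, stringsAsFactors = FALSE),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "integer"))
  if (ncol(d) != 2L) {
    stop("partition file must have two columns (region, cluster)",
         call. = FALSE)
  }
  z <- canonicalize_partition(d[[2L]])
  names(z) <- d[[1L]]
  z
}

#' Co-assignment indicator matrix of a partition
#'
#' Entry (i, j) is 1 when nodes i and j are in the same cluster (M = Z'Z for
#' the one-hot assignment matrix Z). The diagonal is 1.
#'
#' @inheritParams canonicalize_partition
#' @return an N x N binary matrix.
#' @keywords internal
coassignment_matrix <- function(z) {
  z <- validate_partition(z)
  1 * outer(z, z, "==")
}
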