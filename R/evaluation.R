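#' Adjusted mutual information between two partitions
#'
#' Chance-corrected similarity of two clusterings of the same N regions:
#' `AMI = (MI - EMI) / (max(H1, H2) - EMI)`, where MI is the mutual
#' information of the two label vectors, H1/H2 their entropies, and EMI the
#' expected mutual information under the hypergeometric model of random
#' labellings with the observed marginals. Unlike plain normalized MI, the
#' correction removes the bias that inflates agreement between partitions
#' with many clusters. AMI is 1 for identical partitions, concentrates near
#' 0 for independent ones, and is invariant to cluster relabelling of either
#' argument.
#'
#' When both partitions are trivial (a single cluster each) the measure is
#' 0/0; by convention the function returns 1 (the partitions are identical)
#' with a message.
#'
#' @param z1,z2 cluster assignment vectors of equal length.
#' @return the AMI score (a scalar, <= 1).
#' @examples
#' ami(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same grouping, relabelled
#' @export
ami <- function(z1, z2) {
  z1 <- canonicalize_partition(z1)
  z2 <- canonicalize_partition(z2)
  if (length(z1) != length(z2)) {
    stop("partitions must cover the same regions", call. = FALSE)
  }
  n <- length(z1)
  tab <- table(z1, z2)
  a <- rowSums(tab)
  b <- colSums(tab)
  h1 <- entropy_counts(a, n)
  h2 <- entropy_counts(b, n)
  if (h1 == 0 && h2 == 0) {
    message("both partitions are a single cluster; AMI = 1 by convention")
    return(1)
  }
  mi <- mutual_information_counts(tab, n)
  emi <- expected_mi(a, b, n)
  (mi - emi) / (max(h1, h2) - emi)
}

entropy_counts <- function(a, n) {
  p <- a[a > 0] / n
  -sum(p * log(p))
}

mutual_information_counts <- function(tab, n) {
  a <- rowSums(tab)
  b <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[idx]
  sum(nij / n * log(nij * n / (a[idx[, 1L]] * b[idx[, 2L]])))
}

# Expected mutual information under the hypergeometric (fixed-marginal)
# permutation model: cell count n_ij ranges over the support of a
# hypergeometric with a_i draws from b_j successes in n.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      p <- stats::dhyper(nij, bj, n - bj, ai)
      emi <- emi + sum(p * nij / n * log(nij * n / (ai * bj)))
    }
  }
  emi
}

#' Within-cluster streamline ratio r_c
#'
#' For each cluster c, the ratio of within-cluster streamlines to the total
#' number of streamlines connected to the cluster (within plus between),
#' each unordered region pair counted once on a symmetric count matrix. A
#' ratio near 1 marks a community (densely intraconnected); near 0, a
#' profile-based cluster or hub whose members connect mostly outward. A
#' singleton cluster has no within-cluster dyads, so its ratio is 0 whenever
#' it carries any streamlines; a cluster with no incident streamlines at all
#' has an undefined ratio, reported as `NA`.
#'
#' Each region is also assigned the score of its cluster, giving a
#' region-level profile of how community-like the parcellation is locally.
#'
#' @param s symmetric streamline count matrix (see [symmetrize()]).
#' @param z cluster assignment vector.
#' @return a list with `cluster` (named vector of r_c per canonical cluster
#'   id) and `region` (per-region scores, named by region labels).
#' @export
community_ratio <- function(s, z) {
  if (!isSymmetric(unname(s))) {
    stop("community_ratio needs a symmetric count matrix; see symmetrize()",
         call. = FALSE)
  }
  z <- canonicalize_partition(z)
  if (length(z) != nrow(s)) {
    stop("partition length must match the matrix", call. = FALSE)
  }
  k <- max(z)
  rc <- numeric(k)
  for (c in seq_len(k)) {
    inc <- z == c
    within <- sum(s[inc, inc, drop = FALSE]) / 2
    between <- sum(s[inc, !inc, drop = FALSE])
    rc[c] <- if (within + between == 0) NA_real_ else within / (within + between)
  }
  names(rc) <- seq_len(k)
  region <- rc[z]
  names(region) <- rownames(s)
  list(cluster = rc, region = region)
}

#' Uncertainty-weighted color interpolation
#'
#' Blends per-region reference colors (typically the cluster colors of the
#' MAP estimate) by posterior co-assignment:
#' `c_i = sum_j m_ij c_j / sum_j m_ij`. A region firmly co-assigned with one
#' cluster keeps that cluster's color; a region split between, say, a red
#' and a yellow cluster comes out orange. The blend depends only on the
#' ratios of a co-assignment row, not its scale.
#'
#' @param coassign co-assignment matrix from [coassignment()].
#' @param map_colors reference colors, one per region: an N x 3 numeric
#'   matrix with components in \[0, 1\], or a character vector of R colors.
#' @return an N x 3 matrix of blended RGB components in \[0, 1\], with the
#'   corresponding hex colors as row names.
#' @export
interpolate_colors <- function(coassign, map_colors) {
  if (is.character(map_colors)) {
    map_colors <- t(grDevices::col2rgb(map_colors) / 255)
  }
  map_colors <- as.matrix(map_colors)
  if (nrow(map_colors) != nrow(coassign) || ncol(map_colors) != 3L) {
    stop("map_colors must give one RGB triple per region", call. = FALSE)
  }
  if (any(map_colors < 0) || any(map_colors > 1)) {
    stop("color components must lie in [0, 1]", call. = FALSE)
  }
  w <- coassign / rowSums(coassign)
  out <- w %*% map_colors
  out <- pmin(pmax(out, 0), 1)
  rownames(out) <- grDevices::rgb(out[, 1L], out[, 2L], out[, 3L])
  colnames(out) <- c("r", "g", "b")
  out
}
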