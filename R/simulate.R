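#' Draw a partition from the Chinese restaurant process
#'
#' Sequential seating: node i joins an occupied cluster k with probability
#' proportional to its current size m_k and opens a new cluster with
#' probability proportional to `xi`.
#'
#' @param n number of nodes, >= 1.
#' @param xi concentration parameter, > 0.
#' @param seed optional RNG seed.
#' @return canonical cluster assignment vector of length `n`.
#' @export
sample_partition <- function(n, xi, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- integer(n)
  z[1L] <- 1L
  k <- 1L
  sizes <- c(1L)
  for (i in seq_len(n)[-1L]) {
    w <- crp_predictive(sizes, xi)
    pick <- sample.int(k + 1L, 1L, prob = w)
    if (pick == k + 1L) {
      k <- k + 1L
      sizes <- c(sizes, 1L)
    } else {
      sizes[pick] <- sizes[pick] + 1L
    }
    z[i] <- pick
  }
  z
}

#' Draw a network from a stochastic block model
#'
#' Each unordered dyad (i, j) is an independent Bernoulli draw with success
#' probability `rho[z_i, z_j]`. The result is symmetric with a zero
#' diagonal.
#'
#' @param z cluster assignment vector.
#' @param rho symmetric K x K matrix of block connection probabilities,
#'   K = number of clusters of `z`.
#' @param seed optional RNG seed.
#' @return an N x N binary adjacency matrix.
#' @export
sample_network <- function(z, rho, seed = NULL) {
  z <- canonicalize_partition(z)
  k <- max(z)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == k)) {
    stop("rho must be K x K with K = number of clusters", call. = FALSE)
  }
  if (any(rho < 0) || any(rho > 1)) {
    stop("rho entries must be probabilities", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(z)
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  p <- rho[cbind(z[ut[, 1L]], z[ut[, 2L]])]
  a[upper.tri(a)] <- stats::rbinom(nrow(ut), 1L, p)
  a + t(a)
}

#' Draw streamline counts from the Dirichlet-multinomial forward model
#'
#' For each seed region i, a streamline probability vector over the N-1
#' target regions is drawn from a Dirichlet whose pseudo-counts are
#' `delta_t` for connected targets and `delta_f` for unconnected ones; the
#' region's `row_totals[i]` streamlines are then distributed multinomially.
#' Marginally the counts follow the Dirichlet compound multinomial scored by
#' [dirmul_row_loglik()].
#'
#' @param a binary adjacency matrix (symmetric, zero diagonal).
#' @param delta_t,delta_f Dirichlet pseudo-counts for true/false
#'   connections, > 0.
#' @param row_totals number of streamlines seeded per region (length N, or
#'   a single value recycled); defaults to 1000 per region.
#' @param seed optional RNG seed.
#' @return an N x N non-negative integer count matrix with zero diagonal
#'   (rows = seed regions; asymmetric in general).
#' @export
sample_streamlines <- function(a, delta_t, delta_f, row_totals = 1000,
                               seed = NULL) {
  if (delta_t <= 0 || delta_f <= 0) {
    stop("delta_t and delta_f must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  row_totals <- rep_len(row_totals, n)
  if (any(row_totals < 0)) stop("row totals must be >= 0", call. = FALSE)
  s <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    if (row_totals[i] == 0) next
    al <- ifelse(a[i, -i] == 1, delta_t, delta_f)
    g <- stats::rgamma(n - 1L, shape = al)
    if (sum(g) == 0) g <- rep(1, n - 1L)  # numerical underflow guard
    s[i, -i] <- stats::rmultinom(1L, row_totals[i], g / sum(g))
  }
  s
}

#' Twelve-node toy networks for the two clustering regimes
#'
#' Builds the canonical toy example: twelve nodes in three equal clusters,
#' with block connection probabilities chosen to produce either
#' community-based structure (dense within clusters, sparse between:
#' diagonal `rho_high`, off-diagonal `rho_low`) or profile-based structure
#' (the reverse: nodes in a cluster share their connections to the other
#' clusters without being mutually connected).
#'
#' @param regime `"community"` or `"profile"`.
#' @param rho_high,rho_low the two block probability levels (defaults 0.9
#'   and 0.05).
#' @param seed optional RNG seed for the network draw.
#' @return a list with `partition` (three clusters of four), `rho` (3 x 3
#'   block probability matrix), and `adjacency` (one network drawn from
#'   them).
#' @export
make_toy <- function(regime = c("community", "profile"),
                     rho_high = 0.9, rho_low = 0.05, seed = NULL) {
  regime <- match.arg(regime)
  z <- rep(1:3, each = 4L)
  rho <- matrix(rho_low, 3L, 3L)
  if (regime == "community") {
    diag(rho) <- rho_high
  } else {
    rho[] <- rho_high
    diag(rho) <- rho_low
  }
  a <- sample_network(z, rho, seed = seed)
  rownames(a) <- colnames(a) <- paste0("r", seq_len(12L))
  list(partition = z, rho = rho, adjacency = a)
}

#' Simulate a full multi-subject parcellation study
#'
#' Plants a partition, draws one block-model connectome per subject from a
#' diagonal-dominant block probability matrix, and generates streamline
#' counts from the forward model — the complete generative path of the
#' model, usable as ground truth for recovery experiments.
#'
#' @param n number of regions.
#' @param k number of planted clusters (regions split as evenly as
#'   possible).
#' @param n_subjects number of subjects sharing the partition.
#' @param rho_within,rho_between block connection probabilities.
#' @param delta_t,delta_f forward-model pseudo-counts.
#' @param row_totals streamlines seeded per region (default 1000).
#' @param seed optional RNG seed.
#' @return a list with `partition`, `rho`, per-subject `adjacency` and
#'   `streamlines` lists, and the generating parameters.
#' @export
simulate_study <- function(n = 24, k = 4, n_subjects = 1,
                           rho_within = 0.9, rho_between = 0.05,
                           delta_t = 1, delta_f = 0.05,
                           row_totals = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- canonicalize_partition(sort(rep_len(seq_len(k), n)))
  rho <- matrix(rho_between, k, k)
  diag(rho) <- rho_within
  adj <- vector("list", n_subjects)
  str <- vector("list", n_subjects)
  labs <- paste0("r", seq_len(n))
  for (m in seq_len(n_subjects)) {
    a <- sample_network(z, rho)
    dimnames(a) <- list(labs, labs)
    adj[[m]] <- a
    str[[m]] <- sample_streamlines(a, delta_t, delta_f, row_totals)
  }
  list(partition = z, rho = rho, adjacency = adj, streamlines = str,
       params = list(n = n, k = k, n_subjects = n_subjects,
                     rho_within = rho_within, rho_between = rho_between,
                     delta_t = delta_t, delta_f = delta_f,
                     row_totals = row_totals))
}
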