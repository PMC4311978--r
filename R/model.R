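#' Hyperparameters of the streamline infinite relational model
#'
#' Collects the five hyperparameters of the generative model:
#'
#' * `xi` — concentration of the Chinese restaurant process prior over
#'   partitions. Larger values favour more clusters.
#' * `alpha`, `beta` — shape parameters of the Beta prior on each
#'   cluster-to-cluster connection probability. `alpha = beta = 1` is the
#'   uninformative default.
#' * `delta_t`, `delta_f` — Dirichlet pseudo-counts of the streamline forward
#'   model for true and false connections respectively. A true structural
#'   connection must attract at least as much streamline mass as a false one,
#'   so `delta_t >= delta_f` is required; setting them equal switches the
#'   streamline likelihood off (it then carries no information about
#'   connectivity), which is occasionally useful for prior checks.
#'
#' @param xi CRP concentration, > 0.
#' @param alpha,beta Beta shape parameters, > 0.
#' @param delta_t,delta_f Dirichlet pseudo-counts, > 0, with
#'   `delta_t >= delta_f`.
#' @return an object of class `"sirm_hyper"` (a named list).
#' @export
sirm_hyper <- function(xi = 1, alpha = 1, beta = 1,
                       delta_t = 1, delta_f = 0.05) {
  if (xi <= 0 || alpha <= 0 || beta <= 0 || delta_t <= 0 || delta_f <= 0) {
    stop("all hyperparameters must be strictly positive", call. = FALSE)
  }
  if (delta_t < delta_f) {
    stop("delta_t must be >= delta_f: a true connection cannot attract ",
         "less streamline mass than a false one", call. = FALSE)
  }
  structure(list(xi = xi, alpha = alpha, beta = beta,
                 delta_t = delta_t, delta_f = delta_f),
            class = "sirm_hyper")
}

#' @export
print.sirm_hyper <- function(x, ...) {
  cat("sIRM hyperparameters:\n")
  cat(sprintf("  xi = %g (CRP concentration)\n", x$xi))
  cat(sprintf("  alpha = %g, beta = %g (Beta prior on block probabilities)\n",
              x$alpha, x$beta))
  cat(sprintf("  delta_t = %g, delta_f = %g (streamline pseudo-counts)\n",
              x$delta_t, x$delta_f))
  invisible(x)
}

#' Chinese restaurant process log-probability of a partition
#'
#' The exchangeable partition probability of the CRP with concentration `xi`:
#' `P(z) = xi^K * prod_k (m_k - 1)! / prod_{i=0}^{N-1} (xi + i)`, where K is
#' the number of clusters and m_k the cluster sizes. Invariant to node order
#' and to cluster relabelling.
#'
#' @param z cluster assignment vector.
#' @param xi concentration parameter, > 0.
#' @return the log-probability (a scalar).
#' @examples
#' crp_log_prob(c(1, 1), xi = 1)  # log(1/2)
#' @export
crp_log_prob <- function(z, xi) {
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  m <- cluster_sizes(z)
  n <- length(z)
  length(m) * log(xi) + sum(lgamma(m)) - (lgamma(xi + n) - lgamma(xi))
}

#' CRP predictive weights for reassigning one node
#'
#' Given the sizes of the currently occupied clusters with the node in
#' question removed, the CRP seating rule assigns the node to an existing
#' cluster k with unnormalized weight m_k and to a new cluster with weight
#' `xi` (the shared denominator cancels in Gibbs ratios).
#'
#' @param sizes integer vector of occupied-cluster sizes, node removed; may
#'   be empty.
#' @param xi concentration parameter, > 0.
#' @return numeric vector of length `length(sizes) + 1`; the last entry is
#'   the new-cluster weight.
#' @export
crp_predictive <- function(sizes, xi) {
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (any(sizes <= 0)) stop("cluster sizes must be positive", call. = FALSE)
  c(as.numeric(sizes), xi)
}

#' Block sufficient statistics of an adjacency matrix under a partition
#'
#' Counts, for every unordered cluster pair (a, b) with a <= b, the number of
#' present edges `n1` and absent dyads `n0` among the unordered node dyads
#' i < j spanning the pair. Diagonal dyads do not exist (no
#' self-connections), and within-cluster blocks count each dyad once. These
#' are the sufficient statistics of the collapsed Beta-Bernoulli block
#' likelihood.
#'
#' @param a symmetric binary adjacency matrix with zero diagonal.
#' @param z cluster assignment vector of length `nrow(a)`.
#' @return a list with symmetric K x K matrices `n1` (edges) and `n0`
#'   (non-edges); `n1 + n0` equals the dyad count of each block.
#' @export
block_stats <- function(a, z) {
  z <- canonicalize_partition(z)
  if (length(z) != nrow(a)) {
    stop("partition length must equal the number of nodes", call. = FALSE)
  }
  k <- max(z)
  zmat <- matrix(0, length(z), k)
  zmat[cbind(seq_along(z), z)] <- 1
  e <- crossprod(zmat, a %*% zmat)  # e[a,b] = directed edge count
  m <- colSums(zmat)
  pairs <- outer(m, m)
  diag(pairs) <- m * (m - 1) / 2
  n1 <- e
  diag(n1) <- diag(e) / 2
  list(n1 = n1, n0 = pairs - n1)
}

#' Collapsed Beta-Bernoulli log-likelihood of an adjacency matrix
#'
#' The marginal likelihood of a binary network under the stochastic block
#' model with the block probabilities integrated out against their
#' Beta(alpha, beta) prior: a sum over unordered block pairs of
#' `log B(alpha + n1, beta + n0) - log B(alpha, beta)`. Subjects are
#' conditionally independent given the shared partition, so a multi-subject
#' likelihood is the sum of per-subject terms, each with its own statistics.
#'
#' @param stats block sufficient statistics from [block_stats()].
#' @param alpha,beta Beta prior shape parameters, > 0.
#' @return the log marginal likelihood (a scalar).
#' @export
irm_marginal_loglik <- function(stats, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha, beta must be > 0", call. = FALSE)
  if (any(stats$n1 < 0) || any(stats$n0 < 0)) {
    stop("negative block counts", call. = FALSE)
  }
  up <- upper.tri(stats$n1, diag = TRUE)
  sum(lbeta(alpha + stats$n1[up], beta + stats$n0[up]) - lbeta(alpha, beta))
}

#' Dirichlet-compound-multinomial log-likelihood of one streamline row
#'
#' Seed region i distributes its T_i streamlines over the N-1 other regions.
#' Given the region's binary connectivity row, each target j carries a
#' Dirichlet pseudo-count `delta_t` when connected and `delta_f` when not;
#' integrating the latent streamline probability vector out yields the
#' Dirichlet compound multinomial pmf
#' `T! / prod_j s_j! * Gamma(A)/Gamma(A + T) * prod_j Gamma(a_j + s_j)/Gamma(a_j)`
#' with `a_j` the pseudo-counts and `A = sum_j a_j`. The multinomial
#' coefficient is included so the pmf normalizes (it cancels in all sampling
#' ratios).
#'
#' @param counts_row integer streamline counts to the N-1 targets (self entry
#'   removed).
#' @param adj_row binary connectivity indicators for the same targets.
#' @param delta_t,delta_f Dirichlet pseudo-counts, > 0.
#' @return the log pmf (a scalar).
#' @export
dirmul_row_loglik <- function(counts_row, adj_row, delta_t, delta_f) {
  if (delta_t <= 0 || delta_f <= 0) {
    stop("delta_t and delta_f must be > 0", call. = FALSE)
  }
  if (length(counts_row) != length(adj_row)) {
    stop("counts_row and adj_row must be aligned", call. = FALSE)
  }
  if (any(counts_row < 0)) stop("negative streamline counts", call. = FALSE)
  al <- ifelse(adj_row == 1, delta_t, delta_f)
  tot <- sum(counts_row)
  lgamma(tot + 1) - sum(lgamma(counts_row + 1)) +
    lgamma(sum(al)) - lgamma(sum(al) + tot) +
    sum(lgamma(al + counts_row) - lgamma(al))
}

dirmul_total_loglik <- function(s, a, delta_t, delta_f) {
  n <- nrow(s)
  tot <- 0
  for (i in seq_len(n)) {
    tot <- tot + dirmul_row_loglik(s[i, -i], a[i, -i], delta_t, delta_f)
  }
  tot
}

#' Joint log-posterior density of the streamline model
#'
#' Up to a constant, the log joint density of a shared partition, per-subject
#' binary connectomes, and per-subject streamline counts: the CRP partition
#' prior, plus for each subject the collapsed block-model likelihood of its
#' adjacency and the Dirichlet-multinomial likelihood of each streamline row
#' given that adjacency. Used to rank posterior samples for the MAP estimate.
#'
#' @param streamlines a streamline count matrix or list of per-subject
#'   matrices; may be `NULL` when scoring binary-only (bIRM) states.
#' @param adjacencies an adjacency matrix or list of per-subject matrices,
#'   aligned with `streamlines`.
#' @param z shared cluster assignment vector.
#' @param hyper a [sirm_hyper()] object.
#' @return the log density (a scalar).
#' @export
joint_log_posterior <- function(streamlines, adjacencies, z, hyper) {
  if (is.matrix(adjacencies)) adjacencies <- list(adjacencies)
  if (is.matrix(streamlines)) streamlines <- list(streamlines)
  n <- length(z)
  if (any(vapply(adjacencies, nrow, 0L) != n)) {
    stop("adjacency dimension does not match partition length", call. = FALSE)
  }
  if (!is.null(streamlines) && length(streamlines) != length(adjacencies)) {
    stop("subject counts differ between streamlines and adjacencies",
         call. = FALSE)
  }
  lp <- crp_log_prob(z, hyper$xi)
  for (m in seq_along(adjacencies)) {
    a <- adjacencies[[m]]
    lp <- lp + irm_marginal_loglik(block_stats(a, z), hyper$alpha, hyper$beta)
    if (!is.null(streamlines)) {
      if (!all(dim(streamlines[[m]]) == n)) {
        stop("streamline dimension does not match partition length",
             call. = FALSE)
      }
      lp <- lp + dirmul_total_loglik(streamlines[[m]], a,
                                     hyper$delta_t, hyper$delta_f)
    }
  }
  lp
}

#' Posterior mean block connection probabilities
#'
#' Given an adjacency matrix and a partition, the Beta posterior mean of each
#' cluster-to-cluster connection probability:
#' `rho_ab = (alpha + n1_ab) / (alpha + beta + n1_ab + n0_ab)`. Blocks with
#' no dyads (a singleton cluster against itself) fall back to the prior mean
#' `alpha / (alpha + beta)`. Large diagonal entries signal community-like
#' clusters; structure carried by the off-diagonal entries signals
#' profile-based clusters.
#'
#' @inheritParams block_stats
#' @param alpha,beta Beta prior shape parameters.
#' @return a symmetric K x K matrix of probabilities in (0, 1).
#' @export
posterior_rho <- function(a, z, alpha = 1, beta = 1) {
  st <- block_stats(a, z)
  (alpha + st$n1) / (alpha + beta + st$n1 + st$n0)
}
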