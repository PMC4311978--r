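# Independent oracles used across tests: brute-force enumeration of set
# partitions, integer compositions, quadrature, and simple reference
# statistics. Deliberately naive implementations, kept separate from the
# package's own computational paths.

# all set partitions of n elements, as canonical assignment vectors
enumerate_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in enumerate_partitions(n - 1L)) {
    for (c in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

# all compositions of total t into k non-negative parts
enumerate_compositions <- function(t, k) {
  if (k == 1L) return(list(t))
  out <- list()
  for (first in 0:t) {
    for (rest in enumerate_compositions(t - first, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Beta-Bernoulli block marginal by 1-D quadrature over rho per block
quadrature_block_loglik <- function(a, z, alpha, beta) {
  z <- sirm::canonicalize_partition(z)
  k <- max(z)
  total <- 0
  for (b1 in seq_len(k)) {
    for (b2 in b1:k) {
      idx1 <- which(z == b1); idx2 <- which(z == b2)
      if (b1 == b2) {
        dy <- t(utils::combn(idx1, 2L))
      } else {
        dy <- as.matrix(expand.grid(idx1, idx2))
      }
      if (nrow(dy) == 0L) next
      edges <- a[cbind(dy[, 1L], dy[, 2L])]
      f <- function(r) {
        vapply(r, function(rr) prod(rr^edges * (1 - rr)^(1 - edges)) *
                 stats::dbeta(rr, alpha, beta), 0)
      }
      total <- total + log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
    }
  }
  total
}

# exact collapsed partition posterior for a fixed set of adjacencies
exact_partition_posterior <- function(adj_list, hp) {
  n <- nrow(adj_list[[1L]])
  parts <- enumerate_partitions(n)
  lp <- vapply(parts, function(z) {
    v <- sirm::crp_log_prob(z, hp$xi)
    for (a in adj_list) {
      v <- v + sirm::irm_marginal_loglik(sirm::block_stats(a, z),
                                         hp$alpha, hp$beta)
    }
    v
  }, 0)
  p <- exp(lp - max(lp))
  list(partitions = parts, prob = p / sum(p),
       key = vapply(parts, paste, "", collapse = "."))
}

# mutual information of two label vectors (plain definition, for the EMI
# permutation oracle)
plain_mi <- function(z1, z2) {
  n <- length(z1)
  tab <- table(z1, z2)
  a <- rowSums(tab); b <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[idx]
  sum(nij / n * log(nij * n / (a[idx[, 1L]] * b[idx[, 2L]])))
}

# expected CRP cluster count: sum_{i=0}^{n-1} xi / (xi + i)
crp_mean_K <- function(n, xi) sum(xi / (xi + 0:(n - 1L)))

tv_distance <- function(p, q) sum(abs(p - q)) / 2

# small labelled matrix helper
lab <- function(m, prefix = "r") {
  rownames(m) <- colnames(m) <- paste0(prefix, seq_len(nrow(m)))
  m
}
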