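#' Sampler settings for [sirm()]
#'
#' @param sweeps total number of Gibbs sweeps. One sweep updates every edge
#'   dyad of every subject (when connectivity is sampled) and then every
#'   node's cluster assignment (when the partition is sampled).
#' @param burn_in number of initial sweeps discarded; must be < `sweeps`.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched. Runs
#'   with the same seed, data and settings are bit-identical.
#' @param fix_partition keep the partition fixed at its initial value and
#'   sample only the connectomes (conditional edge inference).
#' @param verbose print progress (sweep, log-posterior, number of clusters)
#'   to stderr.
#' @param progress_every sweeps between progress lines.
#' @return an object of class `"sirm_control"`.
#' @export
sirm_control <- function(sweeps = 2000, burn_in = 1000, thin = 2,
                         seed = NULL, fix_partition = FALSE,
                         verbose = FALSE, progress_every = 100) {
  if (burn_in < 0 || sweeps <= burn_in) {
    stop("need sweeps > burn_in >= 0", call. = FALSE)
  }
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(sweeps = as.integer(sweeps), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 fix_partition = isTRUE(fix_partition),
                 verbose = isTRUE(verbose),
                 progress_every = as.integer(progress_every)),
            class = "sirm_control")
}

#' Fit the (streamline) infinite relational model by block Gibbs sampling
#'
#' Jointly infers a partition of brain regions shared across subjects and,
#' in the streamline modes, per-subject latent binary connectomes, from
#' probabilistic-tractography streamline count matrices. The partition
#' carries a Chinese-restaurant-process prior (so the number of clusters is
#' inferred, not fixed), each connectome follows a stochastic block model
#' with Beta-Bernoulli blocks collapsed analytically, and streamline counts
#' follow a Dirichlet-compound-multinomial forward model given the
#' connectome.
#'
#' Three modes are available:
#' * `"sirm"` — the full joint model: count matrices in, both the partition
#'   and the per-subject connectomes sampled.
#' * `"birm"` — the block model on fixed binary connectomes: only the
#'   partition is sampled. If count matrices are supplied in this mode, each
#'   subject's connectome is first point-estimated under a flat connectivity
#'   prior (a `"flat"` run, taking the MAP) and then clustered — the
#'   two-stage pipeline that `"sirm"` replaces by joint inference.
#' * `"flat"` — connectivity estimation only, under the uniform prior
#'   P(A) proportional to 1: the connectomes are sampled, no clustering.
#'
#' Within a sweep, all edge dyads are updated subject-major in lexicographic
#' order, then all node assignments in a fresh random permutation; any valid
#' scan order leaves the stationary distribution unchanged. Edge updates use
#' the collapsed block prior odds of the dyad's block (dyad removed) times
#' the Dirichlet-multinomial likelihood ratio of both affected seed rows;
#' node updates use the CRP predictive times the collapsed block-likelihood
#' change of reinserting the node, evaluated for every existing cluster and
#' a fresh one.
#'
#' @param data a count or adjacency matrix, or a list of per-subject matrices
#'   sharing dimensions and region labels, or file path(s) readable by
#'   [read_connectivity()]. Counts for modes `"sirm"`/`"flat"`; binary
#'   adjacencies (or counts, see above) for `"birm"`.
#' @param mode one of `"sirm"`, `"birm"`, `"flat"`.
#' @param hyper model hyperparameters, see [sirm_hyper()].
#' @param control sampler settings, see [sirm_control()].
#' @param partition optional initial cluster assignment (length-N vector);
#'   the default starts from the fully split state (one cluster per node),
#'   from which Gibbs merging converges much faster than splitting from a
#'   coarse start. With `sirm_control(fix_partition = TRUE)` it stays fixed
#'   throughout.
#' @return an object of class `"sirm"`: a posterior sample chain with
#'   components `z` (samples-by-N matrix of canonical cluster assignments),
#'   `K` (clusters per sample), `log_posterior`, retained connectome samples,
#'   the input data, and run metadata. See [map_estimate()],
#'   [coassignment()], [credible_interval_K()], and the `print`, `summary`,
#'   `coef`, `plot`, `simulate` and `logLik` methods.
#' @examples
#' toy <- make_toy("community", seed = 1)
#' s <- sample_streamlines(toy$adjacency, delta_t = 1, delta_f = 0.05,
#'                         row_totals = rep(200, 12), seed = 2)
#' fit <- sirm(s, mode = "sirm",
#'             control = sirm_control(sweeps = 200, burn_in = 100, seed = 3))
#' map_estimate(fit)$partition
#' @export
sirm <- function(data, mode = c("sirm", "birm", "flat"),
                 hyper = sirm_hyper(), control = sirm_control(),
                 partition = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(hyper, "sirm_hyper"), inherits(control, "sirm_control"))
  if (is.character(data)) {
    kind <- if (mode == "birm") "binary" else "counts"
    data <- lapply(data, function(p) tryCatch(
      read_connectivity(p, kind = kind),
      error = function(e) if (mode == "birm")
        read_connectivity(p, kind = "counts") else stop(e)))
  }
  if (is.matrix(data)) data <- list(data)
  if (length(data) == 0L) stop("no input matrices", call. = FALSE)

  kind <- if (mode == "birm") "binary" else "counts"
  is_binary <- vapply(data, function(m) all(m %in% c(0, 1)), TRUE)
  if (mode == "birm" && !all(is_binary)) {
    # two-stage pipeline: flat-prior MAP connectivity, then cluster it
    message("birm mode with count input: estimating per-subject MAP ",
            "connectivity under a flat prior first")
    data <- lapply(data, function(s) {
      f <- sirm(s, mode = "flat", hyper = hyper, control = control)
      map_estimate(f)$adjacency[[1L]]
    })
  }
  data <- lapply(data, validate_connectivity, kind = kind)
  n <- nrow(data[[1L]])
  labels <- rownames(data[[1L]])
  for (m in data) {
    if (nrow(m) != n) stop("subjects disagree on the number of regions",
                           call. = FALSE)
    if (!identical(rownames(m), labels)) {
      stop("subjects disagree on region labels", call. = FALSE)
    }
  }
  if (!is.null(control$seed)) set.seed(control$seed)

  if (is.null(partition)) {
    # one cluster per node: collapsed Gibbs merges clusters far more easily
    # than it splits them, so start from the fully split state
    z0 <- if (mode == "flat") rep(1L, n) else seq_len(n)
  } else {
    if (length(partition) != n) {
      stop("initial partition length does not match the data", call. = FALSE)
    }
    z0 <- canonicalize_partition(partition)
  }

  res <- gibbs_run(data, mode, hyper, control, z0)
  res$data <- data
  res$labels <- labels
  res$mode <- mode
  res$hyper <- hyper
  res$control <- control
  res$n <- n
  res$n_subjects <- length(data)
  res$initial_partition <- z0
  class(res) <- "sirm"
  res
}

# ---- internal sampler ------------------------------------------------------

dyad_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])  # lexicographic (i, j), i < j
  ut[ord, , drop = FALSE]
}

gibbs_run <- function(data, mode, hyper, control, z0) {
  n <- nrow(data[[1L]])
  nm <- length(data)
  sample_edges <- mode %in% c("sirm", "flat")
  sample_nodes <- mode %in% c("sirm", "birm") && !control$fix_partition
  has_counts <- mode %in% c("sirm", "flat")
  use_block_prior <- mode == "sirm"

  dt <- hyper$delta_t; df_ <- hyper$delta_f
  alpha <- hyper$alpha; beta <- hyper$beta; xi <- hyper$xi
  dyads <- dyad_index(n)
  ndy <- nrow(dyads)

  # Precomputed streamline tables (per subject):
  #   LT/LF: per-entry log Gamma(delta + s) - log Gamma(delta)
  #   ga[d+1]: log Gamma of the row pseudo-count total at degree d
  #   gaT[d+1, i]: the same shifted by the row total T_i
  if (has_counts) {
    LT <- lapply(data, function(s) lgamma(dt + s) - lgamma(dt))
    LF <- lapply(data, function(s) lgamma(df_ + s) - lgamma(df_))
    LR <- mapply(function(a, b) a - b, LT, LF, SIMPLIFY = FALSE)
    dgrid <- 0:(n - 1)
    asum <- dt * dgrid + df_ * (n - 1 - dgrid)
    ga <- lgamma(asum)
    rowtot <- lapply(data, rowSums)
    gaT <- lapply(rowtot, function(tt) outer(asum, tt, function(a, t)
      lgamma(a + t)))
    mcoef <- vapply(seq_len(nm), function(m) {
      s <- data[[m]]
      sum(lgamma(rowtot[[m]] + 1)) - sum(lgamma(s + 1)) + n * lgamma(1)
    }, 0)
  }

  # initial adjacency state
  A <- vector("list", nm)
  if (sample_edges) {
    for (m in seq_len(nm)) {
      a <- matrix(0, n, n)
      d <- rep(0L, n)
      for (e in seq_len(ndy)) {
        i <- dyads[e, 1L]; j <- dyads[e, 2L]
        llr <- LR[[m]][i, j] + LR[[m]][j, i] +
          (ga[d[i] + 2L] - gaT[[m]][d[i] + 2L, i]) -
          (ga[d[i] + 1L] - gaT[[m]][d[i] + 1L, i]) +
          (ga[d[j] + 2L] - gaT[[m]][d[j] + 2L, j]) -
          (ga[d[j] + 1L] - gaT[[m]][d[j] + 1L, j])
        if (llr > 0) {
          a[i, j] <- a[j, i] <- 1
          d[i] <- d[i] + 1L; d[j] <- d[j] + 1L
        }
      }
      A[[m]] <- a
    }
  } else {
    A <- data
  }
  deg <- lapply(A, function(a) as.integer(rowSums(a)))

  z <- z0
  K <- max(z)
  sizes <- tabulate(z, K)
  n1b <- lapply(A, function(a) block_stats(a, z)$n1)

  pairs_of <- function(s) {
    p <- outer(s, s)
    diag(p) <- s * (s - 1) / 2
    p
  }

  log_post <- function() {
    lp <- 0
    if (mode != "flat") {
      lp <- crp_log_prob(z, xi)
      pr <- pairs_of(sizes)
      for (m in seq_len(nm)) {
        n1 <- n1b[[m]]
        up <- upper.tri(n1, diag = TRUE)
        lp <- lp + sum(lbeta(alpha + n1[up], beta + pr[up] - n1[up]) -
                         lbeta(alpha, beta))
      }
    }
    if (has_counts) {
      off <- row(A[[1L]]) != col(A[[1L]])
      for (m in seq_len(nm)) {
        am <- A[[m]]
        lp <- lp + sum(LF[[m]][off]) + sum((LT[[m]] - LF[[m]])[am == 1]) +
          sum(ga[deg[[m]] + 1L] -
                gaT[[m]][cbind(deg[[m]] + 1L, seq_len(n))]) + mcoef[m]
      }
    }
    lp
  }

  n_keep <- (control$sweeps - control$burn_in) %/% control$thin
  keep_z <- matrix(NA_integer_, n_keep, n)
  keep_K <- integer(n_keep)
  keep_lp <- numeric(n_keep)
  keep_edges <- if (sample_edges) vector("list", n_keep) else NULL
  kept <- 0L

  for (sweep in seq_len(control$sweeps)) {
    if (sample_edges) {
      for (m in seq_len(nm)) {
        a <- A[[m]]; d <- deg[[m]]; n1 <- n1b[[m]]
        LRm <- LR[[m]]; gaTm <- gaT[[m]]
        u <- stats::runif(ndy)
        for (e in seq_len(ndy)) {
          i <- dyads[e, 1L]; j <- dyads[e, 2L]
          old <- a[i, j]
          d0i <- d[i] - old; d0j <- d[j] - old
          llr <- LRm[i, j] + LRm[j, i] +
            (ga[d0i + 2L] - gaTm[d0i + 2L, i]) -
            (ga[d0i + 1L] - gaTm[d0i + 1L, i]) +
            (ga[d0j + 2L] - gaTm[d0j + 2L, j]) -
            (ga[d0j + 1L] - gaTm[d0j + 1L, j])
          if (use_block_prior) {
            zi <- z[i]; zj <- z[j]
            np <- if (zi == zj) sizes[zi] * (sizes[zi] - 1) / 2
                  else sizes[zi] * sizes[zj]
            n1m <- n1[zi, zj] - old
            llr <- llr + log(alpha + n1m) - log(beta + np - 1 - n1m)
          }
          new <- as.numeric(u[e] < 1 / (1 + exp(-llr)))
          if (new != old) {
            a[i, j] <- a[j, i] <- new
            dd <- as.integer(2 * new - 1)
            d[i] <- d[i] + dd; d[j] <- d[j] + dd
            n1[z[i], z[j]] <- n1[z[i], z[j]] + dd
            if (z[i] != z[j]) n1[z[j], z[i]] <- n1[z[j], z[i]] + dd
          }
        }
        A[[m]] <- a; deg[[m]] <- d; n1b[[m]] <- n1
      }
    }

    if (sample_nodes) {
      for (i in sample.int(n)) {
        ci <- z[i]
        sizes[ci] <- sizes[ci] - 1L
        removed <- sizes[ci] == 0L
        # per-subject edge counts from node i to each remaining cluster,
        # and block stats with node i removed
        r <- vector("list", nm)
        for (m in seq_len(nm)) {
          nb <- z[-i][A[[m]][i, -i] == 1]
          r[[m]] <- tabulate(nb, nbins = K)
          n1 <- n1b[[m]]
          rm_ <- r[[m]]
          n1[ci, ] <- n1[ci, ] - rm_
          n1[, ci] <- n1[, ci] - rm_
          n1[ci, ci] <- n1b[[m]][ci, ci] - rm_[ci]
          n1b[[m]] <- n1
        }
        if (removed) {
          z[z > ci] <- z[z > ci] - 1L
          z[i] <- 0L
          sizes <- sizes[-ci]
          K <- K - 1L
          for (m in seq_len(nm)) {
            n1b[[m]] <- n1b[[m]][-ci, -ci, drop = FALSE]
            r[[m]] <- r[[m]][-ci]
          }
        }
        sm <- sizes
        logw <- log(crp_predictive(sm, xi))
        if (K > 0L) {
          pr <- pairs_of(sm)
          Pm <- matrix(sm, K, K, byrow = TRUE)
          for (m in seq_len(nm)) {
            n1 <- n1b[[m]]
            n0 <- pr - n1
            Rm <- matrix(r[[m]], K, K, byrow = TRUE)
            delta <- lbeta(alpha + n1 + Rm, beta + n0 + Pm - Rm) -
              lbeta(alpha + n1, beta + n0)
            logw[seq_len(K)] <- logw[seq_len(K)] + rowSums(delta)
            logw[K + 1L] <- logw[K + 1L] +
              sum(lbeta(alpha + r[[m]], beta + sm - r[[m]]) -
                    lbeta(alpha, beta))
          }
        }
        w <- exp(logw - max(logw))
        knew <- sample.int(K + 1L, 1L, prob = w)
        if (knew == K + 1L) {
          K <- K + 1L
          sizes <- c(sizes, 1L)
          for (m in seq_len(nm)) {
            n1 <- rbind(cbind(n1b[[m]], r[[m]]), c(r[[m]], 0))
            n1b[[m]] <- n1
            r[[m]] <- c(r[[m]], 0L)
          }
        } else {
          sizes[knew] <- sizes[knew] + 1L
          for (m in seq_len(nm)) {
            n1 <- n1b[[m]]
            rm_ <- r[[m]]
            n1[knew, ] <- n1[knew, ] + rm_
            n1[, knew] <- n1[, knew] + rm_
            n1[knew, knew] <- n1b[[m]][knew, knew] + rm_[knew]
            n1b[[m]] <- n1
          }
        }
        z[i] <- knew
      }
    }

    if (sweep > control$burn_in &&
        (sweep - control$burn_in) %% control$thin == 0L) {
      kept <- kept + 1L
      keep_z[kept, ] <- canonicalize_partition(z)
      keep_K[kept] <- K
      keep_lp[kept] <- log_post()
      if (sample_edges) {
        keep_edges[[kept]] <- lapply(A, function(a)
          which(a[upper.tri(a)] == 1))
      }
    }
    if (control$verbose && sweep %% control$progress_every == 0L) {
      message(sprintf("sweep %d/%d  K = %d  log-posterior = %.2f",
                      sweep, control$sweeps, K, log_post()))
    }
  }

  list(z = keep_z[seq_len(kept), , drop = FALSE],
       K = keep_K[seq_len(kept)],
       log_posterior = keep_lp[seq_len(kept)],
       edges = if (sample_edges) keep_edges[seq_len(kept)] else NULL,
       fixed_adjacency = if (!sample_edges) A else NULL)
}

# reconstruct the adjacency matrices of retained sample s
sample_adjacency <- function(fit, s) {
  n <- fit$n
  if (is.null(fit$edges)) {
    return(fit$fixed_adjacency)
  }
  lapply(fit$edges[[s]], function(idx) {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a))
    a[ut[idx]] <- 1
    a + t(a)
  })
}
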