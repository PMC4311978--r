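#' Maximum a posteriori estimate from a fitted chain
#'
#' Returns the retained sample with the highest joint log-posterior (ties
#' broken by the earliest sample): the MAP partition and, for modes that
#' sample connectivity, the per-subject MAP connectomes.
#'
#' @param fit a fitted [sirm()] object.
#' @return a list with `partition` (named canonical assignment vector),
#'   `adjacency` (list of per-subject binary matrices), `log_posterior`,
#'   and `index` of the MAP sample in the chain.
#' @export
map_estimate <- function(fit) {
  stopifnot(inherits(fit, "sirm"))
  if (length(fit$log_posterior) == 0L) stop("empty chain", call. = FALSE)
  s <- which.max(fit$log_posterior)
  z <- fit$z[s, ]
  names(z) <- fit$labels
  adj <- sample_adjacency(fit, s)
  adj <- lapply(adj, function(a) {
    dimnames(a) <- list(fit$labels, fit$labels)
    a
  })
  list(partition = z, adjacency = adj,
       log_posterior = fit$log_posterior[s], index = s)
}

#' Posterior co-assignment probabilities
#'
#' The expectation over retained samples of the cluster co-assignment
#' indicator M = Z'Z: entry (i, j) is the posterior probability that regions
#' i and j belong to the same cluster. Symmetric with unit diagonal. This is
#' the package's primary representation of parcellation uncertainty, robust
#' to the label switching and varying cluster counts across samples.
#'
#' @param fit a fitted [sirm()] object.
#' @return an N x N matrix with entries in \[0, 1\].
#' @export
coassignment <- function(fit) {
  stopifnot(inherits(fit, "sirm"))
  s <- nrow(fit$z)
  if (s == 0L) stop("empty chain", call. = FALSE)
  n <- fit$n
  m <- matrix(0, n, n)
  for (r in seq_len(s)) {
    zr <- fit$z[r, ]
    m <- m + outer(zr, zr, "==")
  }
  m <- m / s
  dimnames(m) <- list(fit$labels, fit$labels)
  m
}

#' Equal-tailed credible interval for the number of clusters
#'
#' Empirical quantiles of the per-sample cluster count K at the requested
#' level, rounded outward to integers.
#'
#' @param fit a fitted [sirm()] object.
#' @param level interval probability in (0, 1); default 0.95.
#' @return named numeric vector `c(low, high, range)`.
#' @export
credible_interval_K <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sirm"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  k <- fit$K
  if (length(k) == 0L) stop("empty chain", call. = FALSE)
  lo <- floor(stats::quantile(k, (1 - level) / 2, type = 1, names = FALSE))
  hi <- ceiling(stats::quantile(k, 1 - (1 - level) / 2, type = 1,
                                names = FALSE))
  c(low = lo, high = hi, range = hi - lo)
}

#' Cluster probability map for one region
#'
#' Row i of the posterior co-assignment matrix: for a region of interest,
#' the probability that every other region shares its cluster. The
#' self-entry is 1.
#'
#' @param coassign co-assignment matrix from [coassignment()], or a fitted
#'   [sirm()] object.
#' @param region region index or label.
#' @return a named probability vector of length N.
#' @export
cluster_probability_map <- function(coassign, region) {
  if (inherits(coassign, "sirm")) coassign <- coassignment(coassign)
  if (is.character(region)) {
    region <- match(region, rownames(coassign))
  }
  if (is.na(region) || region < 1 || region > nrow(coassign)) {
    stop("region index out of range", call. = FALSE)
  }
  coassign[region, ]
}

#' @export
print.sirm <- function(x, ...) {
  cat(sprintf("Infinite relational model fit (mode %s)\n", x$mode))
  cat(sprintf("  %d regions, %d subject(s), %d retained samples\n",
              x$n, x$n_subjects, nrow(x$z)))
  mp <- map_estimate(x)
  cat(sprintf("  MAP: %d clusters, log-posterior %.2f\n",
              n_clusters(mp$partition), mp$log_posterior))
  ci <- credible_interval_K(x)
  cat(sprintf("  K posterior: mean %.2f, 95%% CI [%d, %d]\n",
              mean(x$K), ci["low"], ci["high"]))
  invisible(x)
}

#' Summarize a fitted parcellation
#'
#' Collects the MAP partition, the posterior distribution of the number of
#' clusters with its credible interval, cluster sizes, the posterior block
#' connection probabilities at the MAP, and (when streamline counts are
#' available) the within-cluster streamline ratio r_c per cluster.
#'
#' @param object a fitted [sirm()] object.
#' @param level credible level for the interval on K.
#' @param ... unused.
#' @return an object of class `"summary.sirm"`.
#' @export
summary.sirm <- function(object, level = 0.95, ...) {
  mp <- map_estimate(object)
  z <- canonicalize_partition(mp$partition)
  k_tab <- table(object$K) / length(object$K)
  rho <- lapply(mp$adjacency, posterior_rho, z = z,
                alpha = object$hyper$alpha, beta = object$hyper$beta)
  rc <- NULL
  if (object$mode %in% c("sirm", "flat")) {
    stot <- Reduce("+", lapply(object$data, symmetrize))
    rc <- community_ratio(stot, z)$cluster
  }
  structure(list(mode = object$mode, n = object$n,
                 n_subjects = object$n_subjects,
                 n_samples = nrow(object$z),
                 map_partition = mp$partition,
                 map_K = n_clusters(z),
                 map_log_posterior = mp$log_posterior,
                 cluster_sizes = cluster_sizes(z),
                 K_distribution = k_tab,
                 K_interval = credible_interval_K(object, level),
                 level = level,
                 rho_map = rho,
                 community_ratio = rc),
            class = "summary.sirm")
}

#' @export
print.summary.sirm <- function(x, ...) {
  cat(sprintf("Infinite relational model (%s): %d regions, %d subject(s)\n",
              x$mode, x$n, x$n_subjects))
  cat(sprintf("Retained samples: %d\n", x$n_samples))
  cat(sprintf("\nMAP estimate: %d clusters (log-posterior %.2f)\n",
              x$map_K, x$map_log_posterior))
  cat("Cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat(sprintf("\nPosterior of K (%.0f%% CI [%d, %d], range %d):\n",
              100 * x$level, x$K_interval["low"], x$K_interval["high"],
              x$K_interval["range"]))
  print(round(x$K_distribution, 3))
  if (!is.null(x$community_ratio)) {
    cat("\nWithin-cluster streamline ratio r_c (pooled over subjects):\n")
    print(round(x$community_ratio, 3))
  }
  invisible(x)
}

#' @describeIn sirm posterior mean block connection probabilities at the MAP
#'   partition, per subject (a K x K matrix, or a list of them for
#'   multi-subject fits).
#' @param object,x a fitted `sirm` object.
#' @param ... unused.
#' @export
coef.sirm <- function(object, ...) {
  mp <- map_estimate(object)
  z <- canonicalize_partition(mp$partition)
  rho <- lapply(mp$adjacency, posterior_rho, z = z,
                alpha = object$hyper$alpha, beta = object$hyper$beta)
  if (length(rho) == 1L) rho[[1L]] else rho
}

#' @export
logLik.sirm <- function(object, ...) {
  structure(max(object$log_posterior), df = NA_integer_,
            class = "logLik")
}

#' Plot a fitted parcellation
#'
#' Two panels: the posterior co-assignment matrix with regions ordered by
#' the MAP partition (block structure = confident clusters, grey fringes =
#' uncertain assignments), and the joint log-posterior trace over retained
#' samples.
#'
#' @param x a fitted [sirm()] object.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sirm <- function(x, ...) {
  m <- coassignment(x)
  z <- canonicalize_partition(map_estimate(x)$partition)
  ord <- order(z)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(x$n), seq_len(x$n), m[ord, rev(ord)],
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "region (MAP order)", ylab = "region (MAP order)",
                  main = "posterior co-assignment", ...)
  graphics::plot(x$log_posterior, type = "l", xlab = "retained sample",
                 ylab = "joint log-posterior", main = "trace")
  invisible(x)
}

#' Simulate streamline data from a fitted model
#'
#' Draws new streamline count matrices from the forward model at the MAP
#' estimate: for each subject, counts are generated from the
#' Dirichlet-compound-multinomial given the subject's MAP connectome, using
#' the observed per-region row totals. For `"birm"` fits (no counts), new
#' binary networks are drawn instead from the block probabilities at the
#' MAP.
#'
#' @param object a fitted [sirm()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of length `nsim`; each element is a list of per-subject
#'   matrices.
#' @export
simulate.sirm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mp <- map_estimate(object)
  z <- canonicalize_partition(mp$partition)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    if (object$mode == "birm") {
      rho <- lapply(mp$adjacency, posterior_rho, z = z,
                    alpha = object$hyper$alpha, beta = object$hyper$beta)
      out[[s]] <- lapply(rho, function(r) sample_network(z, r))
    } else {
      out[[s]] <- mapply(function(a, dat) {
        sample_streamlines(a, object$hyper$delta_t, object$hyper$delta_f,
                           row_totals = rowSums(dat))
      }, mp$adjacency, object$data, SIMPLIFY = FALSE)
    }
  }
  out
}
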