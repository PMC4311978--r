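test_that("identical seeds give bit-identical chains", {
  toy <- make_toy("community", seed = 1)
  s <- sample_streamlines(toy$adjacency, 1, 0.05, 200, seed = 2)
  ctl <- sirm_control(sweeps = 60, burn_in = 20, thin = 2, seed = 99)
  f1 <- sirm(s, mode = "sirm", control = ctl)
  f2 <- sirm(s, mode = "sirm", control = ctl)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$edges, f2$edges)
  expect_identical(f1$log_posterior, f2$log_posterior)
  # a different seed gives a different chain
  f3 <- sirm(s, mode = "sirm",
             control = sirm_control(sweeps = 60, burn_in = 20, thin = 2,
                                    seed = 100))
  expect_false(identical(f1$z, f3$z))
})

test_that("sampler rejects inconsistent input", {
  a <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  b <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(sirm(list(), mode = "birm"), "no input")
  expect_error(sirm(list(a, b), mode = "birm"), "number of regions")
  expect_error(sirm_control(sweeps = 10, burn_in = 10), "burn_in")
  expect_error(sirm_control(thin = 0), "thin")
})

test_that("a large concentration parameter favours new clusters", {
  # two nodes with no edge: as xi grows the posterior puts nearly all mass
  # on the 2-cluster partition
  a <- lab(matrix(0, 2, 2))
  fit <- sirm(a, mode = "birm", hyper = sirm_hyper(xi = 100),
              control = sirm_control(sweeps = 600, burn_in = 100, thin = 1,
                                     seed = 3))
  expect_gt(mean(fit$K == 2), 0.9)
})

test_that("symmetric clusters receive a symmetric node with equal frequency", {
  # nodes 1-3 and 4-6 form two cliques; node 7 connects to neither, so its
  # co-assignment frequency with each clique should be about equal
  a <- matrix(0, 7, 7)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1
  diag(a) <- 0
  a <- lab(a)
  fit <- sirm(a, mode = "birm",
              control = sirm_control(sweeps = 21000, burn_in = 1000,
                                     thin = 1, seed = 4))
  m <- coassignment(fit)
  with1 <- mean(m[7, 1:3])
  with2 <- mean(m[7, 4:6])
  expect_lt(abs(with1 - with2), 0.03)
})

test_that("flat-mode edge inference favours absence for zero-count dyads", {
  # dyad (1,2) has no streamlines in either direction while the other
  # targets of nodes 1 and 2 carry many counts
  s <- lab(matrix(c(0,  0, 50, 50,
                    0,  0, 50, 50,
                    50, 50, 0,  0,
                    50, 50, 0,  0), 4, byrow = TRUE))
  fit <- sirm(s, mode = "flat", hyper = sirm_hyper(delta_t = 1, delta_f = 0.05),
              control = sirm_control(sweeps = 3000, burn_in = 500, thin = 1,
                                     seed = 5))
  p12 <- mean(vapply(seq_along(fit$edges), function(k)
    1L %in% fit$edges[[k]][[1L]], TRUE))  # dyad index 1 is (1,2)
  expect_lt(p12, 0.5)
})

test_that("MAP extraction takes the highest log-posterior, earliest on ties", {
  fit <- structure(list(z = rbind(c(1, 1, 2), c(1, 2, 2), c(1, 2, 1)),
                        K = c(2L, 2L, 2L),
                        log_posterior = c(-10, -5, -5),
                        edges = NULL,
                        fixed_adjacency = list(matrix(0, 3, 3)),
                        labels = c("a", "b", "c"), n = 3L,
                        n_subjects = 1L, mode = "birm",
                        hyper = sirm_hyper(), control = sirm_control()),
                   class = "sirm")
  mp <- map_estimate(fit)
  expect_equal(mp$index, 2L)
  expect_equal(unname(mp$partition), c(1, 2, 2))
  one <- fit
  one$z <- one$z[1, , drop = FALSE]
  one$log_posterior <- -10
  one$K <- 2L
  expect_equal(map_estimate(one)$index, 1L)
})

test_that("co-assignment expectation averages sample indicators", {
  fit <- structure(list(z = rbind(c(1, 1, 2), c(1, 1, 2)),
                        K = c(2L, 2L), log_posterior = c(-1, -2),
                        edges = NULL, fixed_adjacency = NULL,
                        labels = c("a", "b", "c"), n = 3L, n_subjects = 1L,
                        mode = "birm", hyper = sirm_hyper(),
                        control = sirm_control()),
                   class = "sirm")
  m <- coassignment(fit)
  expect_equal(unname(m), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  # i,j together in exactly one of two samples -> 0.5
  fit$z <- rbind(c(1, 1, 2), c(1, 2, 2))
  m <- coassignment(fit)
  expect_equal(m["a", "b"], 0.5)
  expect_equal(m["b", "c"], 0.5)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(m))
})

test_that("credible intervals on K are equal-tailed and outward-rounded", {
  fit <- structure(list(K = rep(3L, 50), z = matrix(1L, 50, 2),
                        log_posterior = rep(-1, 50)),
                   class = "sirm")
  expect_equal(credible_interval_K(fit),
               c(low = 3, high = 3, range = 0))
  fit$K <- c(rep(3L, 98), rep(4L, 2))
  expect_equal(credible_interval_K(fit, 0.95),
               c(low = 3, high = 3, range = 0))
  fit$K <- c(rep(2L, 10), rep(3L, 80), rep(5L, 10))
  ci <- credible_interval_K(fit, 0.5)
  expect_gte(ci["range"], 0)
  expect_error(credible_interval_K(fit, 1.2), "level")
})

test_that("bIRM recovers the planted community toy and sIRM matches it", {
  toy <- make_toy("community", seed = 1)
  fitb <- sirm(toy$adjacency, mode = "birm",
               control = sirm_control(sweeps = 1500, burn_in = 500, thin = 1,
                                      seed = 7))
  mpb <- map_estimate(fitb)
  expect_equal(n_clusters(mpb$partition), 3)
  expect_equal(ami(mpb$partition, toy$partition), 1)
  # the full streamline pipeline on counts generated from the same network
  s <- sample_streamlines(toy$adjacency, 1, 0.05, 1000, seed = 101)
  fits <- sirm(s, mode = "sirm",
               control = sirm_control(sweeps = 2000, burn_in = 1000,
                                      thin = 2, seed = 2001))
  mps <- map_estimate(fits)
  expect_gte(ami(mps$partition, toy$partition), 0.9)
  # the latent connectome is recovered almost exactly
  expect_lt(mean(mps$adjacency[[1]] != toy$adjacency), 0.05)
  expect_true(all(is.finite(fits$log_posterior)))
})

test_that("birm mode on count input runs the two-stage pipeline", {
  toy <- make_toy("community", seed = 1)
  s <- sample_streamlines(toy$adjacency, 1, 0.05, 500, seed = 10)
  expect_message(
    fit <- sirm(s, mode = "birm",
                control = sirm_control(sweeps = 800, burn_in = 300, thin = 1,
                                       seed = 11)),
    "flat prior")
  expect_equal(n_clusters(map_estimate(fit)$partition), 3)
})

test_that("multi-subject fits share the partition across subjects", {
  set.seed(12)
  sim <- simulate_study(n = 12, k = 3, n_subjects = 3, row_totals = 300,
                        seed = 12)
  fit <- sirm(sim$streamlines, mode = "sirm",
              control = sirm_control(sweeps = 500, burn_in = 200, thin = 2,
                                     seed = 13))
  expect_equal(fit$n_subjects, 3)
  mp <- map_estimate(fit)
  expect_length(mp$adjacency, 3)
  expect_gte(ami(mp$partition, sim$partition), 0.9)
})

test_that("model summaries expose the fitted quantities", {
  toy <- make_toy("community", seed = 1)
  s <- sample_streamlines(toy$adjacency, 1, 0.05, 500, seed = 14)
  fit <- sirm(s, mode = "sirm",
              control = sirm_control(sweeps = 400, burn_in = 200, thin = 2,
                                     seed = 15))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.sirm")
  expect_equal(sm$map_K, n_clusters(map_estimate(fit)$partition))
  expect_length(sm$community_ratio, sm$map_K)
  rho <- coef(fit)
  expect_true(is.matrix(rho))
  expect_true(all(rho > 0 & rho < 1))
  expect_equal(dim(rho), c(sm$map_K, sm$map_K))
  expect_equal(as.numeric(logLik(fit)), max(fit$log_posterior))
  expect_output(print(fit), "MAP")
  expect_output(print(sm), "r_c")
  sims <- simulate(fit, nsim = 2, seed = 16)
  expect_length(sims, 2)
  expect_equal(rowSums(sims[[1]][[1]]), rowSums(s))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
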