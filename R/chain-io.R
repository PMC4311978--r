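#' Serialize and restore a posterior sample chain
#'
#' `write_chain()` stores a fitted chain as newline-delimited JSON, one
#' record per retained sample (cluster assignment, per-subject edge lists as
#' upper-triangle dyad indices, joint log-posterior), together with a JSON
#' metadata header (`<path>.meta.json`: mode, dimensions, region labels,
#' hyperparameters, sampler settings). `read_chain()` restores a `"sirm"`
#' object from the pair; the original data matrices are not stored, so
#' summaries that need streamline counts (the r_c table) are unavailable on
#' a restored chain unless `data` is supplied.
#'
#' @param fit a fitted [sirm()] object.
#' @param path path for the sample records; the metadata header is written
#'   next to it.
#' @param data optional list of the original per-subject matrices to
#'   reattach on read.
#' @return `write_chain()`: `path`, invisibly. `read_chain()`: a `"sirm"`
#'   object.
#' @export
write_chain <- function(fit, path) {
  stopifnot(inherits(fit, "sirm"))
  meta <- list(
    mode = fit$mode, n = fit$n, n_subjects = fit$n_subjects,
    labels = fit$labels,
    hyper = unclass(fit$hyper),
    control = unclass(fit$control),
    has_edges = !is.null(fit$edges),
    fixed_adjacency = if (!is.null(fit$fixed_adjacency))
      lapply(fit$fixed_adjacency, function(a) which(a[upper.tri(a)] == 1))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(nrow(fit$z))) {
    rec <- list(assignment = fit$z[s, ],
                log_posterior = fit$log_posterior[s])
    if (!is.null(fit$edges)) rec$edges <- fit$edges[[s]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path, data = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  z <- do.call(rbind, lapply(recs, function(r) as.integer(r$assignment)))
  lp <- vapply(recs, function(r) as.numeric(r$log_posterior), 0)
  edges <- NULL
  if (isTRUE(meta$has_edges)) {
    edges <- lapply(recs, function(r) {
      e <- r$edges
      if (is.matrix(e)) e <- lapply(seq_len(nrow(e)), function(i) e[i, ])
      if (!is.list(e)) e <- list(e)
      lapply(e, as.integer)
    })
  }
  fixed <- NULL
  if (!is.null(meta$fixed_adjacency)) {
    n <- meta$n
    fx <- meta$fixed_adjacency
    if (!is.list(fx)) fx <- list(fx)
    fixed <- lapply(fx, function(idx) {
      a <- matrix(0, n, n)
      ut <- which(upper.tri(a))
      a[ut[as.integer(idx)]] <- 1
      a + t(a)
    })
  }
  hy <- do.call(sirm_hyper, as.list(meta$hyper))
  ctl_fields <- meta$control[c("sweeps", "burn_in", "thin", "seed",
                               "fix_partition", "verbose",
                               "progress_every")]
  ctl <- do.call(sirm_control, ctl_fields[!vapply(ctl_fields, is.null, TRUE)])
  structure(list(z = z, K = apply(z, 1L, function(r) length(unique(r))),
                 log_posterior = lp, edges = edges,
                 fixed_adjacency = fixed, data = data,
                 labels = as.character(meta$labels), mode = meta$mode,
                 hyper = hy, control = ctl, n = meta$n,
                 n_subjects = meta$n_subjects),
            class = "sirm")
}
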