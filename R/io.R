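#' Read a connectivity matrix from delimited text
#'
#' Reads a square region-by-region matrix from TSV (canonical) or CSV
#' (detected from the header line). The file must carry a header row of
#' region labels and one labelled row per region, with identical row and
#' column label sets in identical order.
#'
#' Two kinds of matrix are supported. `kind = "counts"` is a streamline count
#' matrix: non-negative integers, asymmetry allowed (the streamline count
#' from i to j need not equal the count from j to i). `kind = "binary"` is a
#' structural adjacency matrix: entries 0/1 and symmetric. In both cases
#' regions are not self-connected, so the diagonal must be zero; nonzero
#' diagonals in count matrices (which some tractography exports carry) are
#' zeroed with a warning rather than rejected.
#'
#' @param path path to a TSV/CSV file.
#' @param kind `"counts"` for streamline counts, `"binary"` for an adjacency
#'   matrix.
#' @return a numeric matrix with region labels as dimnames.
#' @seealso [write_connectivity()], [symmetrize()]
#' @export
read_connectivity <- function(path, kind = c("counts", "binary")) {
  kind <- match.arg(kind)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) {
    stop("connectivity matrix must be square, got ",
         nrow(m), " x ", ncol(m), call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row labels and column labels differ", call. = FALSE)
  }
  validate_connectivity(m, kind = kind)
}

validate_connectivity <- function(m, kind = c("counts", "binary")) {
  kind <- match.arg(kind)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("connectivity must be a square matrix", call. = FALSE)
  }
  if (nrow(m) < 2L) {
    stop("need at least 2 regions", call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("r", seq_len(nrow(m)))
  }
  labs <- rownames(m)
  if (anyDuplicated(labs) || any(!nzchar(labs))) {
    stop("region labels must be unique and non-empty", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop("connectivity matrix contains missing values", call. = FALSE)
  }
  if (kind == "counts") {
    if (any(m < 0) || any(m != round(m))) {
      stop("streamline counts must be non-negative integers", call. = FALSE)
    }
    if (any(diag(m) != 0)) {
      warning("nonzero diagonal entries set to zero ",
              "(regions do not seed streamlines to themselves)",
              call. = FALSE)
      diag(m) <- 0
    }
  } else {
    if (!all(m %in% c(0, 1))) {
      stop("adjacency matrix entries must be 0 or 1", call. = FALSE)
    }
    if (!isSymmetric(unname(m))) {
      stop("adjacency matrix must be symmetric (undirected connectivity)",
           call. = FALSE)
    }
    if (any(diag(m) != 0)) {
      warning("nonzero diagonal entries set to zero (no self-connections)",
              call. = FALSE)
      diag(m) <- 0
    }
  }
  m
}

#' Write a connectivity matrix to tab-separated text
#'
#' Inverse of [read_connectivity()]: header row of region labels, one
#' labelled row per region.
#'
#' @param m square matrix with region dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(m, path) {
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("r", seq_len(nrow(m)))
  }
  utils::write.table(cbind(region = rownames(m), as.data.frame(m)),
                     file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Symmetrize a streamline count matrix
#'
#' Streamline counts are seeded per row and need not be symmetric. Methods
#' that require symmetric input (e.g. the within-cluster streamline ratio)
#' use S' = S + t(S), which doubles the total count and makes the count for
#' each unordered region pair the sum of both seeding directions.
#'
#' @param s streamline count matrix (validated as `kind = "counts"`).
#' @return the symmetric matrix `s + t(s)`.
#' @export
symmetrize <- function(s) {
  s <- validate_connectivity(s, kind = "counts")
  s + t(s)
}
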