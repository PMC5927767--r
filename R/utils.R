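# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Coerce any numeric/sparse genes-by-cells matrix to dgCMatrix, preserving
# dimnames, and validate the count-matrix contract.
as_count_matrix <- function(x, check_integer = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(x))) {
    if (nrow(x) > 0) stop("count matrix must carry gene ids (rownames)")
    rownames(x) <- character(0)
  }
  if (is.null(colnames(x))) {
    if (ncol(x) > 0) stop("count matrix must carry cell barcodes (colnames)")
    colnames(x) <- character(0)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate cell barcodes in count matrix")
  v <- x@x
  if (length(v)) {
    if (any(v < 0)) stop("negative entries in count matrix")
    if (check_integer && any(abs(v - round(v)) > 1e-8)) {
      stop("non-integer entries in count matrix")
    }
  }
  x
}

# Per-cell totals and detected-gene counts for a sparse genes-by-cells matrix.
col_stats <- function(counts) {
  list(
    n_umi   = Matrix::colSums(counts),
    n_genes = Matrix::colSums(counts > 0)
  )
}

stopifnot_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", name))
  }
  invisible(p)
}

stopifnot_count <- function(n, name) {
  if (length(n) < 1 || any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop(sprintf("%s must be a positive integer", name))
  }
  invisible(n)
}
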