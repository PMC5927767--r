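#' Quality-control thresholds
#'
#' The defaults are the atlas study's whole-brain settings: cells with fewer
#' than 200 detected genes are discarded, and total UMIs per cell must lie in
#' the 800 to 10,000 window.
#'
#' @param min_genes Minimum number of detected genes per cell.
#' @param umi_lower,umi_upper Inclusive bounds on total UMIs per cell.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, umi_lower = 800, umi_upper = 10000) {
  if (min_genes < 0) stop("min_genes must be >= 0")
  if (umi_lower < 0 || umi_upper < umi_lower) {
    stop("need 0 <= umi_lower <= umi_upper")
  }
  structure(list(min_genes = min_genes, umi_lower = umi_lower,
                 umi_upper = umi_upper), class = "qc_thresholds")
}

#' Filter cells on detected genes and total UMIs
#'
#' Retains cells with `n_genes >= min_genes` and
#' `umi_lower <= n_umi <= umi_upper`, both tests applied jointly in a single
#' pass, so filtering is idempotent and order-independent.
#'
#' @param counts Genes-by-cells count matrix.
#' @param thresholds A [qc_thresholds()] object.
#' @param batch Optional per-cell batch labels carried into the cell table.
#' @param drop_empty_genes Drop genes with zero total count across retained
#'   cells (default `TRUE`).
#' @return A list with `counts` (the filtered matrix), `cells` (a
#'   [cell_table()] of retained cells) and `kept` (logical vector over input
#'   cells).
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(), batch = NULL,
                      drop_empty_genes = TRUE) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  st <- col_stats(counts)
  keep <- st$n_genes >= thresholds$min_genes &
    st$n_umi >= thresholds$umi_lower &
    st$n_umi <= thresholds$umi_upper
  out <- counts[, keep, drop = FALSE]
  if (drop_empty_genes && ncol(out) > 0) {
    out <- out[Matrix::rowSums(out) > 0, , drop = FALSE]
  }
  if (!is.null(batch)) {
    if (length(batch) != length(keep)) stop("batch must have one entry per cell")
    batch <- batch[keep]
  }
  list(counts = out, cells = cell_table(out, batch = batch), kept = unname(keep))
}

#' Library-size log-normalization
#'
#' Computes `x(g, c) = ln(1 + S * count(g, c) / n_umi(c))` with scale factor
#' `S` (default 10,000), the droplet-toolkit default the atlas analysis used.
#' Zeros stay zero, so sparsity is preserved, and for every cell
#' `sum(expm1(x)) == S` exactly.
#'
#' @param counts Genes-by-cells count matrix; every cell must have at least one
#'   UMI (run [qc_filter()] first).
#' @param scale_factor Target per-cell total `S` on the expm1 scale.
#' @return A sparse `dgCMatrix` of normalized values with attribute
#'   `scale_factor`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as_count_matrix(counts)
  n_umi <- Matrix::colSums(counts)
  if (any(n_umi == 0)) {
    stop("cells with zero UMIs present; remove them with qc_filter() first")
  }
  norm <- counts
  tm <- methods::as(norm, "TsparseMatrix")
  tm@x <- log1p(scale_factor * tm@x / n_umi[tm@j + 1L])
  norm <- methods::as(tm, "CsparseMatrix")
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Regress out covariates and scale genes to unit variance
#'
#' Per gene, fits an ordinary-least-squares regression of the normalized
#' values on the covariates (by default a batch indicator design with
#' intercept), keeps the residuals, standardizes them to unit variance and
#' clips at `+/- clip`. With a single batch (or no covariates) this reduces to
#' per-gene centering and scaling. Genes with zero variance are set to zero
#' and flagged rather than erroring.
#'
#' @param norm Normalized genes-by-cells matrix from [log_normalize()].
#' @param covariates Per-cell covariates: a factor/vector (treated as batch),
#'   a data.frame, or `NULL` for intercept-only (pure centering).
#' @param clip Absolute bound on the scaled values (default 10), guarding PCA
#'   against single-cell outliers.
#' @param block_size Number of genes processed per dense block.
#' @return A dense genes-by-cells matrix of clipped residual z-scores with
#'   attribute `constant_genes` (character vector of flagged genes).
#' @export
regress_and_scale <- function(norm, covariates = NULL, clip = 10,
                              block_size = 2000L) {
  norm <- methods::as(norm, "CsparseMatrix")
  n <- ncol(norm)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
  } else if (is.data.frame(covariates)) {
    X <- stats::model.matrix(~., data = covariates)
  } else {
    if (length(covariates) != n) stop("covariates must have one entry per cell")
    df <- data.frame(batch = factor(covariates))
    X <- if (nlevels(df$batch) > 1) stats::model.matrix(~batch, df)
         else matrix(1, n, 1)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design is rank-deficient")
  G <- nrow(norm)
  out <- matrix(0, G, n, dimnames = dimnames(norm))
  const <- logical(G)
  for (start in seq(1L, G, by = block_size)) {
    idx <- start:min(start + block_size - 1L, G)
    Y <- t(as.matrix(norm[idx, , drop = FALSE]))   # cells x genes block
    res <- qr.resid(qx, Y)
    sds <- sqrt(colSums(res^2) / (n - 1))
    zero <- sds < 1e-12
    sds[zero] <- 1
    res <- sweep(res, 2L, sds, "/")
    res[, zero] <- 0
    const[idx] <- zero
    out[idx, ] <- t(pmin(pmax(res, -clip), clip))
  }
  attr(out, "constant_genes") <- rownames(norm)[const]
  attr(out, "clip") <- clip
  out
}
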