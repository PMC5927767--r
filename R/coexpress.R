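# Category labels over subsets of {ACh, Glu, GABA}; "none" completes the
# partition.
transmitter_categories <- function() {
  c("ACh", "Glu", "GABA", "ACh+Glu", "ACh+GABA", "Glu+GABA",
    "ACh+Glu+GABA", "none")
}

#' Per-cell fast-acting neurotransmitter calls
#'
#' A cell is called positive for a transmitter class when its marker gene's
#' log-normalized value exceeds the threshold `tau` (default 2, the display
#' threshold of the atlas t-SNE panels). Markers default to `VAChT` (ACh),
#' `VGlut` (Glu) and `Gad1` (GABA).
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param markers Named character vector mapping class names to marker genes.
#' @param tau Normalized-expression threshold.
#' @return A `data.frame` with one row per cell: `barcode`, one logical
#'   column per class, and `category` (one of the seven non-empty subsets or
#'   `"none"`); attribute `tau` records the threshold.
#' @export
call_transmitter <- function(norm, markers = gene_panels()$transmitters,
                             tau = 2) {
  missing <- setdiff(markers, rownames(norm))
  if (length(missing)) stop("marker gene absent from matrix: ", missing[1L])
  vals <- as.matrix(norm[markers, , drop = FALSE]) > tau
  rownames(vals) <- names(markers)
  calls <- data.frame(barcode = colnames(norm), t(vals), row.names = NULL,
                      stringsAsFactors = FALSE)
  pos <- apply(vals, 2L, function(v) paste(names(markers)[v], collapse = "+"))
  calls$category <- ifelse(pos == "", "none", pos)
  attr(calls, "tau") <- tau
  calls
}

#' Transmitter co-expression summary
#'
#' Counts cells in each of the eight transmitter categories (the seven
#' non-empty subsets of \{ACh, Glu, GABA\} plus `"none"`); the categories
#' partition the cells, so fractions sum to 1.
#'
#' @param calls Output of [call_transmitter()].
#' @return A `data.frame` with `category`, `n`, `fraction`.
#' @export
transmitter_overlap <- function(calls) {
  if (!nrow(calls)) stop("calls for at least one cell required")
  cats <- transmitter_categories()
  n <- vapply(cats, function(k) sum(calls$category == k), integer(1))
  data.frame(category = cats, n = unname(n),
             fraction = unname(n) / nrow(calls), stringsAsFactors = FALSE)
}

#' Neuropeptide radar table
#'
#' For one neuropeptide gene, computes per transmitter category `k` the
#' conditional fraction `f(k) = #(NP-positive and category k) / #(category k)`
#' — the number of co-expressing cells normalized to the total number of
#' cells expressing each neurotransmitter combination — together with the
#' sum-normalized radar values `f(k) / sum(f)` used for plotting relative
#' shapes. NP positivity defaults to raw UMI >= 1 (`detect = "count"`); pass
#' `detect = "normalized"` with a threshold `tau` to use the normalized scale.
#'
#' @param mat Count matrix (for `detect = "count"`) or normalized matrix.
#' @param gene Neuropeptide gene id.
#' @param calls Output of [call_transmitter()] on the same cells.
#' @param detect `"count"` (UMI >= 1) or `"normalized"` (value > `tau`).
#' @param tau Threshold for `detect = "normalized"`.
#' @return A `data.frame` with `category`, `n_category`, `n_coexpressing`,
#'   `fraction`, `radar_value`; empty categories carry `NA` fractions.
#' @export
radar_table <- function(mat, gene, calls, detect = c("count", "normalized"),
                        tau = 2) {
  detect <- match.arg(detect)
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene)
  if (ncol(mat) != nrow(calls)) stop("calls must cover the matrix cells")
  x <- as.numeric(mat[gene, ])
  np_pos <- if (detect == "count") x >= 1 else x > tau
  cats <- transmitter_categories()
  n_cat <- vapply(cats, function(k) sum(calls$category == k), integer(1))
  n_co <- vapply(cats, function(k) sum(np_pos & calls$category == k),
                 integer(1))
  frac <- ifelse(n_cat > 0, n_co / n_cat, NA_real_)
  tot <- sum(frac, na.rm = TRUE)
  radar <- if (tot > 0) frac / tot else ifelse(is.na(frac), NA_real_, 0)
  data.frame(category = cats, n_category = unname(n_cat),
             n_coexpressing = unname(n_co), fraction = unname(frac),
             radar_value = unname(radar), stringsAsFactors = FALSE)
}

#' Histogram of co-expressed gene-set members per cell
#'
#' Counts, per cell of a subset, how many genes of a set are expressed, and
#' tabulates the result over 0..|set| (e.g. how many dopamine receptor types
#' a Kenyon cell expresses).
#'
#' @param mat Count matrix (default detection: UMI >= threshold) or
#'   normalized matrix with `detect = "normalized"`.
#' @param genes Gene set (all must be present).
#' @param cells Optional barcodes or index of the cell subset.
#' @param threshold Detection threshold (default 1 UMI).
#' @param detect `"count"` or `"normalized"` (value > threshold).
#' @return A `data.frame` with `n_genes` (0..|set|), `n_cells`, `fraction`;
#'   counts sum to the subset size.
#' @export
combination_histogram <- function(mat, genes, cells = NULL, threshold = 1,
                                  detect = c("count", "normalized")) {
  detect <- match.arg(detect)
  if (!length(genes)) stop("empty gene set")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) stop("unknown gene: ", missing[1L])
  sub <- mat[genes, , drop = FALSE]
  if (!is.null(cells)) sub <- sub[, cells, drop = FALSE]
  expressed <- if (detect == "count") sub >= threshold else sub > threshold
  per_cell <- Matrix::colSums(expressed)
  bins <- 0:length(genes)
  n <- vapply(bins, function(b) sum(per_cell == b), integer(1))
  data.frame(n_genes = bins, n_cells = n,
             fraction = if (ncol(sub)) n / ncol(sub) else rep(NA_real_, length(n)))
}

#' Neuropeptide burden of a cell subset
#'
#' Fractions of cells expressing at least one and at least two genes of a
#' neuropeptide panel (expression = raw UMI >= 1 by default), as used to
#' quantify neuropeptide co-expression in monoaminergic neurons.
#'
#' @param counts Count matrix.
#' @param panel Non-empty character vector of panel genes; absent genes are
#'   ignored with a warning.
#' @param cells Optional barcodes or index of the subset (non-empty).
#' @param threshold Detection threshold in UMIs.
#' @return A list with `frac_ge1`, `frac_ge2`, `n_cells`, `genes_used`.
#' @export
peptide_burden <- function(counts, panel, cells = NULL, threshold = 1) {
  if (!length(panel)) stop("empty neuropeptide panel")
  present <- intersect(panel, rownames(counts))
  if (!length(present)) stop("no panel genes present in the matrix")
  if (length(present) < length(panel)) {
    warning("panel genes absent from matrix: ",
            paste(setdiff(panel, present), collapse = ", "))
  }
  sub <- counts[present, , drop = FALSE]
  if (!is.null(cells)) sub <- sub[, cells, drop = FALSE]
  if (!ncol(sub)) stop("empty cell subset")
  per_cell <- Matrix::colSums(sub >= threshold)
  list(frac_ge1 = mean(per_cell >= 1), frac_ge2 = mean(per_cell >= 2),
       n_cells = ncol(sub), genes_used = present)
}

#' Pairwise Pearson correlation heatmap with Z-scores
#'
#' Pearson product-moment correlations of the given genes across cells,
#' computed on log-normalized scaled values (any numeric matrix is accepted).
#' Z-scores use the Fisher transform `z = atanh(r) * sqrt(n - 3)` by default;
#' `z = "scale"` instead standardizes the off-diagonal r values within the
#' matrix. Constant genes yield undefined correlations and are flagged.
#'
#' @param values Genes-by-cells numeric matrix (>= 3 cells).
#' @param genes Gene set (>= 2 genes, all present).
#' @param z `"fisher"` or `"scale"`.
#' @return An object of class `correlation_heatmap`: list with `r`, `z`,
#'   `constant` (flagged genes), `n_cells`, `method`.
#' @export
correlation_heatmap <- function(values, genes, z = c("fisher", "scale")) {
  z <- match.arg(z)
  if (length(genes) < 2) stop("need at least two genes")
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) stop("unknown gene: ", missing[1L])
  n <- ncol(values)
  if (n < 3) stop("need at least three cells")
  sub <- t(as.matrix(values[genes, , drop = FALSE]))
  sds <- apply(sub, 2L, stats::sd)
  constant <- genes[sds < 1e-12]
  r <- suppressWarnings(stats::cor(sub))
  if (z == "fisher") {
    zr <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
    diag(zr) <- NA_real_
  } else {
    off <- r[lower.tri(r)]
    off <- off[is.finite(off)]
    zr <- (r - mean(off)) / stats::sd(off)
    diag(zr) <- NA_real_
  }
  structure(list(r = r, z = zr, constant = constant, n_cells = n, method = z),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat("Pearson correlation heatmap:", nrow(x$r), "genes over", x$n_cells,
      "cells\n")
  if (length(x$constant)) {
    cat("constant (undefined) genes:", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a correlation heatmap
#'
#' Basic image plot of the Z-score (or r) matrix.
#'
#' @param x A `correlation_heatmap` object.
#' @param what `"z"` or `"r"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.correlation_heatmap <- function(x, what = c("z", "r"), ...) {
  what <- match.arg(what)
  m <- if (what == "z") x$z else x$r
  k <- nrow(m)
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  graphics::axis(1, seq_len(k), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}
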