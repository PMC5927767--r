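#' Read a Drop-seq digital gene expression (DGE) matrix
#'
#' Reads the tab-delimited DGE dialect written by the Drop-seq tools: the first
#' header field is `GENE`, the remaining header fields are cell barcodes, and
#' each following row holds a gene id and one nonnegative integer UMI count per
#' barcode. Gzipped files are read transparently.
#'
#' @param path Path to a `.dge.txt` or `.dge.txt.gz` file.
#' @return A sparse `dgCMatrix` of UMI counts, genes in rows, barcodes in
#'   columns.
#' @seealso [write_dge()], [read_mtx()], [merge_replicates()]
#' @export
read_dge <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con), add = TRUE)
      data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                        fill = FALSE, data.table = TRUE, showProgress = FALSE)
    } else {
      data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                        data.table = TRUE, showProgress = FALSE)
    }
  },
    error = function(e) stop("malformed DGE file '", path, "': ", conditionMessage(e))
  )
  if (ncol(dt) < 1 || toupper(names(dt)[1]) != "GENE") {
    stop("DGE format error in '", path, "': first header field must be 'GENE'")
  }
  barcodes <- names(dt)[-1]
  if (anyDuplicated(barcodes)) {
    stop("DGE format error in '", path, "': duplicate barcode in header")
  }
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    line <- which(genes == dup)[2L] + 1L
    stop("DGE format error in '", path, "': duplicate gene id '", dup,
         "' at line ", line)
  }
  if (length(barcodes) == 0L || length(genes) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(genes), length(barcodes)),
                              dimnames = list(genes, barcodes))
    return(methods::as(m, "CsparseMatrix"))
  }
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1L]
    stop("DGE format error in '", path, "': non-numeric entries in column ",
         bad + 1L)
  }
  if (any(vals < 0) || any(vals != round(vals))) {
    bad <- which(rowSums(vals < 0 | vals != round(vals)) > 0)[1L]
    stop("DGE format error in '", path, "': negative or non-integer count at line ",
         bad + 1L)
  }
  dimnames(vals) <- list(genes, barcodes)
  as_count_matrix(vals)
}

#' Write a count matrix in the Drop-seq DGE dialect
#'
#' @param counts Genes-by-cells count matrix (sparse or dense) with gene ids in
#'   rownames and barcodes in colnames.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_dge <- function(counts, path) {
  counts <- as_count_matrix(counts)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("GENE", colnames(counts)), collapse = "\t"), con)
  if (nrow(counts)) {
    dense <- as.matrix(counts)
    body <- cbind(rownames(counts),
                  matrix(format(dense, scientific = FALSE, trim = TRUE),
                         nrow = nrow(dense)))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a Matrix-Market triplet count matrix
#'
#' Expects the 10x-style layout: a coordinate `matrix.mtx`, a `features.tsv`
#' (or `genes.tsv`) with gene ids in the first column, and a `barcodes.tsv`.
#' Indices are 1-based per the Matrix-Market standard; duplicate coordinate
#' entries are summed.
#'
#' @param dir Directory containing the three files, or a character vector of
#'   three explicit paths (matrix, features, barcodes).
#' @return A sparse `dgCMatrix` of counts.
#' @export
read_mtx <- function(dir) {
  if (length(dir) == 1L && dir.exists(dir)) {
    mtx <- file.path(dir, "matrix.mtx")
    feats <- file.path(dir, "features.tsv")
    if (!file.exists(feats)) feats <- file.path(dir, "genes.tsv")
    bcs <- file.path(dir, "barcodes.tsv")
  } else if (length(dir) == 3L) {
    mtx <- dir[1L]; feats <- dir[2L]; bcs <- dir[3L]
  } else {
    stop("give a directory or c(matrix, features, barcodes) paths")
  }
  for (f in c(mtx, feats, bcs)) if (!file.exists(f)) stop("missing file: ", f)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("Matrix-Market format error in '", mtx,
                                         "': ", conditionMessage(e)))
  m <- methods::as(m, "CsparseMatrix")  # sums duplicate triplet entries
  genes <- data.table::fread(feats, header = FALSE, sep = "\t",
                             showProgress = FALSE)[[1L]]
  barcodes <- data.table::fread(bcs, header = FALSE, sep = "\t",
                                showProgress = FALSE)[[1L]]
  if (nrow(m) != length(genes)) {
    stop("feature list length (", length(genes), ") does not match matrix rows (",
         nrow(m), ")")
  }
  if (ncol(m) != length(barcodes)) {
    stop("barcode list length (", length(barcodes),
         ") does not match matrix columns (", ncol(m), ")")
  }
  dimnames(m) <- list(as.character(genes), as.character(barcodes))
  as_count_matrix(m)
}

#' Write a count matrix as Matrix-Market triplets
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param counts Genes-by-cells count matrix.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Build a per-cell table of QC metrics
#'
#' One record per matrix column: barcode, batch (if given), total UMIs and
#' number of detected genes.
#'
#' @param counts Genes-by-cells count matrix.
#' @param batch Optional per-cell batch labels, recycled checks apply.
#' @return A `data.frame` with columns `barcode`, `batch`, `n_umi`, `n_genes`.
#' @export
cell_table <- function(counts, batch = NULL) {
  counts <- as_count_matrix(counts)
  st <- col_stats(counts)
  if (is.null(batch)) {
    batch <- rep(NA_character_, ncol(counts))
  } else if (length(batch) != ncol(counts)) {
    stop("batch must have one entry per cell")
  }
  data.frame(barcode = colnames(counts), batch = as.character(batch),
             n_umi = unname(st$n_umi), n_genes = unname(st$n_genes),
             stringsAsFactors = FALSE)
}

#' Merge replicate count matrices into one pooled dataset
#'
#' Genes are unioned (absent genes filled with zeros) and barcodes are made
#' unique by prefixing the batch id with an underscore, since Drop-seq cell
#' barcodes can recur across runs. Total UMIs are conserved.
#'
#' @param matrices List of genes-by-cells count matrices, one per replicate.
#' @param batch_ids Character vector of batch identifiers, one per matrix;
#'   defaults to `names(matrices)` or `batch1..batchN`.
#' @return A list with `counts` (pooled sparse matrix) and `cells` (a
#'   [cell_table()] `data.frame` with the batch of origin).
#' @export
merge_replicates <- function(matrices, batch_ids = NULL) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("matrices must be a non-empty list")
  }
  matrices <- lapply(matrices, as_count_matrix)
  if (is.null(batch_ids)) {
    batch_ids <- if (!is.null(names(matrices))) names(matrices)
                 else paste0("batch", seq_along(matrices))
  }
  if (length(batch_ids) != length(matrices)) {
    stop("batch_ids must have one entry per matrix")
  }
  genes <- Reduce(union, lapply(matrices, rownames))
  trips <- vector("list", length(matrices))
  barcodes <- character(0)
  batch <- character(0)
  offset <- 0L
  for (m in seq_along(matrices)) {
    x <- matrices[[m]]
    tm <- methods::as(x, "TsparseMatrix")
    gi <- match(rownames(x), genes)
    trips[[m]] <- data.frame(i = gi[tm@i + 1L], j = tm@j + 1L + offset, x = tm@x)
    barcodes <- c(barcodes, paste0(batch_ids[m], "_", colnames(x)))
    batch <- c(batch, rep(batch_ids[m], ncol(x)))
    offset <- offset + ncol(x)
  }
  tr <- do.call(rbind, trips)
  pooled <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                 dims = c(length(genes), offset),
                                 dimnames = list(genes, barcodes))
  pooled <- as_count_matrix(pooled)
  list(counts = pooled, cells = cell_table(pooled, batch = batch))
}
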