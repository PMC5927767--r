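#' Principal component analysis of a scaled expression matrix
#'
#' Computes the top principal components of the cells-by-genes data (genes are
#' the variables). Scores are the centered data projected on the top
#' eigenvectors of the gene covariance; loadings are orthonormal with a
#' deterministic sign convention (the largest-magnitude element of each
#' loading is positive). A truncated SVD (irlba) is used when many more
#' components are available than requested; small problems fall back to an
#' exact SVD.
#'
#' @param scaled Genes-by-cells matrix from [regress_and_scale()].
#' @param n_pcs Number of components (default 50, the whole-brain setting).
#' @param seed Seed for the iterative SVD initialisation.
#' @return An object of class `atlas_pca`: list with `loadings` (genes x PCs),
#'   `scores` (cells x PCs), `var_explained` (fractions of total variance) and
#'   `n_pcs`.
#' @export
run_pca <- function(scaled, n_pcs = 50, seed = 42L) {
  X <- t(as.matrix(scaled))                     # cells x genes
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1 || n_pcs > min(dim(X))) {
    stop("n_pcs must lie in [1, min(genes, cells)]")
  }
  X <- sweep(X, 2L, colMeans(X), "-")
  total_var <- sum(X^2) / (nrow(X) - 1)
  if (n_pcs > 0.5 * min(dim(X)) || min(dim(X)) < 100) {
    sv <- svd(X, nu = n_pcs, nv = n_pcs)
    d <- sv$d[seq_len(n_pcs)]
    u <- sv$u; v <- sv$v
  } else {
    sv <- with_seed(seed, irlba::irlba(X, nv = n_pcs))
    d <- sv$d; u <- sv$u; v <- sv$v
  }
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(n_pcs)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]; u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, n_pcs, n_pcs)
  dimnames(scores) <- list(colnames(scaled), paste0("PC", seq_len(n_pcs)))
  dimnames(v) <- list(rownames(scaled), paste0("PC", seq_len(n_pcs)))
  structure(list(loadings = v, scores = scores,
                 var_explained = d^2 / (nrow(X) - 1) / total_var,
                 n_pcs = n_pcs), class = "atlas_pca")
}

#' Jack Straw test for principal-component significance
#'
#' For each replicate, a small fraction of genes is permuted across cells, the
#' PCA is recomputed on the perturbed matrix, and the absolute gene-PC
#' correlations of the permuted genes form the null distribution of
#' association scores for each PC. Because the permuted genes take part in
#' the re-fitted PCA, the null carries the same overfitting as the observed
#' scores. A PC is called significant when the fraction of its genes whose
#' observed score beats the null at the 0.05 level is itself larger than
#' expected by chance (one-sided binomial test at level `alpha`). Each
#' replicate re-runs the PCA, so the test costs `n_reps` times the PCA.
#'
#' @param scaled Genes-by-cells scaled matrix.
#' @param n_pcs Number of PCs to assess.
#' @param n_reps Number of permutation replicates (default 100).
#' @param frac_permuted Fraction of genes permuted per replicate (default
#'   0.01).
#' @param alpha Significance level of the PC-level call.
#' @param seed RNG seed.
#' @return A list with `significant` (integer PC indices), `pc_pvalues`,
#'   `gene_pvalues` (genes x PCs empirical p-values) and the parameters.
#' @export
jackstraw <- function(scaled, n_pcs = 20, n_reps = 100, frac_permuted = 0.01,
                      alpha = 0.05, seed = 42L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (frac_permuted <= 0 || frac_permuted >= 1) {
    stop("frac_permuted must lie in (0, 1)")
  }
  pca <- run_pca(scaled, n_pcs = n_pcs, seed = seed)
  X <- as.matrix(scaled)
  G <- nrow(X)
  obs <- abs(stats::cor(t(X), pca$scores))      # genes x PCs
  m <- max(1L, round(frac_permuted * G))
  null_scores <- with_seed(seed, {
    out <- matrix(0, n_reps * m, n_pcs)
    for (r in seq_len(n_reps)) {
      gi <- sample(G, m)
      Xp <- X
      for (g in gi) Xp[g, ] <- sample(Xp[g, ])
      pca_p <- run_pca(Xp, n_pcs = n_pcs, seed = seed + r)
      out[((r - 1L) * m + 1L):(r * m), ] <-
        abs(stats::cor(t(Xp[gi, , drop = FALSE]), pca_p$scores))
    }
    out
  })
  gene_p <- matrix(NA_real_, G, n_pcs,
                   dimnames = list(rownames(scaled), paste0("PC", seq_len(n_pcs))))
  pc_p <- numeric(n_pcs)
  for (j in seq_len(n_pcs)) {
    nj <- sort(null_scores[, j])
    gene_p[, j] <- 1 - (findInterval(obs[, j], nj) / (length(nj) + 1))
    hits <- sum(gene_p[, j] <= 0.05)
    pc_p[j] <- stats::binom.test(hits, G, p = 0.05,
                                 alternative = "greater")$p.value
  }
  list(significant = which(pc_p < alpha), pc_pvalues = pc_p,
       gene_pvalues = gene_p, n_pcs = n_pcs, n_reps = n_reps,
       frac_permuted = frac_permuted, alpha = alpha, seed = seed)
}

#' t-SNE embedding of PCA scores
#'
#' @param pca An `atlas_pca` object (or a plain cells-by-dims score matrix).
#' @param perplexity t-SNE perplexity (default 30); must be below
#'   `(cells - 1) / 3`.
#' @param seed RNG seed; identical seeds give identical embeddings.
#' @param n_pcs Optional number of leading PCs to use (default all).
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return A cells-by-2 coordinate matrix with barcode rownames.
#' @export
run_tsne <- function(pca, perplexity = 30, seed = 42L, n_pcs = NULL, ...) {
  scores <- if (inherits(pca, "atlas_pca")) pca$scores else as.matrix(pca)
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity must be below (cells - 1) / 3; got ", perplexity,
         " with ", n, " cells")
  }
  emb <- with_seed(seed, Rtsne::Rtsne(scores, dims = 2,
                                      perplexity = perplexity, pca = FALSE,
                                      check_duplicates = FALSE, ...))$Y
  dimnames(emb) <- list(rownames(scores), c("tSNE1", "tSNE2"))
  emb
}

#' Shared-nearest-neighbor graph
#'
#' Builds the k-nearest-neighbor sets of every cell in PC space (Euclidean
#' distance, each cell's set including itself) and weights the edge between
#' two cells by the Jaccard overlap of their neighbor sets. Edges whose weight
#' does not exceed `prune` are removed (so `prune = 1` empties the graph).
#'
#' @param pca An `atlas_pca` object or a cells-by-dims score matrix.
#' @param k Neighborhood size (default 20).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return An object of class `snn_graph`: list with `snn` (sparse symmetric
#'   weight matrix, zero diagonal), `k`, `prune`.
#' @export
build_snn <- function(pca, k = 20, prune = 1/15) {
  scores <- if (inherits(pca, "atlas_pca")) pca$scores else as.matrix(pca)
  n <- nrow(scores)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- RANN::nn2(scores, k = k)$nn.idx          # includes self (column 1)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                            dims = c(n, n))
  inter <- Matrix::tcrossprod(A)                 # |kNN(i) intersect kNN(j)|
  # tcrossprod returns a symmetric class storing one triangle; expand it
  tm <- methods::as(methods::as(inter, "generalMatrix"), "TsparseMatrix")
  w <- tm@x / (2 * k - tm@x)                     # Jaccard: |I| / (|A|+|B|-|I|)
  keep <- w > prune & tm@i != tm@j               # strict: prune = 1 empties the graph
  snn <- Matrix::sparseMatrix(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                              x = w[keep], dims = c(n, n),
                              dimnames = list(rownames(scores), rownames(scores)))
  structure(list(snn = snn, k = k, prune = prune), class = "snn_graph")
}

#' Modularity (Louvain) clustering of an SNN graph
#'
#' Greedy modularity optimisation with a resolution parameter, via the Louvain
#' algorithm. The atlas default resolution is 2.5, the whole-brain setting.
#' Cells isolated by pruning form singleton communities.
#'
#' @param graph An `snn_graph` from [build_snn()].
#' @param resolution Modularity resolution (larger gives more clusters).
#' @param seed RNG seed fixing the (randomized) node visit order.
#' @return An object of class `cluster_labels`: list with `labels` (integer,
#'   contiguous from 0, named by barcode), `method`, `resolution`, `seed`.
#' @export
modularity_cluster <- function(graph, resolution = 2.5, seed = 42L) {
  stopifnot(inherits(graph, "snn_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$snn, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  labels <- as.integer(igraph::membership(comm)) - 1L
  names(labels) <- rownames(graph$snn)
  labels <- relabel_contiguous(labels)
  structure(list(labels = labels, method = "snn_louvain",
                 resolution = resolution, seed = seed),
            class = "cluster_labels")
}

#' Manually edit cluster labels
#'
#' Explicit curation interface: reassigns the given cells to a (possibly new)
#' cluster and relabels contiguously. Published atlas clusters were
#' "subsequently manually modified"; this supports the same step as data
#' editing, not as an algorithm.
#'
#' @param labels A `cluster_labels` object.
#' @param cells Barcodes (names of the label vector) to reassign.
#' @param new_label Integer label to assign (new values allowed).
#' @return The modified `cluster_labels` object (`method` gains a
#'   `"+manual"` suffix on first edit).
#' @export
edit_cluster_labels <- function(labels, cells, new_label) {
  stopifnot(inherits(labels, "cluster_labels"))
  missing <- setdiff(cells, names(labels$labels))
  if (length(missing)) stop("unknown barcode: ", missing[1L])
  labels$labels[cells] <- as.integer(new_label)
  labels$labels <- relabel_contiguous(labels$labels)
  if (!grepl("\\+manual$", labels$method)) {
    labels$method <- paste0(labels$method, "+manual")
  }
  labels
}

# Map labels to 0..(K-1) in order of first appearance.
relabel_contiguous <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u) - 1L
  names(out) <- names(labels)
  out
}

#' k-means clustering of PCA scores
#'
#' Standard k-means with k-means++ seeding (the whole-brain alternative that
#' produced 29 clusters used k = 29).
#'
#' @param pca An `atlas_pca` object or score matrix.
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param iter_max Maximum Lloyd iterations.
#' @return A `cluster_labels` object (`method = "kmeans"`).
#' @export
kmeans_cluster <- function(pca, k, seed = 42L, iter_max = 100) {
  scores <- if (inherits(pca, "atlas_pca")) pca$scores else as.matrix(pca)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(scores)) stop("k must not exceed the number of cells")
  labels <- with_seed(seed, {
    centers <- kmeanspp_init(scores, k)
    if (k == 1L) {
      rep(0L, nrow(scores))
    } else {
      fit <- stats::kmeans(scores, centers = centers, iter.max = iter_max)
      as.integer(fit$cluster) - 1L
    }
  })
  names(labels) <- rownames(scores)
  structure(list(labels = relabel_contiguous(labels), method = "kmeans",
                 k = k, seed = seed), class = "cluster_labels")
}

# k-means++ initial centers: each next center drawn with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
    for (j in 2L:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Re-cluster a subset of cells
#'
#' Re-runs the analysis chain (log-normalize, regress/scale, PCA, SNN,
#' modularity clustering) on a subset of cells only, optionally restricting
#' the PCA to a list of guide genes, as done for the projection-neuron and
#' monoaminergic re-clusterings (6 PCs; the monoamine run used the nine guide
#' genes of [gene_panels()]`$monoamine_markers`).
#'
#' @param counts Full genes-by-cells count matrix.
#' @param cells Barcodes (or logical/integer index) of the subset.
#' @param batch Optional per-cell batch labels for the full matrix.
#' @param guide_genes Optional genes to restrict the PCA input to.
#' @param n_pcs PCs used for re-clustering (default 6).
#' @param k,prune SNN parameters.
#' @param resolution Louvain resolution.
#' @param scale_factor,clip Preprocessing parameters.
#' @param seed RNG seed.
#' @return A list with `labels` (a `cluster_labels` object), `pca` and the
#'   subset barcodes.
#' @export
subcluster <- function(counts, cells, batch = NULL, guide_genes = NULL,
                       n_pcs = 6, k = 20, prune = 1/15, resolution = 1,
                       scale_factor = 1e4, clip = 10, seed = 42L) {
  counts <- as_count_matrix(counts)
  if (is.character(cells)) {
    missing <- setdiff(cells, colnames(counts))
    if (length(missing)) stop("unknown barcodes in subset: ", missing[1L])
    idx <- match(cells, colnames(counts))
  } else {
    idx <- seq_len(ncol(counts))[cells]
  }
  if (!length(idx)) stop("empty cell subset")
  if (!is.null(guide_genes)) {
    unknown <- setdiff(guide_genes, rownames(counts))
    if (length(unknown)) stop("unknown guide gene: ", unknown[1L])
  }
  sub <- counts[, idx, drop = FALSE]
  sub <- sub[Matrix::rowSums(sub) > 0, , drop = FALSE]
  norm <- log_normalize(sub, scale_factor = scale_factor)
  cov <- if (!is.null(batch)) batch[idx] else NULL
  scaled <- regress_and_scale(norm, covariates = cov, clip = clip)
  if (!is.null(guide_genes)) {
    present <- intersect(guide_genes, rownames(scaled))
    if (!length(present)) stop("no guide genes present after filtering")
    scaled <- scaled[present, , drop = FALSE]
  }
  n_pcs <- min(n_pcs, nrow(scaled) - 1L, ncol(scaled) - 1L)
  pca <- run_pca(scaled, n_pcs = n_pcs, seed = seed)
  snn <- build_snn(pca, k = min(k, ncol(scaled) - 1L), prune = prune)
  labels <- modularity_cluster(snn, resolution = resolution, seed = seed)
  list(labels = labels, pca = pca, cells = colnames(sub))
}
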