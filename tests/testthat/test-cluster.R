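test_that("PCA recovers planted low-rank structure and hand-computed loadings", {
  # rank-1 data: one direction carries essentially all variance
  set.seed(1)
  u <- rnorm(30); v <- rnorm(10)
  X <- outer(v, u)                   # genes x cells
  dimnames(X) <- list(paste0("g", 1:10), paste0("c", 1:30))
  pca <- run_pca(X, n_pcs = 3)
  expect_gte(pca$var_explained[1], 0.999)

  # 2-gene, 3-cell toy: loadings equal the covariance eigenvectors (up to sign,
  # fixed by the largest-element-positive convention)
  Y <- rbind(g1 = c(0, 1, 2), g2 = c(0, 2, 4.5))
  colnames(Y) <- paste0("c", 1:3)
  pca2 <- run_pca(Y, n_pcs = 2)
  ev <- eigen(stats::cov(t(Y)))$vectors
  for (j in 1:2) {
    s <- ev[which.max(abs(ev[, j])), j]
    expect_equal(unname(pca2$loadings[, j]), ev[, j] * sign(s),
                 tolerance = 1e-10)
  }
  expect_equal(crossprod(pca2$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # scores are invariant to cell order
  perm <- c(2, 3, 1)
  pca3 <- run_pca(Y[, perm], n_pcs = 2)
  expect_equal(unname(pca3$scores), unname(pca2$scores[perm, ]),
               tolerance = 1e-10)

  expect_error(run_pca(Y, n_pcs = 5), "n_pcs")
})

test_that("jackstraw flags structured PCs and nothing at alpha = 0", {
  set.seed(2)
  # strong 2-cluster structure on 40 genes
  grp <- rep(0:1, each = 30)
  X <- matrix(rnorm(120 * 60), 120, 60)
  X[1:40, grp == 1] <- X[1:40, grp == 1] + 3
  dimnames(X) <- list(paste0("g", 1:120), paste0("c", 1:60))
  scaled <- regress_and_scale(Matrix::Matrix(X, sparse = TRUE))
  js <- jackstraw(scaled, n_pcs = 5, n_reps = 50, frac_permuted = 0.05,
                  seed = 1)
  expect_true(1 %in% js$significant)

  js0 <- jackstraw(scaled, n_pcs = 5, n_reps = 20, frac_permuted = 0.05,
                   alpha = 0, seed = 1)
  expect_length(js0$significant, 0)

  # pure noise: the PC-level test stays near its nominal size
  N <- matrix(rnorm(150 * 80), 150, 80,
              dimnames = list(paste0("g", 1:150), paste0("c", 1:80)))
  scaled_n <- regress_and_scale(Matrix::Matrix(N, sparse = TRUE))
  js_n <- jackstraw(scaled_n, n_pcs = 20, n_reps = 50, frac_permuted = 0.05,
                    alpha = 0.05, seed = 3)
  expect_lte(length(js_n$significant), 4)
})

test_that("t-SNE embeddings are shaped, deterministic and separate planted blobs", {
  set.seed(4)
  n <- 120
  scores <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
                  matrix(rnorm(n / 2 * 5, mean = 12), ncol = 5))
  rownames(scores) <- paste0("c", 1:n)
  emb <- run_tsne(scores, perplexity = 15, seed = 99)
  expect_equal(dim(emb), c(n, 2L))
  expect_identical(emb, run_tsne(scores, perplexity = 15, seed = 99))

  lab <- rep(1:2, each = n / 2)
  sil <- cluster::silhouette(lab, dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(run_tsne(scores, perplexity = 60), "perplexity")
})

test_that("SNN Jaccard weights match brute force on four collinear points", {
  # near-equidistant points on a line (spacing perturbed so the nearest
  # neighbor of every point is unique), k = 2 (self + nearest): Jaccard
  # weights checked by exhaustive neighbor-set enumeration
  scores <- matrix(c(0, 1, 2.05, 3.15), ncol = 1,
                   dimnames = list(paste0("c", 1:4), "PC1"))
  g <- build_snn(scores, k = 2, prune = 0)
  nn_sets <- lapply(seq_len(4), function(i) {
    d <- abs(scores[, 1] - scores[i, 1])
    order(d)[1:2]
  })
  for (i in 1:3) {
    for (j in (i + 1):4) {
      jac <- length(intersect(nn_sets[[i]], nn_sets[[j]])) /
        length(union(nn_sets[[i]], nn_sets[[j]]))
      got <- g$snn[i, j]
      if (jac == 0) expect_equal(got, 0) else expect_equal(got, jac)
    }
  }
  expect_true(Matrix::isSymmetric(g$snn))
  expect_true(all(g$snn@x >= 0 & g$snn@x <= 1))
  expect_equal(unname(Matrix::diag(g$snn)), rep(0, 4))

  # prune = 1 removes every edge
  g2 <- build_snn(scores, k = 2, prune = 1)
  expect_equal(Matrix::nnzero(g2$snn), 0)
  expect_error(build_snn(scores, k = 0), "positive")
})

test_that("modularity clustering splits cliques and respects the resolution limit", {
  # two 10-node cliques joined by a single edge
  n <- 20
  A <- matrix(0, n, n)
  A[1:10, 1:10] <- 1; A[11:20, 11:20] <- 1
  diag(A) <- 0
  A[10, 11] <- A[11, 10] <- 1
  snn <- structure(list(snn = Matrix::Matrix(A, sparse = TRUE,
                                             dimnames = list(paste0("c", 1:n),
                                                             paste0("c", 1:n))),
                        k = 9, prune = 0), class = "snn_graph")
  lab <- modularity_cluster(snn, resolution = 1, seed = 1)
  expect_equal(length(unique(lab$labels)), 2L)
  expect_equal(length(unique(lab$labels[1:10])), 1L)
  expect_equal(length(unique(lab$labels[11:20])), 1L)

  low <- modularity_cluster(snn, resolution = 0.01, seed = 1)
  expect_equal(length(unique(low$labels)), 1L)

  # disconnected components are never merged
  A2 <- A; A2[10, 11] <- A2[11, 10] <- 0
  snn2 <- snn; snn2$snn <- Matrix::Matrix(A2, sparse = TRUE,
                                          dimnames = dimnames(snn$snn))
  lab2 <- modularity_cluster(snn2, resolution = 0.0001, seed = 1)
  expect_equal(length(unique(lab2$labels[1:10])), 1L)
  expect_false(any(lab2$labels[1:10] %in% lab2$labels[11:20]))
})

test_that("k-means recovers separated blobs and honors k = 1", {
  set.seed(5)
  scores <- rbind(matrix(rnorm(200), ncol = 2),
                  matrix(rnorm(200, mean = 20), ncol = 2))
  rownames(scores) <- paste0("c", 1:200)
  one <- kmeans_cluster(scores, k = 1, seed = 1)
  expect_equal(unique(one$labels), 0L)

  two <- kmeans_cluster(scores, k = 2, seed = 1)
  truth <- rep(1:2, each = 100)
  expect_equal(mclust::adjustedRandIndex(two$labels, truth), 1)
  expect_identical(two$labels, kmeans_cluster(scores, k = 2, seed = 1)$labels)
  expect_error(kmeans_cluster(scores, k = 0), "positive")
})

test_that("manual label edits reassign cells and stay contiguous", {
  labels <- structure(list(labels = stats::setNames(c(0L, 0L, 1L, 1L),
                                                    paste0("c", 1:4)),
                           method = "snn_louvain", resolution = 1, seed = 1L),
                      class = "cluster_labels")
  edited <- edit_cluster_labels(labels, c("c3"), 5L)
  expect_equal(sort(unique(edited$labels)), c(0L, 1L, 2L))
  expect_false(edited$labels[["c3"]] == edited$labels[["c4"]])
  expect_match(edited$method, "\\+manual$")
  expect_error(edit_cluster_labels(labels, "nope", 0L), "unknown barcode")
})

test_that("subclustering recovers planted subtypes within a subset", {
  res <- small_atlas()
  truth <- res$truth$cells
  # restrict to two planted clusters and re-cluster them
  sub_bc <- truth$barcode[truth$cluster %in% c(1, 2) & !truth$doublet]
  sc <- subcluster(res$counts, sub_bc, batch = truth$batch, n_pcs = 6,
                   resolution = 0.5, seed = 42)
  lab <- sc$labels$labels
  truth_sub <- truth$cluster[match(sc$cells, truth$barcode)]
  expect_gte(mclust::adjustedRandIndex(lab, truth_sub), 0.9)
  expect_error(subcluster(res$counts, sub_bc, guide_genes = "nope"),
               "unknown guide gene")
  expect_error(subcluster(res$counts, character(0)), "barcodes|empty")
})
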