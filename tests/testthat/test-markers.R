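test_that("rank-sum test matches exact enumeration on canonical toys", {
  # all ranks separated: C(6,3) = 20 assignments, two extremes -> p = 0.1
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)
  expect_equal(res$U, 0)

  # identical samples: perfect symmetry, p = 1
  expect_equal(rank_sum_test(c(2, 5, 5), c(2, 5, 5))$p, 1)

  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum p-values equal the enumeration oracle on random draws", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    vals <- sample(0:4, n1 + n2, replace = TRUE)  # heavy ties on purpose
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    expect_equal(rank_sum_test(a, b)$p, oracle_ranksum_exact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the tie-corrected normal approximation matches R's implementation", {
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:3, 25, replace = TRUE)
    b <- sample(0:3, 30, replace = TRUE)
    if (length(unique(c(a, b))) < 2) next
    mine <- rank_sum_test(a, b)$p
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
  # the matrix path agrees with the scalar path
  M <- rbind(g1 = c(a, b), g2 = rnorm(55))
  colnames(M) <- paste0("c", 1:55)
  grp <- rep(c(TRUE, FALSE), c(25, 30))
  mat <- dropatlas:::ranksum_rows(M, grp)
  expect_equal(mat$p[1], rank_sum_test(M[1, grp], M[1, !grp])$p,
               tolerance = 1e-12)
  expect_equal(mat$p[2], rank_sum_test(M[2, grp], M[2, !grp])$p,
               tolerance = 1e-12)
})

make_two_cluster_norm <- function(n_side = 60, n_null = 40, fold = 4,
                                  seed = 1) {
  set.seed(seed)
  n <- 2 * n_side
  base_mu <- 5
  counts <- matrix(rpois(n_null * n, base_mu), n_null, n)
  marker <- c(rpois(n_side, base_mu * fold), rpois(n_side, base_mu))
  m <- rbind(matrix(marker, 1), counts)
  dimnames(m) <- list(c("marker", paste0("null", seq_len(n_null))),
                      paste0("c", seq_len(n)))
  list(norm = log_normalize(m), labels = rep(c(0L, 1L), each = n_side))
}

test_that("one-vs-rest marker discovery finds planted markers and no nulls", {
  d <- make_two_cluster_norm()
  mk <- find_markers(d$norm, d$labels)
  expect_true("marker" %in% mk$gene[mk$cluster == 0])
  expect_false(any(grepl("^null", mk$gene)))
  expect_true(all(mk$avg_log2fc >= 1))
  expect_true(all(mk$p_val_adj < 0.01))

  # invariance under cell permutation
  perm <- sample(ncol(d$norm))
  mk2 <- find_markers(d$norm[, perm], d$labels[perm])
  expect_equal(mk2[order(mk2$cluster, mk2$gene), ],
               mk[order(mk$cluster, mk$gene), ], ignore_attr = TRUE)

  # Bonferroni monotonicity: stricter alpha yields a subset
  strict <- find_markers(d$norm, d$labels, alpha = 1e-6)
  loose <- find_markers(d$norm, d$labels, alpha = 0.05)
  expect_true(all(paste(strict$gene, strict$cluster) %in%
                    paste(loose$gene, loose$cluster)))

  expect_error(find_markers(d$norm, rep(0L, ncol(d$norm))), "two clusters")
})

test_that("identical clusters produce no markers", {
  set.seed(3)
  m <- matrix(rpois(50 * 80, 4), 50, 80,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:80)))
  norm <- log_normalize(m)
  lab <- rep(c(0L, 1L), 40)
  expect_equal(nrow(find_markers(norm, lab)), 0L)
  expect_equal(nrow(pairwise_markers(norm, lab)), 0L)
})

test_that("pairwise markers honor the either-cluster fraction gate", {
  d <- make_two_cluster_norm(fold = 6)
  pw <- pairwise_markers(d$norm, d$labels, min_fraction = 0.5, lfc_min = 1.5)
  expect_true("marker" %in% pw$gene)
  expect_true(all(pw$other != pw$cluster))

  # a gene expressed only in one cluster still passes the gate through that
  # cluster; an impossible gate removes everything
  none <- pairwise_markers(d$norm, d$labels, min_fraction = 1.01)
  expect_equal(nrow(none), 0L)
})

test_that("marker presets carry the figure-legend thresholds", {
  expect_equal(marker_preset("kc"), list(min_fraction = 0.5, lfc_min = 1.5,
                                         alpha = 0.01))
  expect_equal(marker_preset("glia"), list(min_fraction = 0.75, lfc_min = 2,
                                           alpha = 0.01))
  expect_equal(marker_preset("monoamine"),
               list(min_fraction = 0.5, lfc_min = 1, alpha = 0.01))
})

test_that("panel annotation names planted cell types and leaves distractors", {
  set.seed(9)
  n_per <- 40
  # three clusters; clusters 0/1 carry planted panels, cluster 2 is flat
  genes <- c("sNPF", "Fas2", "trio", paste0("bg", 1:20))
  mk_cluster <- function(active) {
    m <- matrix(rpois(23 * n_per, 1), 23, n_per)
    m[active, ] <- m[active, ] + matrix(rpois(length(active) * n_per, 20),
                                        length(active), n_per)
    m
  }
  m <- cbind(mk_cluster(1:2), mk_cluster(3), mk_cluster(integer(0)))
  dimnames(m) <- list(genes, paste0("c", seq_len(3 * n_per)))
  norm <- log_normalize(m)
  lab <- rep(0:2, each = n_per)
  panels <- list(marker_panel("ab_like", c("sNPF", "Fas2"), negative = "trio"),
                 marker_panel("prime_like", "trio", negative = "sNPF"))
  ann <- annotate_clusters(norm, lab, panels)
  expect_equal(ann$annotation, c("ab_like", "prime_like", "unannotated"))

  # panel order does not matter
  ann2 <- annotate_clusters(norm, lab, rev(panels))
  expect_equal(ann2$annotation, ann$annotation)

  # no panels: everything unannotated
  empty <- annotate_clusters(norm, lab, list())
  expect_true(all(empty$annotation == "unannotated"))

  # absent panel genes warn and are scored over present genes
  expect_warning(annotate_clusters(norm, lab,
                                   list(marker_panel("x", c("sNPF", "gone")))),
                 "absent")
})

test_that("the built-in Kenyon-cell panels encode the subtype logic", {
  p <- kc_panels()
  names(p) <- vapply(p, `[[`, "", "name")
  expect_true("trio" %in% p$KC_gamma$positive)
  expect_true("trio" %in% p$KC_alpha_beta$negative)
  expect_true("sNPF" %in% p$KC_alpha_prime_beta_prime$negative)
})
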