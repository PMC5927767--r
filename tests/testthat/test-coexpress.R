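make_norm_toy <- function(vals, genes) {
  m <- toy_counts(vals, genes = genes)
  norm <- Matrix::Matrix(m, sparse = TRUE)
  attr(norm, "scale_factor") <- 1e4
  norm
}

test_that("transmitter calls threshold each marker gene at tau", {
  # one cell with VAChT = 3.0, Gad1 = 2.5, VGlut = 0 -> ACh+GABA; one blank
  norm <- make_norm_toy(c(3, 0, 2.5, 0, 0, 0),
                        genes = c("VAChT", "VGlut", "Gad1"))
  calls <- call_transmitter(norm, tau = 2)
  expect_equal(calls$category, c("ACh+GABA", "none"))
  expect_true(calls$ACh[1] && calls$GABA[1] && !calls$Glu[1])
  expect_equal(attr(calls, "tau"), 2)
  expect_error(call_transmitter(norm[1:2, ]), "absent")
})

test_that("transmitter overlap partitions cells and matches brute force", {
  set.seed(12)
  vals <- matrix(runif(3 * 10, 0, 4), 3, 10,
                 dimnames = list(c("VAChT", "VGlut", "Gad1"), paste0("c", 1:10)))
  norm <- Matrix::Matrix(vals, sparse = TRUE)
  calls <- call_transmitter(norm, tau = 2)
  ov <- transmitter_overlap(calls)
  expect_equal(sum(ov$n), 10L)
  expect_equal(sum(ov$fraction), 1)
  oracle <- oracle_transmitter_categories(vals, 2)
  for (k in ov$category) {
    expect_equal(ov$n[ov$category == k], sum(oracle == k))
  }
})

test_that("radar tables equal exhaustive counting on a 20-cell toy", {
  set.seed(13)
  tx <- matrix(sample(c(0, 3), 3 * 20, replace = TRUE), 3, 20,
               dimnames = list(c("VAChT", "VGlut", "Gad1"), paste0("c", 1:20)))
  np <- matrix(sample(0:2, 20, replace = TRUE), 1, 20,
               dimnames = list("Tk", paste0("c", 1:20)))
  counts <- rbind(tx, np)
  calls <- call_transmitter(Matrix::Matrix(tx, sparse = TRUE), tau = 2)
  rt <- radar_table(counts, "Tk", calls)
  cats <- oracle_transmitter_categories(tx, 2)
  for (i in seq_len(nrow(rt))) {
    k <- rt$category[i]
    n_cat <- sum(cats == k)
    expect_equal(rt$n_category[i], n_cat)
    if (n_cat > 0) {
      expect_equal(rt$fraction[i], sum(np[1, ] >= 1 & cats == k) / n_cat)
    } else {
      expect_true(is.na(rt$fraction[i]))
    }
  }
  # radar values renormalize the defined fractions to unit sum
  expect_equal(sum(rt$radar_value, na.rm = TRUE), 1)

  # a neuropeptide expressed nowhere gives all-zero fractions
  counts["Tk", ] <- 0
  rt0 <- radar_table(counts, "Tk", calls)
  expect_true(all(rt0$fraction[rt0$n_category > 0] == 0))
  expect_error(radar_table(counts, "nope", calls), "unknown gene")
})

test_that("combination histograms count co-expressed set members exactly", {
  m <- toy_counts(c(1, 0, 2, 0,   0, 0, 0, 0,   1, 1, 1, 1,
                    0, 1, 0, 0,   2, 0, 1, 0,   3, 3, 0, 1),
                  genes = c("r1", "r2", "r3", "r4"))
  h <- combination_histogram(m, c("r1", "r2", "r3", "r4"))
  per_cell <- colSums(m >= 1)
  for (b in 0:4) expect_equal(h$n_cells[h$n_genes == b], sum(per_cell == b))
  expect_equal(sum(h$n_cells), ncol(m))

  # bin 0 captures cells expressing none
  expect_equal(h$n_cells[h$n_genes == 0], sum(per_cell == 0))
  expect_error(combination_histogram(m, character(0)), "empty gene set")
  expect_error(combination_histogram(m, "missing"), "unknown gene")
})

test_that("peptide burden reports at-least-one and at-least-two fractions", {
  # exactly half the cells express one panel gene
  m <- toy_counts(c(1, 0, 0, 0, 1, 0, 0, 0), genes = c("npA", "npB"))
  pb <- peptide_burden(m, c("npA", "npB"))
  expect_equal(pb$frac_ge1, 0.5)
  expect_equal(pb$frac_ge2, 0)
  expect_error(peptide_burden(m, character(0)), "empty")
  expect_error(peptide_burden(m, c("npA"), cells = integer(0)), "empty cell")
  expect_warning(peptide_burden(m, c("npA", "gone")), "absent")
})

test_that("correlation heatmaps match closed-form Pearson values", {
  vals <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
                flat = c(5, 5, 5))
  colnames(vals) <- paste0("c", 1:3)
  ch <- correlation_heatmap(vals, c("a", "b", "c", "flat"))
  expect_equal(ch$r["a", "a"], 1)
  expect_equal(ch$r["a", "b"], 1)
  expect_equal(ch$r["a", "c"], -1)
  expect_equal(ch$r, t(ch$r))
  expect_equal(ch$constant, "flat")
  expect_true(all(abs(ch$r[c("a", "b", "c"), c("a", "b", "c")]) <= 1))

  zs <- correlation_heatmap(vals, c("a", "b", "c"), z = "scale")
  expect_true(is.na(zs$z["a", "a"]))

  expect_error(correlation_heatmap(vals, "a"), "two genes")
  expect_error(correlation_heatmap(vals[, 1:2], c("a", "b")), "three cells")
})

test_that("correlation is invariant to cell permutation", {
  set.seed(14)
  vals <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:30)))
  ch <- correlation_heatmap(vals, rownames(vals))
  ch_perm <- correlation_heatmap(vals[, sample(30)], rownames(vals))
  expect_equal(ch$r, ch_perm$r, tolerance = 1e-12)

  # Fisher Z-scores: atanh(r) * sqrt(n - 3)
  expect_equal(ch$z["g1", "g2"], atanh(ch$r["g1", "g2"]) * sqrt(30 - 3),
               tolerance = 1e-12)
})

test_that("co-expression fractions equal brute force on random toy matrices", {
  set.seed(15)
  for (i in 1:20) {
    n_cells <- sample(5:25, 1)
    genes <- c("VAChT", "VGlut", "Gad1", "np1", "np2")
    m <- matrix(rpois(length(genes) * n_cells, 0.8) *
                  sample(0:1, length(genes) * n_cells, replace = TRUE, prob = c(0.4, 0.6)),
                length(genes), n_cells,
                dimnames = list(genes, paste0("c", seq_len(n_cells))))
    keep <- colSums(m) > 0
    if (sum(keep) < 2) next
    m <- m[, keep, drop = FALSE]
    norm <- log_normalize(m)
    calls <- call_transmitter(norm, tau = 0.5)
    ov <- transmitter_overlap(calls)
    dense_norm <- as.matrix(norm)[c("VAChT", "VGlut", "Gad1"), , drop = FALSE]
    oracle <- oracle_transmitter_categories(dense_norm, 0.5)
    expect_equal(ov$n, vapply(ov$category, function(k) sum(oracle == k),
                              integer(1)), ignore_attr = TRUE)

    pb <- peptide_burden(m, c("np1", "np2"))
    n_np <- colSums(m[c("np1", "np2"), , drop = FALSE] >= 1)
    expect_equal(pb$frac_ge1, mean(n_np >= 1))
    expect_equal(pb$frac_ge2, mean(n_np >= 2))

    hh <- combination_histogram(m, c("np1", "np2"))
    expect_equal(hh$n_cells, vapply(0:2, function(b) sum(n_np == b),
                                    integer(1)))
  }
})
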