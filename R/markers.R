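#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test of location shift between two samples. For group sizes of at
#' most 8 on both sides the p-value is computed by exhaustive enumeration of
#' all group assignments of the (mid-)ranks, which is exact under ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max Largest per-group size for the exact enumeration path.
#' @return A list with `U` (statistic of the first sample) and `p` (two-sided
#'   p-value).
#' @export
rank_sum_test <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    mu <- n1 * n2 / 2
    combos <- utils::combn(N, n1)
    rank_sums <- colSums(matrix(r[combos], nrow = n1))
    Us <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    p <- ranksum_normal_p(U, n1, n2, r)
  }
  list(U = U, p = p)
}

# Normal-approximation two-sided p with tie correction and continuity
# correction, given the pooled (mid-)ranks.
ranksum_normal_p <- function(U, n1, n2, pooled_ranks) {
  N <- n1 + n2
  ties <- table(pooled_ranks)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Per-row (mid-)ranks and tie terms, computed once per matrix so that
# one-vs-rest tests over many clusters can reuse them.
row_rank_stats <- function(M) {
  ranks <- t(apply(M, 1L, rank))
  tie_term <- apply(M, 1L, function(x) {
    d <- tabulate(match(x, unique(x)))
    sum(d^3 - d)
  })
  list(ranks = ranks, tie_term = tie_term)
}

# Vectorized rank-sum p-values for every row given precomputed rank stats.
# grp: logical vector over columns marking the "in" group. Returns the
# normal-approximation p (same formula as ranksum_normal_p) per row.
ranksum_rows_from_stats <- function(rs, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); N <- n1 + n2
  U <- rowSums(rs$ranks[, grp, drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - rs$tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300))
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[sigma2 <= 0] <- 1
  list(U = U, p = p)
}

ranksum_rows <- function(M, grp) {
  ranksum_rows_from_stats(row_rank_stats(M), grp)
}

# Mean of expm1(normalized values) per row over a column subset, and the
# fraction of cells with nonzero expression.
.group_summary <- function(norm, idx) {
  sub <- norm[, idx, drop = FALSE]
  list(mean_expm1 = Matrix::rowSums(expm1(sub)) / length(idx),
       frac = Matrix::rowSums(sub > 0) / length(idx))
}

# Log2 fold change on expm1-normalized means with pseudocount 1.
.log2fc <- function(mean_in, mean_out) {
  log2((mean_in + 1) / (mean_out + 1))
}

#' One-vs-rest marker discovery
#'
#' For each cluster, tests every gene passing an expressed-fraction gate with
#' the Wilcoxon rank-sum test against all other cells, Bonferroni-corrects
#' over the genes tested for that cluster, and reports genes with average log2
#' fold change at least `lfc_min` and adjusted p below `alpha` (defaults 1 and
#' 0.01, the atlas thresholds). Log2 fold changes are computed on expm1 of
#' the normalized means with pseudocount 1; a gene counts as expressed in a
#' cell when its raw UMI count is at least 1 (equivalently, its normalized
#' value is nonzero).
#'
#' @param norm Normalized genes-by-cells matrix from [log_normalize()].
#' @param labels A `cluster_labels` object or an integer/character vector of
#'   per-cell labels.
#' @param cluster Optional single cluster to test (default: all clusters).
#' @param min_fraction Expressed-fraction gate: genes are tested when
#'   expressed in at least this fraction of cells in the cluster or in the
#'   rest (default 0.1).
#' @param lfc_min,alpha Reporting thresholds on log2 FC and Bonferroni p.
#' @return A `data.frame` of marker records sorted by log2 FC within cluster:
#'   `gene`, `cluster`, `avg_log2fc`, `p_val`, `p_val_adj`, `pct_in`,
#'   `pct_out`.
#' @export
find_markers <- function(norm, labels, cluster = NULL, min_fraction = 0.1,
                         lfc_min = 1, alpha = 0.01) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  if (length(lab) != ncol(norm)) stop("labels must have one entry per cell")
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("marker discovery needs at least two clusters")
  targets <- if (is.null(cluster)) clusters else cluster
  if (!all(targets %in% clusters)) stop("unknown cluster requested")
  # ranks over all cells are shared by every one-vs-rest comparison
  rank_stats <- row_rank_stats(as.matrix(norm))
  out <- list()
  for (k in targets) {
    grp <- lab == k
    s_in <- .group_summary(norm, which(grp))
    s_out <- .group_summary(norm, which(!grp))
    tested <- which(pmax(s_in$frac, s_out$frac) >= min_fraction)
    if (!length(tested)) next
    rs <- ranksum_rows_from_stats(
      list(ranks = rank_stats$ranks[tested, , drop = FALSE],
           tie_term = rank_stats$tie_term[tested]), grp)
    lfc <- .log2fc(s_in$mean_expm1[tested], s_out$mean_expm1[tested])
    padj <- pmin(1, rs$p * length(tested))
    keep <- lfc >= lfc_min & padj < alpha
    if (!any(keep)) next
    rec <- data.frame(gene = rownames(norm)[tested][keep],
                      cluster = k,
                      avg_log2fc = unname(lfc[keep]),
                      p_val = unname(rs$p[keep]),
                      p_val_adj = unname(padj[keep]),
                      pct_in = unname(s_in$frac[tested][keep]),
                      pct_out = unname(s_out$frac[tested][keep]),
                      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- rec[order(-rec$avg_log2fc), ]
  }
  if (!length(out)) {
    return(data.frame(gene = character(), cluster = integer(),
                      avg_log2fc = numeric(), p_val = numeric(),
                      p_val_adj = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise marker discovery between clusters
#'
#' Tests all unordered pairs of the given clusters. The expressed-fraction
#' gate applies to either member of a pair; thresholds follow the figure
#' presets (see [marker_preset()]).
#'
#' @inheritParams find_markers
#' @param clusters Clusters to compare (default: all, at least two).
#' @param min_fraction Gate on the fraction expressing in either cluster of a
#'   pair (default 0.5, the Kenyon-cell preset).
#' @param lfc_min,alpha Reporting thresholds (defaults 1.5 and 0.01).
#' @return A `data.frame` with columns `gene`, `cluster`, `other`,
#'   `avg_log2fc`, `p_val`, `p_val_adj`, `pct_in`, `pct_out`; each pair
#'   appears once per direction in which a gene passes.
#' @export
pairwise_markers <- function(norm, labels, clusters = NULL, min_fraction = 0.5,
                             lfc_min = 1.5, alpha = 0.01) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  if (length(lab) != ncol(norm)) stop("labels must have one entry per cell")
  if (is.null(clusters)) clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need at least two clusters to compare")
  out <- list()
  for (i in seq_along(clusters)[-length(clusters)]) {
    for (j in (i + 1L):length(clusters)) {
      a <- clusters[i]; b <- clusters[j]
      ia <- which(lab == a); ib <- which(lab == b)
      s_a <- .group_summary(norm, ia)
      s_b <- .group_summary(norm, ib)
      tested <- which(pmax(s_a$frac, s_b$frac) >= min_fraction)
      if (!length(tested)) next
      M <- as.matrix(norm[tested, c(ia, ib), drop = FALSE])
      grp <- rep(c(TRUE, FALSE), c(length(ia), length(ib)))
      rs <- ranksum_rows(M, grp)
      padj <- pmin(1, rs$p * length(tested))
      lfc_ab <- .log2fc(s_a$mean_expm1[tested], s_b$mean_expm1[tested])
      for (dir in 1:2) {
        lfc <- if (dir == 1) lfc_ab else -lfc_ab
        keep <- lfc >= lfc_min & padj < alpha
        if (!any(keep)) next
        s_hi <- if (dir == 1) s_a else s_b
        s_lo <- if (dir == 1) s_b else s_a
        out[[length(out) + 1L]] <- data.frame(
          gene = rownames(norm)[tested][keep],
          cluster = if (dir == 1) a else b,
          other = if (dir == 1) b else a,
          avg_log2fc = unname(lfc[keep]),
          p_val = unname(rs$p[keep]),
          p_val_adj = unname(padj[keep]),
          pct_in = unname(s_hi$frac[tested][keep]),
          pct_out = unname(s_lo$frac[tested][keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), cluster = integer(),
                      other = integer(), avg_log2fc = numeric(),
                      p_val = numeric(), p_val_adj = numeric(),
                      pct_in = numeric(), pct_out = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$other, -res$avg_log2fc), ]
}

#' Marker-panel cluster annotation
#'
#' Scores each cluster against each panel: the score is the mean, over the
#' panel's positive genes, of (fraction of cluster cells expressing the gene)
#' times (mean normalized expression in the cluster); negative markers are
#' scored the same way. A cluster is assigned the best-scoring panel whose
#' positive score reaches `min_score` and whose negative-marker score stays
#' below `neg_ratio` times the positive score (scores live on the normalized
#' expression scale, so the negative gate is relative rather than absolute);
#' otherwise it is `"unannotated"`. Panel genes absent from the matrix are
#' dropped with a warning, and ties are broken by panel name so the result
#' does not depend on panel listing order.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param labels Cluster labels (object or vector).
#' @param panels List of [marker_panel()] objects.
#' @param min_score Minimum positive score for assignment (default 0.5).
#' @param neg_ratio Maximum tolerated negative-to-positive score ratio
#'   (default 0.5).
#' @return A `data.frame` with one row per cluster: `cluster`, `annotation`,
#'   `score`, `negative_score`.
#' @export
annotate_clusters <- function(norm, labels, panels, min_score = 0.5,
                              neg_ratio = 0.5) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  clusters <- sort(unique(lab))
  if (!length(panels)) {
    return(data.frame(cluster = clusters, annotation = "unannotated",
                      score = NA_real_, negative_score = NA_real_,
                      stringsAsFactors = FALSE))
  }
  panel_score <- function(genes, idx) {
    present <- intersect(genes, rownames(norm))
    if (!length(present)) return(NA_real_)
    sub <- norm[present, idx, drop = FALSE]
    frac <- Matrix::rowSums(sub > 0) / length(idx)
    mexp <- Matrix::rowSums(sub) / length(idx)
    mean(frac * mexp)
  }
  for (p in panels) {
    missing <- setdiff(c(p$positive, p$negative), rownames(norm))
    if (length(missing)) {
      warning("panel '", p$name, "': genes absent from matrix: ",
              paste(missing, collapse = ", "))
    }
  }
  panels <- panels[order(vapply(panels, `[[`, "", "name"))]
  res <- data.frame(cluster = clusters, annotation = "unannotated",
                    score = NA_real_, negative_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(clusters)) {
    idx <- which(lab == clusters[ci])
    best <- NULL; best_score <- -Inf; best_neg <- NA_real_
    for (p in panels) {
      pos <- panel_score(p$positive, idx)
      neg <- if (length(p$negative)) panel_score(p$negative, idx) else 0
      if (is.na(pos)) next
      if (is.na(neg)) neg <- 0
      if (pos >= min_score && neg < neg_ratio * pos && pos > best_score) {
        best <- p$name; best_score <- pos; best_neg <- neg
      }
    }
    if (!is.null(best)) {
      res$annotation[ci] <- best
      res$score[ci] <- best_score
      res$negative_score[ci] <- best_neg
    }
  }
  res
}

#' Export a marker table as TSV
#'
#' Writes the marker records in the layout of the published per-cluster
#' marker tables (gene, cluster, average log-fold change, adjusted p-value,
#' expression fractions).
#'
#' @param markers Output of [find_markers()] or [pairwise_markers()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
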