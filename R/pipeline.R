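#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis. Defaults equal
#' the whole-brain study settings wherever the study states one: QC at 200
#' genes and 800-10,000 UMIs, scale factor 10,000, 50 PCs, SNN with k = 20,
#' Louvain resolution 2.5, transmitter threshold tau = 2, sex gene roX1.
#'
#' @param qc A [qc_thresholds()] object.
#' @param scale_factor Log-normalization scale factor `S`.
#' @param clip Scaling clip bound.
#' @param n_pcs Number of principal components.
#' @param run_jackstraw Run the Jack Straw PC-significance test (off by
#'   default; it is a diagnostic, not a pipeline dependency).
#' @param jackstraw_reps,jackstraw_frac Jack Straw parameters.
#' @param k_snn,prune SNN graph parameters.
#' @param resolution Louvain resolution.
#' @param run_tsne Compute the 2-D t-SNE embedding.
#' @param perplexity t-SNE perplexity.
#' @param run_markers Run one-vs-rest marker discovery on the final clusters.
#' @param marker_min_fraction,marker_lfc_min,marker_alpha Marker thresholds.
#' @param tau Transmitter-call threshold on normalized values.
#' @param sex_gene Male-specific gene id (skipped when absent).
#' @param panels Optional list of [marker_panel()] for annotation.
#' @param seed Master RNG seed for PCA/t-SNE/clustering.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), scale_factor = 1e4,
                            clip = 10, n_pcs = 50, run_jackstraw = FALSE,
                            jackstraw_reps = 100, jackstraw_frac = 0.01,
                            k_snn = 20, prune = 1/15, resolution = 2.5,
                            run_tsne = TRUE, perplexity = 30,
                            run_markers = TRUE, marker_min_fraction = 0.1,
                            marker_lfc_min = 1, marker_alpha = 0.01,
                            tau = 2, sex_gene = "roX1", panels = NULL,
                            seed = 42L) {
  stopifnot(inherits(qc, "qc_thresholds"))
  structure(list(qc = qc, scale_factor = scale_factor, clip = clip,
                 n_pcs = as.integer(n_pcs), run_jackstraw = run_jackstraw,
                 jackstraw_reps = jackstraw_reps,
                 jackstraw_frac = jackstraw_frac, k_snn = as.integer(k_snn),
                 prune = prune, resolution = resolution, run_tsne = run_tsne,
                 perplexity = perplexity, run_markers = run_markers,
                 marker_min_fraction = marker_min_fraction,
                 marker_lfc_min = marker_lfc_min, marker_alpha = marker_alpha,
                 tau = tau, sex_gene = sex_gene, panels = panels,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Scalar fields of [pipeline_config()] may be set in the file; unknown keys
#' error. QC thresholds are given as `min_genes`, `umi_lower`, `umi_upper`.
#'
#' @param path YAML (or JSON, parsed by yaml) configuration file.
#' @return A `pipeline_config` object.
#' @export
pipeline_config_from_file <- function(path) {
  raw <- yaml::read_yaml(path)
  qc_keys <- intersect(names(raw), c("min_genes", "umi_lower", "umi_upper"))
  qc <- do.call(qc_thresholds, raw[qc_keys])
  rest <- raw[setdiff(names(raw), qc_keys)]
  allowed <- setdiff(names(formals(pipeline_config)), c("qc", "panels"))
  unknown <- setdiff(names(rest), allowed)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(qc = qc), rest))
}

#' Run the full atlas analysis pipeline
#'
#' Executes the whole-brain workflow in fixed order: QC filter, library-size
#' log-normalization, batch regression and per-gene scaling, PCA (optionally
#' Jack Straw), SNN-graph Louvain clustering, t-SNE embedding, one-vs-rest
#' marker discovery, optional marker-panel annotation, per-cell transmitter
#' calls with the overlap summary, and bimodal sex assignment when the sex
#' gene is present. Each stage logs cells/genes in and out when
#' `verbose = TRUE`, and the run manifest records every parameter and seed so
#' identical inputs reproduce identical results.
#'
#' @param counts Genes-by-cells UMI count matrix (pooled replicates; see
#'   [merge_replicates()]).
#' @param batch Optional per-cell batch labels (regressed out when at least
#'   two levels are present).
#' @param config A [pipeline_config()] object.
#' @param verbose Log one line per stage.
#' @return An object of class `atlas_fit` with components `cells` (per-cell
#'   table with cluster, transmitter category and sex call), `labels`
#'   (`cluster_labels`), `embedding`, `pca`, `markers`, `annotation`,
#'   `transmitter_overlap`, `sex`, `jackstraw`, `manifest`.
#' @export
run_pipeline <- function(counts, batch = NULL, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  counts <- as_count_matrix(counts)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("qc_filter: %d genes x %d cells in", nrow(counts), ncol(counts))
  qc <- stage("qc_filter", qc_filter(counts, config$qc, batch = batch))
  if (ncol(qc$counts) < 3) stop("fewer than 3 cells pass QC")
  say("qc_filter: %d genes x %d cells out", nrow(qc$counts), ncol(qc$counts))
  batch_kept <- qc$cells$batch

  norm <- stage("log_normalize",
                log_normalize(qc$counts, scale_factor = config$scale_factor))
  cov <- if (!is.null(batch) && length(unique(batch_kept)) > 1) batch_kept
         else NULL
  scaled <- stage("regress_and_scale",
                  regress_and_scale(norm, covariates = cov, clip = config$clip))
  say("regress_and_scale: %d constant genes flagged",
      length(attr(scaled, "constant_genes")))

  n_pcs <- min(config$n_pcs, nrow(scaled) - 1L, ncol(scaled) - 1L)
  pca <- stage("run_pca", run_pca(scaled, n_pcs = n_pcs, seed = config$seed))
  js <- NULL
  if (config$run_jackstraw) {
    js <- stage("jackstraw",
                jackstraw(scaled, n_pcs = n_pcs,
                          n_reps = config$jackstraw_reps,
                          frac_permuted = config$jackstraw_frac,
                          seed = config$seed))
    say("jackstraw: %d of %d PCs significant", length(js$significant), n_pcs)
  }

  snn <- stage("build_snn",
               build_snn(pca, k = min(config$k_snn, ncol(scaled) - 1L),
                         prune = config$prune))
  labels <- stage("modularity_cluster",
                  modularity_cluster(snn, resolution = config$resolution,
                                     seed = config$seed))
  say("clustering: %d clusters", length(unique(labels$labels)))

  embedding <- NULL
  if (config$run_tsne) {
    perp <- min(config$perplexity, floor((ncol(scaled) - 2) / 3))
    embedding <- stage("run_tsne",
                       run_tsne(pca, perplexity = perp, seed = config$seed))
  }

  markers <- NULL
  if (config$run_markers && length(unique(labels$labels)) >= 2) {
    markers <- stage("find_markers",
                     find_markers(norm, labels,
                                  min_fraction = config$marker_min_fraction,
                                  lfc_min = config$marker_lfc_min,
                                  alpha = config$marker_alpha))
    say("markers: %d records", nrow(markers))
  }
  annotation <- NULL
  if (!is.null(config$panels)) {
    annotation <- stage("annotate_clusters",
                        annotate_clusters(norm, labels, config$panels))
  }

  tx_genes <- gene_panels()$transmitters
  calls <- NULL; overlap <- NULL
  if (all(tx_genes %in% rownames(norm))) {
    calls <- stage("call_transmitter",
                   call_transmitter(norm, tau = config$tau))
    overlap <- transmitter_overlap(calls)
  }

  sex <- NULL
  if (!is.null(config$sex_gene) && config$sex_gene %in% rownames(qc$counts)) {
    sex <- stage("sex_assign", sex_assign(qc$counts, config$sex_gene))
    if (sex$fit$bimodal) {
      say("sex_assign: cutoff %.1f, %.1f%% positive", sex$fit$cutoff,
          100 * sex$positive_fraction)
    }
  }

  cells <- qc$cells
  cells$cluster <- unname(labels$labels)
  cells$transmitter <- if (!is.null(calls)) calls$category else NA_character_
  cells$sex <- if (!is.null(sex)) sex$calls$sex else NA_character_
  if (!is.null(annotation)) {
    cells$annotation <- annotation$annotation[match(cells$cluster,
                                                    annotation$cluster)]
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dropatlas")),
    config = config, seed = config$seed,
    n_cells_in = ncol(counts), n_cells_kept = ncol(qc$counts),
    n_genes_in = nrow(counts), n_genes_kept = nrow(qc$counts),
    n_clusters = length(unique(labels$labels)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(cells = cells, labels = labels, embedding = embedding,
                 pca = pca, markers = markers, annotation = annotation,
                 transmitter_overlap = overlap, sex = sex, jackstraw = js,
                 manifest = manifest), class = "atlas_fit")
}

#' @export
print.atlas_fit <- function(x, ...) {
  m <- x$manifest
  cat("Atlas analysis fit\n")
  cat(sprintf("  cells: %d of %d passed QC (%d genes kept)\n",
              m$n_cells_kept, m$n_cells_in, m$n_genes_kept))
  cat(sprintf("  clusters: %d (%s, resolution %.2g, seed %d)\n",
              m$n_clusters, x$labels$method, x$labels$resolution, m$seed))
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %d records\n", nrow(x$markers)))
  }
  if (!is.null(x$sex) && x$sex$fit$bimodal) {
    cat(sprintf("  sex: cutoff %.1f, %.1f%% positive\n", x$sex$fit$cutoff,
                100 * x$sex$positive_fraction))
  }
  invisible(x)
}

#' @export
summary.atlas_fit <- function(object, ...) {
  cs <- table(object$cells$cluster)
  out <- list(cluster_sizes = cs,
              transmitter_overlap = object$transmitter_overlap,
              manifest = object$manifest)
  class(out) <- "summary.atlas_fit"
  out
}

#' @export
print.summary.atlas_fit <- function(x, ...) {
  cat("Cluster sizes:\n")
  print(x$cluster_sizes)
  if (!is.null(x$transmitter_overlap)) {
    cat("\nTransmitter co-expression (fractions):\n")
    df <- x$transmitter_overlap
    print(data.frame(category = df$category,
                     fraction = round(df$fraction, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Plot an atlas fit
#'
#' Scatter plot of the t-SNE embedding colored by cluster (requires the
#' pipeline to have been run with `run_tsne = TRUE`).
#'
#' @param x An `atlas_fit` object.
#' @param color `"cluster"`, `"transmitter"` or `"sex"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.atlas_fit <- function(x, color = c("cluster", "transmitter", "sex"),
                           ...) {
  if (is.null(x$embedding)) stop("no embedding: run the pipeline with run_tsne = TRUE")
  color <- match.arg(color)
  f <- factor(x$cells[[color]])
  pal <- grDevices::hcl.colors(max(3, nlevels(f)), "Dark 3")
  graphics::plot(x$embedding, col = pal[as.integer(f)], pch = 16, cex = 0.4,
                 xlab = "tSNE1", ylab = "tSNE2", ...)
  graphics::legend("topright", legend = levels(f),
                   col = pal[seq_len(nlevels(f))], pch = 16, cex = 0.6,
                   bty = "n")
  invisible(x)
}

#' Export pipeline results as TSV tables
#'
#' Writes `cells.tsv` (per-cell table), `embedding.tsv` and `markers.tsv`
#' (when present) into a directory.
#'
#' @param fit An `atlas_fit` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_atlas_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "atlas_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(fit$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$embedding)) {
    emb <- data.frame(barcode = rownames(fit$embedding), fit$embedding,
                      row.names = NULL)
    utils::write.table(emb, file.path(dir, "embedding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$markers)) {
    write_markers(fit$markers, file.path(dir, "markers.tsv"))
  }
  invisible(dir)
}
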