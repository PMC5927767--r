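#' Configuration for the synthetic midbrain atlas generator
#'
#' Defines the generative model used to emulate a pooled Drop-seq experiment:
#' negative-binomial UMI counts with per-cell lognormal library sizes,
#' multiplicative per-batch effects across eight replicates, planted marker
#' programs per cluster, a configurable doublet fraction, a male-specific
#' bimodal gene (roX1-like), and per-cluster transmitter/neuropeptide
#' expression probabilities. Defaults mirror the study design: 8 equal
#' batches, a 50/50 male/female mix with a male peak at 9 UMIs, a ~3% doublet
#' fraction, and library sizes centred inside the 800-10,000 UMI QC window.
#'
#' @param n_cells,n_genes,n_clusters Total cells, genes and planted clusters.
#' @param cluster_proportions Probability vector over clusters (sums to 1);
#'   default equal.
#' @param n_batches Number of replicate batches (cells split equally).
#' @param batch_effect_sd Log-scale SD of multiplicative per-gene batch
#'   effects.
#' @param library_size_lognormal_params `c(meanlog, sdlog)` of the per-cell
#'   library size.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (`var = mu + phi * mu^2`), shared across genes.
#' @param marker_log2fc Planted log2 fold change of cluster markers.
#' @param markers_per_cluster Number of disjoint marker genes per cluster.
#' @param doublet_rate Fraction of barcodes that are two-cell doublets.
#' @param sex_gene Name of the male-specific gene.
#' @param male_fraction Probability a cell is male.
#' @param male_mean_umi Poisson mean of the sex gene in males (default 9, the
#'   male peak position).
#' @param female_leak Probability a female cell shows one stray sex-gene UMI.
#' @param transmitter_program `n_clusters x 3` matrix of probabilities that a
#'   cell of each cluster expresses the ACh/Glu/GABA marker genes (`VAChT`,
#'   `VGlut`, `Gad1`); default gives each cluster one dominant transmitter.
#' @param neuropeptide_program `n_clusters x P` matrix of expression
#'   probabilities over a neuropeptide panel (default the 16-gene panel of
#'   [gene_panels()]).
#' @param transmitter_mean_umi,neuropeptide_mean_umi Poisson means of the
#'   program genes when expressed.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `atlas_config`.
#' @export
atlas_config <- function(n_cells = 3000, n_genes = 2000, n_clusters = 8,
                         cluster_proportions = NULL, n_batches = 8,
                         batch_effect_sd = 0.15,
                         library_size_lognormal_params = c(log(2000), 0.4),
                         nb_dispersion = 0.3, marker_log2fc = 2,
                         markers_per_cluster = 50, doublet_rate = 0.03,
                         sex_gene = "roX1", male_fraction = 0.5,
                         male_mean_umi = 9, female_leak = 0.01,
                         transmitter_program = NULL,
                         neuropeptide_program = NULL,
                         transmitter_mean_umi = 8, neuropeptide_mean_umi = 4,
                         seed = 1L) {
  stopifnot_count(n_cells, "n_cells"); stopifnot_count(n_genes, "n_genes")
  stopifnot_count(n_clusters, "n_clusters")
  stopifnot_count(n_batches, "n_batches")
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-6 ||
      any(cluster_proportions < 0)) {
    stop("cluster_proportions must be a probability vector over n_clusters")
  }
  stopifnot_prob(doublet_rate, "doublet_rate")
  stopifnot_prob(male_fraction, "male_fraction")
  stopifnot_prob(female_leak, "female_leak")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (is.null(transmitter_program)) {
    transmitter_program <- matrix(0.05, n_clusters, 3,
                                  dimnames = list(NULL, unname(gene_panels()$transmitters)))
    for (k in seq_len(n_clusters)) {
      transmitter_program[k, ((k - 1) %% 3) + 1] <- 0.85
    }
  }
  if (is.null(neuropeptide_program)) {
    np_genes <- gene_panels()$neuropeptides
    neuropeptide_program <- matrix(0.02, n_clusters, length(np_genes),
                                   dimnames = list(NULL, np_genes))
    for (j in seq_along(np_genes)) {
      neuropeptide_program[((j - 1) %% n_clusters) + 1, j] <- 0.5
    }
  }
  stopifnot_prob(transmitter_program, "transmitter_program")
  stopifnot_prob(neuropeptide_program, "neuropeptide_program")
  if (nrow(transmitter_program) != n_clusters ||
      nrow(neuropeptide_program) != n_clusters) {
    stop("program matrices need one row per cluster")
  }
  special <- c(sex_gene, colnames(transmitter_program),
               colnames(neuropeptide_program))
  if (anyDuplicated(special)) stop("special gene names collide")
  if (n_genes <= length(special) + n_clusters * markers_per_cluster) {
    stop("n_genes too small for the marker and program genes")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    n_batches = as.integer(n_batches), batch_effect_sd = batch_effect_sd,
    library_size_lognormal_params = library_size_lognormal_params,
    nb_dispersion = nb_dispersion, marker_log2fc = marker_log2fc,
    markers_per_cluster = as.integer(markers_per_cluster),
    doublet_rate = doublet_rate, sex_gene = sex_gene,
    male_fraction = male_fraction, male_mean_umi = male_mean_umi,
    female_leak = female_leak, transmitter_program = transmitter_program,
    neuropeptide_program = neuropeptide_program,
    transmitter_mean_umi = transmitter_mean_umi,
    neuropeptide_mean_umi = neuropeptide_mean_umi,
    seed = as.integer(seed)), class = "atlas_config")
}

# Counts for one set of cell bodies given per-cell cluster/batch/sex/library.
# P: background relative-expression profiles (G_bg x K), Bmat: batch effects.
.atlas_cell_counts <- function(cells, P, Bmat, cfg, gene_names) {
  G_bg <- nrow(P)
  n <- nrow(cells)
  counts <- matrix(0L, G_bg, n)
  combo <- interaction(cells$cluster, cells$batch, drop = TRUE)
  for (lv in levels(combo)) {
    idx <- which(combo == lv)
    k <- cells$cluster[idx[1L]]; b <- cells$batch[idx[1L]]
    mu0 <- P[, k] * Bmat[, b]
    mu0 <- mu0 / sum(mu0)
    mu <- outer(mu0, cells$library_size[idx])
    counts[, idx] <- matrix(
      stats::rnbinom(G_bg * length(idx), mu = mu, size = 1 / cfg$nb_dispersion),
      G_bg, length(idx))
  }
  tx <- cfg$transmitter_program[cells$cluster, , drop = FALSE]
  tx_counts <- matrix(stats::rbinom(length(tx), 1L, as.vector(tx)) *
                        stats::rpois(length(tx), cfg$transmitter_mean_umi),
                      n, ncol(tx))
  np <- cfg$neuropeptide_program[cells$cluster, , drop = FALSE]
  np_counts <- matrix(stats::rbinom(length(np), 1L, as.vector(np)) *
                        stats::rpois(length(np), cfg$neuropeptide_mean_umi),
                      n, ncol(np))
  male <- cells$sex == "male"
  sex_counts <- integer(n)
  sex_counts[male] <- stats::rpois(sum(male), cfg$male_mean_umi)
  sex_counts[!male] <- stats::rbinom(sum(!male), 1L, cfg$female_leak)
  full <- rbind(counts, t(tx_counts), t(np_counts), matrix(sex_counts, 1L, n))
  rownames(full) <- gene_names
  full
}

#' Generate a synthetic atlas with ground truth
#'
#' Draws a genes-by-cells UMI matrix under the model described in
#' [atlas_config()] together with the planted structure: per-cell cluster,
#' batch, sex, doublet status and component totals, and per-cluster marker
#' sets and expression programs. Doublet barcodes are the sum of two
#' independently drawn cell profiles (second cluster uniform over clusters,
#' same batch).
#'
#' @param config An [atlas_config()] object.
#' @return A list with `counts` (sparse `dgCMatrix`) and `truth` (class
#'   `atlas_truth`: `$cells` data.frame, `$clusters` list with `markers` and
#'   the program matrices, `$seed`).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_special <- 1L + ncol(cfg$transmitter_program) + ncol(cfg$neuropeptide_program)
    G_bg <- cfg$n_genes - n_special
    bg_names <- sprintf("gene%05d", seq_len(G_bg))
    gene_names <- c(bg_names, colnames(cfg$transmitter_program),
                    colnames(cfg$neuropeptide_program), cfg$sex_gene)

    base <- stats::rlnorm(G_bg, 0, 1)
    base <- base / sum(base)
    P <- matrix(base, G_bg, cfg$n_clusters)
    markers <- vector("list", cfg$n_clusters)
    for (k in seq_len(cfg$n_clusters)) {
      idx <- ((k - 1L) * cfg$markers_per_cluster + 1L):(k * cfg$markers_per_cluster)
      markers[[k]] <- bg_names[idx]
      P[idx, k] <- P[idx, k] * 2^cfg$marker_log2fc
    }
    Bmat <- matrix(exp(stats::rnorm(G_bg * cfg$n_batches, 0, cfg$batch_effect_sd)),
                   G_bg, cfg$n_batches)

    N <- cfg$n_cells
    lp <- cfg$library_size_lognormal_params
    cells <- data.frame(
      barcode = sprintf("cell%05d", seq_len(N)),
      cluster = sample(cfg$n_clusters, N, replace = TRUE,
                       prob = cfg$cluster_proportions),
      batch = sample(rep_len(seq_len(cfg$n_batches), N)),
      sex = ifelse(stats::runif(N) < cfg$male_fraction, "male", "female"),
      library_size = stats::rlnorm(N, lp[1], lp[2]),
      stringsAsFactors = FALSE)

    counts <- .atlas_cell_counts(cells, P, Bmat, cfg, gene_names)
    umi1 <- colSums(counts)

    n_d <- round(cfg$doublet_rate * N)
    doublet <- rep(FALSE, N)
    cluster2 <- rep(NA_integer_, N)
    umi2 <- rep(NA_real_, N)
    if (n_d > 0) {
      d_idx <- sample(N, n_d)
      doublet[d_idx] <- TRUE
      comp <- data.frame(
        barcode = cells$barcode[d_idx],
        cluster = sample(cfg$n_clusters, n_d, replace = TRUE),
        batch = cells$batch[d_idx],
        sex = ifelse(stats::runif(n_d) < cfg$male_fraction, "male", "female"),
        library_size = stats::rlnorm(n_d, lp[1], lp[2]),
        stringsAsFactors = FALSE)
      extra <- .atlas_cell_counts(comp, P, Bmat, cfg, gene_names)
      counts[, d_idx] <- counts[, d_idx, drop = FALSE] + extra
      cluster2[d_idx] <- comp$cluster
      umi2[d_idx] <- colSums(extra)
    }
    colnames(counts) <- cells$barcode
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")

    truth <- structure(list(
      cells = data.frame(cells[, c("barcode", "cluster", "batch", "sex")],
                         doublet = doublet, cluster2 = cluster2,
                         expected_library_size = cells$library_size,
                         umi_component1 = unname(umi1),
                         umi_component2 = unname(umi2),
                         stringsAsFactors = FALSE),
      clusters = list(markers = markers,
                      transmitter_program = cfg$transmitter_program,
                      neuropeptide_program = cfg$neuropeptide_program),
      seed = cfg$seed, config = cfg), class = "atlas_truth")
    list(counts = counts, truth = truth)
  })
}

#' Configuration for the two-species (barnyard) mixing generator
#'
#' Models the species-mixing control experiment: a roughly 1:1 suspension of
#' cells from two species whose gene namespaces are kept disjoint by
#' species-prefixed gene ids, so cross-species barcodes reveal droplet
#' doublets.
#'
#' @param n_cells_per_species Length-2 counts of cell bodies per species.
#' @param species_labels Two identifiers used as gene/barcode prefixes.
#' @param doublet_rate Fraction of barcodes holding two cells (each drawn
#'   independently from the species proportions).
#' @param n_genes_per_species Length-2 gene counts.
#' @param library_size_lognormal_params `c(meanlog, sdlog)` of library size.
#' @param nb_dispersion Negative-binomial dispersion.
#' @param contamination Cross-species ambient fraction of each cell's UMIs.
#' @param seed Integer seed.
#' @return A validated list of class `barnyard_config`.
#' @export
barnyard_config <- function(n_cells_per_species = c(1000, 1000),
                            species_labels = c("S2", "Sf9"),
                            doublet_rate = 0.03,
                            n_genes_per_species = c(500, 500),
                            library_size_lognormal_params = c(log(2000), 0.4),
                            nb_dispersion = 0.3, contamination = 0.01,
                            seed = 1L) {
  if (length(n_cells_per_species) != 2 || length(n_genes_per_species) != 2 ||
      length(species_labels) != 2) {
    stop("two species required")
  }
  stopifnot_count(n_cells_per_species, "n_cells_per_species")
  stopifnot_count(n_genes_per_species, "n_genes_per_species")
  if (species_labels[1] == species_labels[2]) stop("species labels must differ")
  stopifnot_prob(doublet_rate, "doublet_rate")
  stopifnot_prob(contamination, "contamination")
  structure(list(n_cells_per_species = as.integer(n_cells_per_species),
                 species_labels = species_labels, doublet_rate = doublet_rate,
                 n_genes_per_species = as.integer(n_genes_per_species),
                 library_size_lognormal_params = library_size_lognormal_params,
                 nb_dispersion = nb_dispersion, contamination = contamination,
                 seed = as.integer(seed)), class = "barnyard_config")
}

#' Generate a synthetic barnyard (species-mixing) matrix
#'
#' Each barcode's counts come from one species' expression profile (plus a
#' small cross-species contamination fraction), or from the sum of two
#' independently drawn cell profiles for doublets. Only doublets whose two
#' cells come from different species are observable as mixed-species barcodes.
#'
#' @param config A [barnyard_config()] object.
#' @return A list with `counts` (sparse matrix, species-prefixed gene ids) and
#'   `truth` (`$cells` data.frame with species of each component and doublet
#'   flags, `$seed`).
#' @export
generate_barnyard <- function(config) {
  stopifnot(inherits(config, "barnyard_config"))
  cfg <- config
  with_seed(cfg$seed, {
    labs <- cfg$species_labels
    G <- cfg$n_genes_per_species
    gene_names <- c(paste0(labs[1], "_", sprintf("gene%04d", seq_len(G[1]))),
                    paste0(labs[2], "_", sprintf("gene%04d", seq_len(G[2]))))
    props <- list(local({p <- stats::rlnorm(G[1], 0, 1); p / sum(p)}),
                  local({p <- stats::rlnorm(G[2], 0, 1); p / sum(p)}))
    blocks <- list(seq_len(G[1]), G[1] + seq_len(G[2]))
    N <- sum(cfg$n_cells_per_species)
    pA <- cfg$n_cells_per_species[1] / N
    lp <- cfg$library_size_lognormal_params
    eps <- cfg$contamination

    draw_profile <- function(species) {
      L <- stats::rlnorm(1, lp[1], lp[2])
      x <- numeric(sum(G))
      own <- blocks[[species]]; other <- blocks[[3 - species]]
      x[own] <- stats::rnbinom(length(own),
                               mu = props[[species]] * L * (1 - eps),
                               size = 1 / cfg$nb_dispersion)
      x[other] <- stats::rpois(length(other), props[[3 - species]] * L * eps)
      x
    }

    n_d <- round(cfg$doublet_rate * N)
    is_doublet <- rep(FALSE, N)
    if (n_d > 0) is_doublet[sample(N, n_d)] <- TRUE
    sp1 <- ifelse(stats::runif(N) < pA, 1L, 2L)
    sp2 <- rep(NA_integer_, N)
    sp2[is_doublet] <- ifelse(stats::runif(n_d) < pA, 1L, 2L)

    counts <- matrix(0, sum(G), N)
    umi1 <- numeric(N); umi2 <- rep(NA_real_, N)
    for (c in seq_len(N)) {
      prof <- draw_profile(sp1[c])
      umi1[c] <- sum(prof)
      if (is_doublet[c]) {
        prof2 <- draw_profile(sp2[c])
        umi2[c] <- sum(prof2)
        prof <- prof + prof2
      }
      counts[, c] <- prof
    }
    dimnames(counts) <- list(gene_names, sprintf("bc%05d", seq_len(N)))
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    truth <- structure(list(
      cells = data.frame(barcode = colnames(counts),
                         species1 = labs[sp1],
                         species2 = ifelse(is.na(sp2), NA_character_, labs[sp2]),
                         doublet = is_doublet,
                         umi_component1 = umi1, umi_component2 = umi2,
                         stringsAsFactors = FALSE),
      seed = cfg$seed, config = cfg), class = "atlas_truth")
    list(counts = counts, truth = truth)
  })
}

#' Write an atlas ground-truth table as TSV
#'
#' @param truth An `atlas_truth` object from [generate_atlas()] or
#'   [generate_barnyard()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "atlas_truth"))
  utils::write.table(truth$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
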