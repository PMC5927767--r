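#' Built-in gene panels for co-expression analyses
#'
#' Gene sets used throughout the fly midbrain analyses, under their FlyBase
#' symbols:
#' \describe{
#'   \item{transmitters}{The fast-acting transmitter markers `VAChT` (ACh),
#'     `VGlut` (Glu) and `Gad1` (GABA).}
#'   \item{neuropeptides}{The 16 neuropeptide-encoding genes of the radar
#'     analyses: sNPF, CCHa2, Tk, spab, jeb, amn, Dh31, Nplp1, AstA, dNPF,
#'     AstC, Dh44, Ms, Mip, PDF, SIFa.}
#'   \item{ilps}{The four detected insulin-like peptides (Ilp2/3/5/6).}
#'   \item{monoamine_markers}{The nine guide genes used for monoaminergic
#'     re-clustering: ple, DAT, SerT, Trh, Vmat, Oamb, Ddc, Tdc2, Tbh.}
#'   \item{da_receptors}{The four dopamine receptors Dop1R1, Dop1R2, Dop2R,
#'     DopEcR.}
#'   \item{nachr_subunits}{The nine detected nicotinic acetylcholine receptor
#'     subunits (alpha 1-7, beta 1-2).}
#'   \item{activity_regulated}{Activity-regulated genes named in the source
#'     analysis (Hr38, sr, CG14186, CG13055); extend with the full published
#'     list when working with real data.}
#' }
#'
#' @return A named list of character vectors.
#' @export
gene_panels <- function() {
  list(
    transmitters = c(ACh = "VAChT", Glu = "VGlut", GABA = "Gad1"),
    neuropeptides = c("sNPF", "CCHa2", "Tk", "spab", "jeb", "amn", "Dh31",
                      "Nplp1", "AstA", "dNPF", "AstC", "Dh44", "Ms", "Mip",
                      "PDF", "SIFa"),
    ilps = c("Ilp2", "Ilp3", "Ilp5", "Ilp6"),
    monoamine_markers = c("ple", "DAT", "SerT", "Trh", "Vmat", "Oamb", "Ddc",
                          "Tdc2", "Tbh"),
    da_receptors = c("Dop1R1", "Dop1R2", "Dop2R", "DopEcR"),
    nachr_subunits = c("nAChRalpha1", "nAChRalpha2", "nAChRalpha3",
                       "nAChRalpha4", "nAChRalpha5", "nAChRalpha6",
                       "nAChRalpha7", "nAChRbeta1", "nAChRbeta2"),
    activity_regulated = c("Hr38", "sr", "CG14186", "CG13055")
  )
}

#' Marker-panel definition
#'
#' A cell-type marker panel: positive markers that should be enriched, and
#' optional negative markers that should be absent.
#'
#' @param name Cell-type name assigned when the panel wins.
#' @param positive Character vector of positive marker genes (non-empty).
#' @param negative Optional character vector of negative markers.
#' @return A list of class `marker_panel`.
#' @export
marker_panel <- function(name, positive, negative = character(0)) {
  if (!length(positive)) stop("a marker panel needs at least one positive gene")
  structure(list(name = name, positive = positive, negative = negative),
            class = "marker_panel")
}

#' Built-in Kenyon-cell subtype marker panels
#'
#' Encodes the subtype logic of the mushroom-body analysis: `sNPF` and `Fas2`
#' mark alpha-beta and gamma Kenyon cells while `trio` marks gamma and
#' alpha'beta' cells, so alpha-beta is sNPF+/Fas2+/trio-, gamma is
#' sNPF+/Fas2+/trio+, and alpha'beta' is trio+/sNPF-.
#'
#' @return A list of three [marker_panel()] objects.
#' @export
kc_panels <- function() {
  list(
    marker_panel("KC_alpha_beta", positive = c("sNPF", "Fas2"),
                 negative = "trio"),
    marker_panel("KC_gamma", positive = c("sNPF", "Fas2", "trio")),
    marker_panel("KC_alpha_prime_beta_prime", positive = "trio",
                 negative = "sNPF")
  )
}

#' Threshold presets for pairwise marker comparisons
#'
#' Named presets matching the figure-legend settings of the source analyses:
#' `"kc"` (expressed in >50% of cells in either cluster, log2 FC > 1.5),
#' `"glia"` (>75%, log2 FC > 2), `"monoamine"` (>50%, log2 FC > 1), all with
#' Bonferroni-corrected p < 0.01.
#'
#' @param name One of `"kc"`, `"glia"`, `"monoamine"`.
#' @return A list with `min_fraction`, `lfc_min`, `alpha`.
#' @export
marker_preset <- function(name = c("kc", "glia", "monoamine")) {
  name <- match.arg(name)
  switch(name,
         kc = list(min_fraction = 0.5, lfc_min = 1.5, alpha = 0.01),
         glia = list(min_fraction = 0.75, lfc_min = 2, alpha = 0.01),
         monoamine = list(min_fraction = 0.5, lfc_min = 1, alpha = 0.01))
}

#' Read marker panels from a YAML or TSV file
#'
#' YAML files hold a list of `name`/`positive`/`negative` entries; TSV files
#' need columns `name`, `gene` and `direction` (`positive`/`negative`).
#'
#' @param path File path (`.yml`/`.yaml` or `.tsv`/`.txt`).
#' @return A list of [marker_panel()] objects.
#' @export
read_marker_panels <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    lapply(raw, function(p) {
      marker_panel(p$name, unlist(p$positive),
                   if (is.null(p$negative)) character(0) else unlist(p$negative))
    })
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "gene", "direction") %in% names(df))) {
      stop("panel TSV needs columns name, gene, direction")
    }
    lapply(split(df, df$name), function(d) {
      marker_panel(d$name[1L], d$gene[d$direction == "positive"],
                   d$gene[d$direction == "negative"])
    })
  }
}
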