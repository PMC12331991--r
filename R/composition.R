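# Exudate sugar composition: mole percentages of hydrolyzable monomers,
# carbohydrate fraction of released DOC, PCA of scaled mole%, PERMANOVA
# between maturity stages, and the Model II regression of DOC exudation on
# the mannuronic-acid mole fraction (the alginate-solubilization signal).

#' Retained sugar monomers
#'
#' The nine hydrolyzable monomers carried through composition analysis.
#' Glucose and mannose+xylose are never present: they leach from the dialysis
#' step and are excluded upstream.
#' @export
SUGAR_MONOMERS <- c("fucose", "rhamnose", "arabinose", "galactosamine",
                    "glucosamine", "galactose", "gal_ura", "glc_ura",
                    "man_ura")

#' Mole percentages of hydrolyzable sugars
#'
#' Converts per-monomer molar concentrations into percentages of total moles
#' over the retained monomers: `mole_pct_i = 100 * c_i / sum(c)`.
#'
#' @param conc numeric matrix or data.frame, samples x monomers,
#'   concentrations >= 0 with at least one positive entry per sample.
#' @return matrix of mole percentages, each row summing to 100.
#' @export
compute_mole_pct <- function(conc) {
  conc <- as.matrix(conc)
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  tot <- rowSums(conc)
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("every sample needs at least one positive monomer concentration")
  100 * conc / tot
}

#' Carbohydrate fraction of released DOC
#'
#' Total hydrolyzable sugar release as a percentage of DOC release, both in
#' carbon units (umol C): `100 * sugar / doc`. `NA` where DOC release is not
#' positive (fraction undefined).
#'
#' @param doc_release_umol_c DOC released (umol C, vectorized).
#' @param sugar_release_umol_c total sugar released (umol C, carbon-normalized
#'   per monomer carbon count, vectorized).
#' @return percentage, `NA` where `doc_release_umol_c <= 0`.
#' @export
carbohydrate_fraction <- function(doc_release_umol_c, sugar_release_umol_c) {
  ifelse(is.finite(doc_release_umol_c) & doc_release_umol_c > 0,
         100 * sugar_release_umol_c / doc_release_umol_c, NA_real_)
}

#' PCA of scaled sugar mole percentages
#'
#' Standard principal component analysis of the mole% matrix after centering
#' and scaling each monomer to unit variance. Zero-variance monomers are
#' dropped with a warning before scaling. Group centroids in score space are
#' returned when labels are supplied.
#'
#' @param mole_pct samples x monomers matrix (rows sum to 100), >= 3 samples.
#' @param groups optional group labels (e.g. maturity) for centroids.
#' @return list with `scores`, `loadings` (rotation), `variance_explained`
#'   (fractions), `centroids` (or NULL), `dropped` (monomers removed).
#' @export
composition_pca <- function(mole_pct, groups = NULL) {
  x <- as.matrix(mole_pct)
  if (nrow(x) < 3L) stop("composition_pca requires >= 3 samples")
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance monomer(s): ", paste(dropped, collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  centroids <- NULL
  if (!is.null(groups)) {
    centroids <- do.call(rbind, lapply(split(seq_len(nrow(x)), groups), function(i)
      colMeans(pc$x[i, , drop = FALSE])))
  }
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       centroids = centroids, dropped = dropped)
}

#' DOC exudation vs mannuronic-acid mole fraction
#'
#' Model II (SMA) regression of per-blade mean DOC exudation on the Man-URA
#' mole *fraction* (0-1). Man-URA enrichment in the exudate marks alginate
#' solubilization, so this slope links composition to the elevated senescent
#' DOC release.
#'
#' @param doc_ex per-sample (typically per-blade mean) DOC exudation rates,
#'   umol C g_DW^-1 h^-1.
#' @param man_ura_mole_pct Man-URA mole percentages (0-100), converted to
#'   fractions internally.
#' @return a [model2_regression()] fit of `doc_ex` on the mole fraction.
#' @export
docex_vs_manura <- function(doc_ex, man_ura_mole_pct) {
  keep <- is.finite(doc_ex) & is.finite(man_ura_mole_pct)
  if (sum(keep) < 3L) stop("docex_vs_manura requires >= 3 paired samples")
  model2_regression(man_ura_mole_pct[keep] / 100, doc_ex[keep])
}
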