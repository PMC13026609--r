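# Exploratory pair embeddings: each pairing becomes one row of a
# shared-allele-count matrix (one column per SNP), projected by PCA or PCoA.
# These are exploratory views only; no classifier is built on them.

#' Pairwise allele-sharing matrix
#'
#' Builds the pairings x SNPs matrix of shared-allele counts (0/1/2) used by
#' the PCA/PCoA embeddings. Loci missing in either member of a pairing are
#' encoded as -1 (PCA policy) or `NA` (PCoA policy, enabling
#' pairwise-complete distances).
#'
#' @param pair_list Named list of pairs, each `list(a = , b = )` of dosage
#'   vectors.
#' @param missing_code `"neg1"` or `"na"`.
#' @return Numeric matrix, one row per pairing.
#' @export
pair_sharing_matrix <- function(pair_list, missing_code = c("neg1", "na")) {
  missing_code <- match.arg(missing_code)
  rows <- lapply(pair_list, function(p) {
    s <- shared_allele_count(p$a, p$b)
    if (missing_code == "neg1") s[is.na(s)] <- -1L
    s
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(pair_list)
  m
}

#' Embed pairings by PCA or PCoA
#'
#' PCA: column-centred principal components of the sharing matrix (via
#' [stats::prcomp()]). PCoA: classical scaling ([ape::pcoa()]) of the
#' pairwise genotype-difference distance ([ape::dist.gene()] with pairwise
#' deletion, i.e. counts of loci with differing sharing values over
#' pairwise-complete columns).
#'
#' @param m Sharing matrix from [pair_sharing_matrix()] (use the `"na"`
#'   policy for PCoA).
#' @param method `"pca"` or `"pcoa"`.
#' @param n_components Number of leading components to return.
#' @return Numeric matrix rows x `n_components` of coordinates.
#' @export
embed_pairs <- function(m, method = c("pca", "pcoa"), n_components = 2) {
  method <- match.arg(method)
  if (nrow(m) < 2) stop_input("need at least two pairings to embed")
  if (method == "pca") {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    if (k < n_components)
      warning(sprintf("rank supports only %d component(s)", k))
    coords <- pc$x[, seq_len(k), drop = FALSE]
  } else {
    d <- ape::dist.gene(m, method = "pairwise", pairwise.deletion = TRUE)
    pco <- ape::pcoa(d)
    k <- min(n_components, ncol(pco$vectors))
    if (k < n_components)
      warning(sprintf("rank supports only %d component(s)", k))
    coords <- pco$vectors[, seq_len(k), drop = FALSE]
    rownames(coords) <- rownames(m)
  }
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  coords
}
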