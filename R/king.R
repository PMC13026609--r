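# Robust kinship coefficient from IBS states (heterozygote/opposite-
# homozygote counts), and its degree classification table.

#' Robust kinship coefficient
#'
#' Estimates the kinship coefficient of a pair from genotype IBS counts:
#'
#'   phi = (N_AaAa - 2 N_AAaa) / (2 N_Aa(i)) + 1/2
#'         - (N_Aa(i) + N_Aa(j)) / (4 N_Aa(i))
#'
#' where N_AaAa counts loci with both samples heterozygous, N_AAaa loci with
#' opposite homozygotes, and N_Aa(i), N_Aa(j) the per-sample heterozygote
#' counts, with i the sample with the greater heterozygosity. Loci missing
#' in either sample are excluded from all counts.
#'
#' @param geno_a,geno_b Integer dosage vectors (0/1/2, NA missing).
#' @return List with `phi` and the counts
#'   `n_both_het, n_opp_hom, n_het_i, n_het_j`; `phi` is `NA` (abstention)
#'   when sample i has no usable heterozygous locus.
#' @export
king_phi <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b))
    stop_input("genotype vectors differ in length (%d vs %d)",
               length(geno_a), length(geno_b))
  valid <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[valid]; b <- geno_b[valid]
  n_bh <- sum(a == 1L & b == 1L)
  n_opp <- sum(abs(a - b) == 2L)
  het_a <- sum(a == 1L); het_b <- sum(b == 1L)
  n_i <- max(het_a, het_b); n_j <- min(het_a, het_b)
  phi <- if (n_i == 0) NA_real_
  else (n_bh - 2 * n_opp) / (2 * n_i) + 0.5 - (n_i + n_j) / (4 * n_i)
  list(phi = phi, n_both_het = n_bh, n_opp_hom = n_opp,
       n_het_i = n_i, n_het_j = n_j)
}

#' Kinship-coefficient inference ranges
#'
#' The degree classification table for the kinship coefficient: degree d is
#' expected at phi = 2^-(d+1) and inferred over the half-open interval
#' (2^-((2d+3)/2), 2^-((2d+1)/2)] (upper bound inclusive); unrelated is
#' phi <= 2^-(21/2). The intervals tile (0, 2^-(3/2)]; coefficients above
#' the degree-1 upper bound are clamped to degree 1. The table spans
#' degrees 1-9: parent-child and siblings are not separated (both degree 1).
#'
#' @return Data frame `degree, expected, lower, upper` (degree 10 =
#'   unrelated, with `lower = -Inf`).
#' @export
king_ranges <- function() {
  d <- 1:9
  data.frame(degree = c(d, UNRELATED_ORDINAL),
             expected = c(2^-(d + 1), 0),
             lower = c(2^(-(2 * d + 3) / 2), -Inf),
             upper = c(2^(-(2 * d + 1) / 2), 2^(-21 / 2)))
}

#' Classify a kinship coefficient into a degree
#'
#' @param phi Kinship coefficient (or `NA` to abstain).
#' @param ranges Table from [king_ranges()].
#' @return An inference-result row (see [inference_result()]): degree
#'   ordinal 1-9 or 10 for unrelated; values above the degree-1 upper bound
#'   are clamped to degree 1.
#' @export
king_classify <- function(phi, ranges = king_ranges()) {
  if (is.na(phi))
    return(inference_result("king", NA_character_, NA_integer_, NA_real_, abstained = TRUE))
  hit <- which(phi > ranges$lower & phi <= ranges$upper)
  degree <- if (length(hit)) ranges$degree[hit[1]] else 1L  # clamp phi > 2^-3/2
  label <- if (degree >= UNRELATED_ORDINAL) "unrelated" else sprintf("degree-%d", degree)
  inference_result("king", label, degree, phi)
}
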