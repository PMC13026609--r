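# Locus-level allele sharing between two diploid genotypes.

#' Shared-allele count between two genotype codes
#'
#' For alternate-allele dosage codes in \{0, 1, 2\} (NA = missing), returns
#' the number of alleles identical by state between the two genotypes:
#' 2 for equal genotypes, 1 when one sample is heterozygous and the other is
#' not the opposite homozygote, 0 for opposite homozygotes, and NA when
#' either code is missing. Vectorised over both arguments.
#'
#' @param code_a,code_b Integer dosage codes (0, 1, 2 or NA).
#' @return Integer vector of shared-allele counts (0, 1, 2 or NA).
#' @export
shared_allele_count <- function(code_a, code_b) {
  check_codes <- function(x, lab) {
    bad <- which(!(is.na(x) | x %in% 0:2))
    if (length(bad))
      stop_input("invalid genotype code %s at position %d (%s): codes must be 0, 1, 2 or NA",
                 format(x[bad[1]]), bad[1], lab)
  }
  check_codes(code_a, "first argument")
  check_codes(code_b, "second argument")
  as.integer(2L - abs(code_a - code_b))
}

# TRUE where the two genotypes share at least one allele (i.e. are not
# opposite homozygotes); NA where either is missing. The concordance notion
# used by both detectors: IBD1 tracts are only half-identical, so genotype
# concordance means >= 1 shared allele.
is_concordant <- function(code_a, code_b) {
  abs(code_a - code_b) <= 1L
}
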