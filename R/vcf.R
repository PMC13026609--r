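# VCF genotype I/O aligned to a panel manifest.
#
# Genotype matrices are plain integer matrices: one row per sample, one
# column per manifest locus (manifest order), entries the alternate-allele
# dosage 0/1/2 with NA for missing. Phase in GT is ignored throughout: every
# method in the package is genotype-level.

#' Read pair genotypes from a VCF
#'
#' Reads the GT field of a VCF and aligns it to a panel manifest by
#' chromosome and position. Unphased (`0/1`) and phased (`0|1`) genotypes are
#' accepted; `./.` and half-calls become missing. Manifest loci absent from
#' the VCF are filled with missing for every sample (a warning reports the
#' count); VCF records whose REF/ALT contradict the manifest alleles are an
#' error.
#'
#' @param path VCF path (plain text or gzipped).
#' @param manifest A `panel_manifest`.
#' @return Integer matrix samples x loci with `NA` for missing calls.
#' @export
read_genotypes_vcf <- function(path, manifest) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- sub("^chr", "", fix[, "CHROM"])
  key_vcf <- paste(chrom, fix[, "POS"], sep = ":")
  key_man <- sprintf("%d:%.0f", manifest$chrom, manifest$pos)
  hit <- match(key_man, key_vcf)
  n_absent <- sum(is.na(hit))
  if (n_absent > 0)
    warning(sprintf("%d manifest loci absent from VCF; set to missing for all samples", n_absent))
  present <- which(!is.na(hit))
  vrow <- hit[present]
  mism <- which(fix[vrow, "REF"] != manifest$ref[present] |
                  fix[vrow, "ALT"] != manifest$alt[present])
  if (length(mism))
    stop_input("VCF alleles disagree with manifest at %s:%s (manifest %s/%s, VCF %s/%s)",
               chrom[vrow[mism[1]]], fix[vrow[mism[1]], "POS"],
               manifest$ref[present[mism[1]]], manifest$alt[present[mism[1]]],
               fix[vrow[mism[1]], "REF"], fix[vrow[mism[1]], "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(gt)
  codes <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(manifest),
                  dimnames = list(samples, manifest$id))
  if (length(present)) {
    sub <- gt[vrow, , drop = FALSE]
    dose <- gt_to_dosage(sub)
    codes[, present] <- t(dose)
  }
  codes
}

# Convert GT strings ("0/1", "1|0", "./.", NA) to dosage; anything containing
# a "." or an allele beyond 0/1 is missing.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2 || any(!parts %in% c("0", "1"))) return(NA_integer_)
    sum(as.integer(parts))
  }, integer(1))
  matrix(map[match(as.vector(gt), u)], nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write genotypes to a VCF
#'
#' Writes a samples-x-loci dosage matrix aligned to a manifest as a minimal
#' VCFv4.2 file carrying only the GT field (`0/0`, `0/1`, `1/1`, `./.`).
#' Round-trips through [read_genotypes_vcf()] code-identically.
#'
#' @param codes Integer matrix samples x loci (rows named by sample).
#' @param manifest A `panel_manifest` with `ncol(codes)` loci.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(codes, manifest, path) {
  if (is.null(dim(codes)) || nrow(codes) < 1)
    stop_input("empty sample set: codes must be a matrix with at least one sample row")
  if (ncol(codes) != nrow(manifest))
    stop_input("codes have %d loci but manifest has %d", ncol(codes), nrow(manifest))
  samples <- rownames(codes) %||% paste0("S", seq_len(nrow(codes)))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  tcodes <- t(codes)  # loci x samples
  body <- matrix(gt_str[as.character(tcodes)], nrow = nrow(tcodes))
  body[is.na(tcodes)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kinsnp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- paste(manifest$chrom, sprintf("%.0f", manifest$pos), manifest$id, manifest$ref,
                 manifest$alt, ".", ".", ".", "GT",
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
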