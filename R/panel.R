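# Panel manifests: ordered autosomal SNP loci with alleles and frequencies.

#' GRCh38 autosome lengths
#'
#' Physical lengths of the 22 human autosomes in megabase pairs (GRCh38
#' primary assembly). Used to lay out synthetic panel fixtures so that
#' chromosome spans and the ~2,875 Mbp total autosome length are realistic.
#'
#' @return Named numeric vector of length 22 (names `"1"`..`"22"`), in Mbp.
#' @export
grch38_autosome_lengths <- function() {
  c(`1` = 248.956422, `2` = 242.193529, `3` = 198.295559, `4` = 190.214555,
    `5` = 181.538259, `6` = 170.805979, `7` = 159.345973, `8` = 145.138636,
    `9` = 138.394717, `10` = 133.797422, `11` = 135.086622, `12` = 133.275309,
    `13` = 114.364328, `14` = 107.043718, `15` = 101.991189, `16` = 90.338345,
    `17` = 83.257441, `18` = 80.373285, `19` = 58.617616, `20` = 64.444167,
    `21` = 46.709983, `22` = 50.818468)
}

SNP_CATEGORIES <- c("kiSNP", "aiSNP", "iiSNP", "piSNP")

validate_panel_manifest <- function(df) {
  required <- c("chrom", "pos", "id", "ref", "alt", "category", "alt_freq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_input("manifest is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df$chrom <- as.integer(df$chrom)
  df$pos <- as.numeric(df$pos)
  bad <- which(!(df$chrom %in% 1:22))
  if (length(bad))
    stop_input("manifest row %d: chrom must be an autosome label 1-22", bad[1])
  bad <- which(df$ref == df$alt)
  if (length(bad))
    stop_input("manifest row %d (id %s): ref and alt alleles are identical", bad[1], df$id[bad[1]])
  bad <- which(!(df$alt_freq > 0 & df$alt_freq < 1))
  if (length(bad))
    stop_input("manifest row %d (id %s): alt_freq %g outside (0,1)", bad[1], df$id[bad[1]], df$alt_freq[bad[1]])
  dup <- which(duplicated(df$id))
  if (length(dup))
    stop_input("manifest row %d: duplicate id %s", dup[1], df$id[dup[1]])
  if (nrow(df) > 1) {
    d_chrom <- diff(df$chrom)
    if (any(d_chrom < 0))
      stop_input("manifest row %d (id %s): chromosomes out of order",
                 which(d_chrom < 0)[1] + 1L, df$id[which(d_chrom < 0)[1] + 1L])
    bad <- which(d_chrom == 0 & diff(df$pos) <= 0)
    if (length(bad))
      stop_input("manifest row %d (id %s): position not strictly increasing within chromosome",
                 bad[1] + 1L, df$id[bad[1] + 1L])
  }
  rownames(df) <- NULL
  class(df) <- c("panel_manifest", "data.frame")
  df
}

#' Load a SNP panel manifest
#'
#' Reads a tab-separated panel manifest with columns
#' `chrom, pos, id, ref, alt, category, alt_freq`, validates it and returns
#' a `panel_manifest` (a data frame sorted by chromosome and position, with
#' marker ordinals implied by row order).
#'
#' @param path Path to the manifest TSV.
#' @return A `panel_manifest` data frame.
#' @export
load_panel_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  validate_panel_manifest(df)
}

#' Write a panel manifest to TSV
#'
#' @param manifest A `panel_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic autosomal SNP panel
#'
#' Builds a synthetic panel fixture emulating a medium-density forensic
#' kinship panel: `n_snps` biallelic loci spread over `n_chrom` autosomes with
#' per-chromosome counts proportional to GRCh38 autosome lengths (~2,875 Mbp
#' in total over 22 autosomes). Alternate-allele frequencies are drawn from a
#' Beta(2, 2) distribution clipped to (0.05, 0.95), giving the
#' intermediate-frequency spectrum typical of kinship-informative SNPs.
#'
#' @param n_snps Total number of loci (default 10030, the autosomal marker
#'   count of the emulated panel).
#' @param n_chrom Number of autosomes to use, starting from chromosome 1.
#' @param seed Integer seed; the fixture is deterministic given the seed.
#' @return A `panel_manifest`.
#' @export
generate_panel_fixture <- function(n_snps = 10030, n_chrom = 22, seed = 1) {
  stopifnot(n_chrom >= 1, n_chrom <= 22, n_snps >= n_chrom)
  lens <- grch38_autosome_lengths()[seq_len(n_chrom)]
  # largest-remainder apportionment with at least one SNP per chromosome
  quota <- n_snps * lens / sum(lens)
  counts <- pmax(1L, floor(quota))
  while (sum(counts) < n_snps) {
    i <- which.max(quota - counts)
    counts[i] <- counts[i] + 1L
  }
  while (sum(counts) > n_snps) {
    i <- which.max(counts - quota)
    counts[i] <- counts[i] - 1L
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_chrom), function(ci) {
      n <- counts[ci]
      len_bp <- round(lens[ci] * 1e6)
      pos <- sort(sample.int(len_bp - 2L, n)) + 1L
      data.frame(chrom = ci, pos = pos, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
    freq <- pmin(0.95, pmax(0.05, stats::rbeta(n, 2, 2)))
    category <- sample(SNP_CATEGORIES, n, replace = TRUE,
                       prob = c(9867, 56, 94, 22) / 10039)
    df$id <- sprintf("rs_fix_%05d", seq_len(n))
    df$ref <- unname(ref)
    df$alt <- unname(alt)
    df$category <- category
    df$alt_freq <- freq
    validate_panel_manifest(df)
  })
}

# Row indices of `manifest` falling on chromosome `chrom`.
manifest_chrom_index <- function(manifest, chrom) {
  which(manifest$chrom == chrom)
}

#' Panel genome span
#'
#' Length of the genome covered by the panel, defined as the sum over
#' chromosomes of (last SNP position - first SNP position). This is the
#' denominator used by the IBD0-proportion classifier: detected segments can
#' never extend beyond panel coverage, so the covered span rather than the
#' full assembly length is the natural reference.
#'
#' @param manifest A `panel_manifest`.
#' @return Genome span in Mbp.
#' @export
genome_span_mbp <- function(manifest) {
  spans <- tapply(manifest$pos, manifest$chrom, function(p) max(p) - min(p))
  sum(spans) / 1e6
}

#' Derive coverage-gap mask intervals from a panel
#'
#' Identifies regions of the panel with gaps in SNP coverage: for every pair
#' of adjacent manifest SNPs whose distance strictly exceeds
#' `gap_mbp` megabase pairs, the open interval between them is reported as a
#' masked region (0-based half-open, BED convention). Long coverage gaps are
#' where run-based IBD detection loses positional specificity, so detected
#' segments are trimmed against these intervals.
#'
#' @param manifest A `panel_manifest`.
#' @param gap_mbp Gap threshold in Mbp (default 5); strictly greater gaps are
#'   masked.
#' @return Data frame `chrom, start, end` (0-based half-open), possibly empty.
#' @export
derive_gap_mask <- function(manifest, gap_mbp = 5) {
  stopifnot(gap_mbp > 0)
  out <- lapply(unique(manifest$chrom), function(ci) {
    pos <- manifest$pos[manifest$chrom == ci]
    if (length(pos) < 2) return(NULL)
    gap <- diff(pos)
    hit <- which(gap > gap_mbp * 1e6)
    if (!length(hit)) return(NULL)
    # open gap between the two SNPs: (pos[i], pos[i+1]) exclusive of both,
    # i.e. 0-based half-open [pos[i], pos[i+1] - 1)
    data.frame(chrom = ci, start = pos[hit], end = pos[hit + 1L] - 1L)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chrom = integer(), start = numeric(), end = numeric())
  rownames(out) <- NULL
  out
}
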