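# IBD segment detection.
#
# A1: maximal runs of genotype concordance (no opposite homozygotes),
#     filtered by physical length and SNP informativity, then trimmed
#     against masked regions.
# A2: sliding windows of L SNPs scored by the robust kinship coefficient;
#     windows above threshold are merged and filtered by sharing purity.
#
# Segments are data frames with columns chrom, start_ord, end_ord (manifest
# ordinals, inclusive), start_bp, end_bp, length_mbp, n_snps, informativity,
# purity, source.

#' Detector configuration
#'
#' Thresholds for both IBD-segment detectors. Defaults are the operating
#' point used throughout: 10 Mbp minimum segment length and informativity
#' threshold 50 for the concordance-run detector (A1); 80-SNP windows, a
#' window kinship-coefficient threshold of 0.23 and a minimum sharing purity
#' of 0.95 for the windowed detector (A2).
#'
#' @param min_len_mbp Minimum segment length (Mbp) for A1.
#' @param min_informativity Informativity threshold for A1 (segments kept
#'   only if strictly above it).
#' @param window_len Window length in SNPs for A2 (>= 2).
#' @param window_phi_threshold Kinship-coefficient threshold above which a
#'   window is stored (strict).
#' @param min_purity Minimum fraction of non-missing in-segment loci sharing
#'   at least one allele for A2 segments.
#' @param masks Optional mask intervals (data frame `chrom, start, end`,
#'   0-based half-open) applied by A1's trimming step.
#' @return A `detector_config` list.
#' @export
detector_config <- function(min_len_mbp = 10, min_informativity = 50,
                            window_len = 80, window_phi_threshold = 0.23,
                            min_purity = 0.95, masks = NULL) {
  stopifnot(min_len_mbp > 0, min_informativity > 0, window_len >= 2,
            window_phi_threshold > 0, min_purity > 0)
  structure(list(min_len_mbp = min_len_mbp,
                 min_informativity = min_informativity,
                 window_len = as.integer(window_len),
                 window_phi_threshold = window_phi_threshold,
                 min_purity = min_purity,
                 masks = masks),
            class = "detector_config")
}

empty_segments <- function() {
  data.frame(chrom = integer(), start_ord = integer(), end_ord = integer(),
             start_bp = numeric(), end_bp = numeric(), length_mbp = numeric(),
             n_snps = integer(), informativity = numeric(), purity = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

make_segments <- function(chrom, start_ord, end_ord, manifest, n_snps = NULL,
                          informativity = NA_real_, purity = NA_real_,
                          source = NA_character_) {
  if (!length(chrom)) return(empty_segments())
  start_bp <- manifest$pos[start_ord]
  end_bp <- manifest$pos[end_ord]
  data.frame(chrom = chrom, start_ord = start_ord, end_ord = end_ord,
             start_bp = start_bp, end_bp = end_bp,
             length_mbp = (end_bp - start_bp) / 1e6,
             n_snps = if (is.null(n_snps)) end_ord - start_ord + 1L else n_snps,
             informativity = informativity, purity = purity, source = source,
             stringsAsFactors = FALSE)
}

#' Maximal concordance runs between two profiles
#'
#' Scans each chromosome for maximal runs of consecutive concordant SNPs,
#' where a SNP is concordant when the pair shares at least one allele (i.e.
#' the genotypes are not opposite homozygotes). Loci missing in either
#' sample neither break nor extend a run: the run continues across them, and
#' they are not counted in `n_snps`. Runs with fewer than 2 counted SNPs are
#' discarded. These unfiltered "base" runs (IBS regions) are the input to
#' informativity calibration and to A1 filtering.
#'
#' @param geno_a,geno_b Integer dosage vectors aligned to `manifest`.
#' @param manifest A `panel_manifest`.
#' @return Segment data frame with `source = "base"`.
#' @export
concordance_runs <- function(geno_a, geno_b, manifest) {
  if (length(geno_a) != nrow(manifest) || length(geno_b) != nrow(manifest))
    stop_input("genotype vectors (%d, %d loci) do not match manifest (%d loci)",
               length(geno_a), length(geno_b), nrow(manifest))
  out <- lapply(unique(manifest$chrom), function(ci) {
    loc <- manifest_chrom_index(manifest, ci)
    a <- geno_a[loc]; b <- geno_b[loc]
    valid <- which(!is.na(a) & !is.na(b))
    if (length(valid) < 2) return(NULL)
    conc <- is_concordant(a[valid], b[valid])
    r <- rle(conc)
    ends_v <- cumsum(r$lengths)
    starts_v <- ends_v - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L
    if (!any(keep)) return(NULL)
    make_segments(chrom = rep(ci, sum(keep)),
                  start_ord = loc[valid[starts_v[keep]]],
                  end_ord = loc[valid[ends_v[keep]]],
                  manifest = manifest,
                  n_snps = r$lengths[keep],
                  source = "base")
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- empty_segments()
  rownames(out) <- NULL
  out
}

#' SNP informativity map
#'
#' Calibrates the per-SNP informativity used by the A1 filter from the base
#' concordance runs of a reference pair set: Ic(i) is the number of runs
#' whose ordinal span contains SNP i, med(Ic) the median IBS count over SNPs
#' appearing in at least one run, and the informativity of SNP i is
#' MI(i) = med(Ic) / Ic(i). SNPs never covered by a run contribute 0 to
#' segment informativity sums.
#'
#' @param runs Segment data frame of base runs pooled over all reference
#'   pairs (see [concordance_runs()]).
#' @param manifest A `panel_manifest`.
#' @return An `informativity_map`: list with `ic`, `mi` (per-manifest-SNP
#'   vectors) and `med_ic`.
#' @export
snp_informativity <- function(runs, manifest) {
  if (!nrow(runs))
    stop_input("cannot calibrate informativity: no runs supplied")
  L <- nrow(manifest)
  delta <- numeric(L + 1L)
  tab_s <- tabulate(runs$start_ord, nbins = L)
  tab_e <- tabulate(runs$end_ord + 1L, nbins = L + 1L)
  delta[seq_len(L)] <- tab_s
  delta <- delta - tab_e
  ic <- cumsum(delta[seq_len(L)])
  covered <- ic >= 1
  med_ic <- stats::median(ic[covered])
  mi <- numeric(L)
  mi[covered] <- med_ic / ic[covered]
  structure(list(ic = as.integer(ic), mi = mi, med_ic = med_ic),
            class = "informativity_map")
}

#' Segment informativity
#'
#' Sum of per-SNP informativity MI over the manifest SNPs inside a segment's
#' ordinal span (loci with zero IBS count contribute nothing). Vectorised
#' over the rows of `segments`.
#'
#' @param segments Segment data frame.
#' @param info An `informativity_map`.
#' @return Numeric vector of informativity values Is, one per segment.
#' @export
segment_informativity <- function(segments, info) {
  if (!nrow(segments)) return(numeric(0))
  cs <- c(0, cumsum(info$mi))
  cs[segments$end_ord + 1L] - cs[segments$start_ord]
}

#' Trim segments against masked regions
#'
#' Subtracts masked intervals from each segment's physical span; every
#' remnant is re-anchored to its outermost contained SNPs and kept only if
#' it is still strictly longer than `cfg$min_len_mbp` and its informativity
#' is strictly above `cfg$min_informativity`. Segments not overlapping any
#' mask pass through unchanged.
#'
#' @param segments Segment data frame.
#' @param masks Mask intervals (`chrom, start, end`, 0-based half-open), or
#'   `NULL`/empty for no masking.
#' @param info An `informativity_map`.
#' @param manifest A `panel_manifest`.
#' @param cfg A `detector_config`.
#' @return Segment data frame of surviving (possibly trimmed) segments.
#' @export
mask_trim <- function(segments, masks, info, manifest, cfg) {
  if (!nrow(segments)) return(segments)
  if (is.null(masks) || !nrow(masks)) return(segments)
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    m <- masks[masks$chrom == seg$chrom, , drop = FALSE]
    if (!nrow(m)) { out[[i]] <- seg; next }
    seg_ir <- IRanges::IRanges(start = seg$start_bp, end = seg$end_bp)
    mask_ir <- IRanges::IRanges(start = m$start + 1, end = m$end)
    remn <- IRanges::setdiff(seg_ir, mask_ir)
    if (identical(length(remn), 1L) &&
        IRanges::start(remn) == seg$start_bp && IRanges::end(remn) == seg$end_bp) {
      out[[i]] <- seg
      next
    }
    if (!length(remn)) next
    pos <- manifest$pos
    loc <- seq(seg$start_ord, seg$end_ord)
    pieces <- lapply(seq_along(remn), function(k) {
      lo <- IRanges::start(remn)[k]; hi <- IRanges::end(remn)[k]
      inside <- loc[pos[loc] >= lo & pos[loc] <= hi]
      if (length(inside) < 2) return(NULL)
      make_segments(seg$chrom, inside[1], inside[length(inside)], manifest,
                    source = seg$source)
    })
    pieces <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (is.null(pieces) || !nrow(pieces)) next
    pieces$informativity <- segment_informativity(pieces, info)
    keep <- pieces$length_mbp > cfg$min_len_mbp &
      pieces$informativity > cfg$min_informativity
    out[[i]] <- pieces[keep, , drop = FALSE]
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_segments())
  rownames(out) <- NULL
  out
}

#' IBD detection, algorithm A1 (concordance runs + informativity filter)
#'
#' Runs the base concordance scan, removes runs shorter than
#' `cfg$min_len_mbp`, removes runs whose informativity is not strictly above
#' `cfg$min_informativity`, then trims survivors against `cfg$masks`
#' (re-applying both thresholds to the trimmed remnants).
#'
#' @param geno_a,geno_b Integer dosage vectors aligned to `manifest`.
#' @param manifest A `panel_manifest`.
#' @param info An `informativity_map` calibrated from the reference set.
#' @param cfg A `detector_config`.
#' @return Segment data frame with `source = "A1"` and informativity
#'   attached.
#' @export
detect_a1 <- function(geno_a, geno_b, manifest, info, cfg = detector_config()) {
  runs <- concordance_runs(geno_a, geno_b, manifest)
  if (!nrow(runs)) return(empty_segments())
  runs <- runs[runs$length_mbp >= cfg$min_len_mbp, , drop = FALSE]
  if (nrow(runs)) {
    runs$informativity <- segment_informativity(runs, info)
    runs <- runs[runs$informativity > cfg$min_informativity, , drop = FALSE]
  }
  runs <- mask_trim(runs, cfg$masks, info, manifest, cfg)
  if (nrow(runs)) runs$source <- "A1"
  rownames(runs) <- NULL
  runs
}

#' Windowed kinship-coefficient scan (A2, stage 1)
#'
#' Slides a window of `cfg$window_len` SNPs along each chromosome (one
#' window per starting ordinal; a chromosome with fewer SNPs than the window
#' yields a single window spanning all of them), computes the robust kinship
#' coefficient restricted to the window's non-missing loci, and returns the
#' windows whose coefficient is strictly greater than
#' `cfg$window_phi_threshold`. Windows with no usable heterozygous locus for
#' the higher-heterozygosity sample are skipped.
#'
#' @param geno_a,geno_b Integer dosage vectors aligned to `manifest`.
#' @param manifest A `panel_manifest`.
#' @param cfg A `detector_config`.
#' @return Data frame `chrom, start_ord, end_ord, phi` of stored windows.
#' @export
window_scan <- function(geno_a, geno_b, manifest, cfg = detector_config()) {
  L <- cfg$window_len
  out <- lapply(unique(manifest$chrom), function(ci) {
    loc <- manifest_chrom_index(manifest, ci)
    a <- geno_a[loc]; b <- geno_b[loc]
    n <- length(loc)
    valid <- !is.na(a) & !is.na(b)
    both_het <- valid & a == 1L & b == 1L
    opp <- valid & abs(a - b) == 2L
    het_a <- valid & a == 1L
    het_b <- valid & b == 1L
    if (n <= L) {
      starts <- 1L; ends <- n
    } else {
      starts <- seq_len(n - L + 1L); ends <- starts + L - 1L
    }
    cs <- function(x) c(0, cumsum(x))
    c_bh <- cs(both_het); c_opp <- cs(opp); c_ha <- cs(het_a); c_hb <- cs(het_b)
    w_bh <- c_bh[ends + 1L] - c_bh[starts]
    w_opp <- c_opp[ends + 1L] - c_opp[starts]
    w_ha <- c_ha[ends + 1L] - c_ha[starts]
    w_hb <- c_hb[ends + 1L] - c_hb[starts]
    n_i <- pmax(w_ha, w_hb)
    n_j <- pmin(w_ha, w_hb)
    usable <- n_i > 0
    phi <- rep(NA_real_, length(starts))
    phi[usable] <- (w_bh[usable] - 2 * w_opp[usable]) / (2 * n_i[usable]) +
      0.5 - (n_i[usable] + n_j[usable]) / (4 * n_i[usable])
    keep <- usable & phi > cfg$window_phi_threshold
    if (!any(keep)) return(NULL)
    data.frame(chrom = ci, start_ord = loc[starts[keep]],
               end_ord = loc[ends[keep]], phi = phi[keep])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = integer(), start_ord = integer(),
                      end_ord = integer(), phi = numeric())
  rownames(out) <- NULL
  out
}

#' IBD detection, algorithm A2 (windowed scan + merge + purity filter)
#'
#' Merges overlapping stored windows from [window_scan()] into candidate
#' segments (bounds anchored at the terminal SNPs), computes each segment's
#' sharing purity p -- the fraction of non-missing in-segment loci at which
#' the pair shares at least one allele -- and removes segments with
#' p < `cfg$min_purity`.
#'
#' @inheritParams window_scan
#' @return Segment data frame with `source = "A2"` and purity attached.
#' @export
detect_a2 <- function(geno_a, geno_b, manifest, cfg = detector_config()) {
  win <- window_scan(geno_a, geno_b, manifest, cfg)
  if (!nrow(win)) return(empty_segments())
  merged <- lapply(unique(win$chrom), function(ci) {
    w <- win[win$chrom == ci, , drop = FALSE]
    w <- w[order(w$start_ord), , drop = FALSE]
    grp <- cumsum(c(TRUE, w$start_ord[-1] > cummax(w$end_ord)[-nrow(w)]))
    data.frame(chrom = ci,
               start_ord = tapply(w$start_ord, grp, min),
               end_ord = tapply(w$end_ord, grp, max))
  })
  merged <- do.call(rbind, merged)
  segs <- make_segments(merged$chrom, merged$start_ord, merged$end_ord,
                        manifest, source = "A2")
  valid <- !is.na(geno_a) & !is.na(geno_b)
  conc <- valid & is_concordant(geno_a, geno_b)
  conc[is.na(conc)] <- FALSE
  c_val <- c(0, cumsum(valid)); c_conc <- c(0, cumsum(conc))
  n_val <- c_val[segs$end_ord + 1L] - c_val[segs$start_ord]
  n_conc <- c_conc[segs$end_ord + 1L] - c_conc[segs$start_ord]
  segs$purity <- ifelse(n_val > 0, n_conc / n_val, 0)
  segs <- segs[segs$purity >= cfg$min_purity, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}
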