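# IBD segment detection: concordance runs, informativity, mask trimming,
# and the windowed kinship-coefficient scan.

test_that("concordance runs split exactly at opposite homozygotes", {
  man <- toy_manifest(10)        # SNPs at 1..10 Mbp
  a <- rep(1L, 10)
  b <- rep(1L, 10)
  a[5] <- 0L; b[5] <- 2L          # opposite homozygotes at SNP 5
  runs <- concordance_runs(a, b, man)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$start_ord, c(1L, 6L))
  expect_equal(runs$end_ord, c(4L, 10L))
  expect_equal(runs$length_mbp, c(3, 4))
  expect_equal(runs$n_snps, c(4L, 5L))
})

test_that("identical profiles give one chromosome-spanning run; full discordance none", {
  man <- toy_manifest_multi(8, 1:3)
  g <- rep(c(0L, 1L, 2L), length.out = 24)
  runs <- concordance_runs(g, g, man)
  expect_equal(nrow(runs), 3)
  expect_equal(runs$n_snps, rep(8L, 3))
  expect_equal(runs$start_ord, c(1L, 9L, 17L))
  opp <- ifelse(g == 0L, 2L, ifelse(g == 2L, 0L, 1L))
  opp_all <- rep(c(0L, 2L), length.out = 24)
  none <- concordance_runs(opp_all, 2L - opp_all, man)
  expect_equal(nrow(none), 0)
  expect_error(concordance_runs(g[-1], g, man), "do not match manifest")
})

test_that("missing genotypes neither break runs nor count as SNPs", {
  man <- toy_manifest(10)
  a <- rep(2L, 10); b <- rep(2L, 10)
  a[4] <- NA; b[7] <- NA
  runs <- concordance_runs(a, b, man)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start_ord, 1L)
  expect_equal(runs$end_ord, 10L)
  expect_equal(runs$n_snps, 8L)   # two loci missing
})

test_that("informativity follows MI = med(Ic)/Ic", {
  man <- toy_manifest(4)
  runs <- data.frame(start_ord = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 4L),
                     end_ord   = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L))
  info <- snp_informativity(runs, man)
  expect_equal(info$ic, c(2L, 4L, 4L, 8L))
  expect_equal(info$med_ic, 4)
  expect_equal(info$mi, c(2, 1, 1, 0.5))
  # all-equal counts give MI = 1 everywhere
  runs2 <- data.frame(start_ord = rep(1L, 3), end_ord = rep(4L, 3))
  expect_equal(snp_informativity(runs2, man)$mi, rep(1, 4))
  expect_error(snp_informativity(runs[0, ], man), "no runs")
})

test_that("segment informativity sums MI over the ordinal span", {
  man <- toy_manifest(3)
  info <- flat_info(man)
  info$mi <- c(1, 0.5, 2)
  seg <- kinsnp:::make_segments(1L, 1L, 3L, man)
  expect_equal(segment_informativity(seg, info), 3.5)
  expect_equal(segment_informativity(kinsnp:::empty_segments(), info), numeric(0))
  # 100 SNPs at MI = 1 sum to 100 (passes the >50 informativity filter)
  man2 <- toy_manifest(100)
  expect_equal(segment_informativity(kinsnp:::make_segments(1L, 1L, 100L, man2),
                                     flat_info(man2)), 100)
})

test_that("mask trimming drops short remnants and keeps informative ones", {
  man <- toy_manifest(40)        # SNPs at 1..40 Mbp
  cfg <- detector_config()
  info <- flat_info(man, mi = 10)     # informativity never the binding filter
  seg <- kinsnp:::make_segments(1L, 20L, 40L, man)  # 20-40 Mbp
  mask <- data.frame(chrom = 1, start = 28e6, end = 32e6)
  out <- mask_trim(seg, mask, info, man, cfg)
  expect_equal(nrow(out), 0)     # 8 Mbp + 8 Mbp remnants, both < 10 Mbp
  seg2 <- kinsnp:::make_segments(1L, 10L, 40L, man)  # 10-40 Mbp
  mask2 <- data.frame(chrom = 1, start = 28e6, end = 30e6)
  out2 <- mask_trim(seg2, mask2, info, man, cfg)
  # remnants 10-28 (18 Mbp, kept) and 30-40 (10 Mbp, dropped: strictly > 10)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$start_bp, 10e6)
  expect_equal(out2$end_bp, 28e6)
  # low informativity kills the surviving remnant too
  out3 <- mask_trim(seg2, mask2, flat_info(man, mi = 1), man, cfg)
  expect_equal(nrow(out3), 0)    # Is = 19 < 50
  # no overlap: unchanged
  far <- data.frame(chrom = 1, start = 60e6, end = 70e6)
  expect_equal(mask_trim(seg2, far, info, man, cfg), seg2)
  expect_equal(mask_trim(seg2, NULL, info, man, cfg), seg2)
})

test_that("A1 composes the length, informativity and mask filters", {
  man <- toy_manifest(60)
  cfg <- detector_config()
  # run of SNPs 1..9 (8 Mbp) then discordance, run 11..23 (12 Mbp), ...
  a <- rep(1L, 60); b <- rep(1L, 60)
  a[10] <- 0L; b[10] <- 2L
  a[24] <- 2L; b[24] <- 0L
  a[36] <- 0L; b[36] <- 2L       # run 25..35 (10 Mbp), run 37..60 (23 Mbp)
  info_hi <- flat_info(man, mi = 6)   # every run comfortably informative
  segs <- detect_a1(a, b, man, info_hi, cfg)
  # 8 Mbp run removed; 12, 10 and 23 Mbp runs kept (length filter is >= 10)
  expect_equal(segs$start_ord, c(11L, 25L, 37L))
  expect_true(all(segs$source == "A1"))
  # informativity threshold: MI such that the 12 Mbp run scores Is = 39 <= 50
  info_lo <- flat_info(man, mi = 3)
  segs_lo <- detect_a1(a, b, man, info_lo, cfg)
  expect_false(11L %in% segs_lo$start_ord)
  # 23 Mbp run scores 24 * 3 = 72 > 50 and stays
  expect_true(37L %in% segs_lo$start_ord)
})

test_that("window scan counts windows, scores identity at 0.5 and merges", {
  man <- toy_manifest(100, spacing_mbp = 0.3)
  cfg <- detector_config()
  g <- rep(c(0L, 1L, 2L, 1L), 25)
  win <- window_scan(g, g, man, cfg)
  expect_equal(nrow(win), 100 - 80 + 1)   # n - L + 1 windows, all stored
  expect_true(all(abs(win$phi - 0.5) < 1e-12))
  segs <- detect_a2(g, g, man, cfg)
  expect_equal(nrow(segs), 1)             # overlapping windows merge
  expect_equal(segs$start_ord, 1L)
  expect_equal(segs$end_ord, 100L)
  expect_equal(segs$purity, 1)
  expect_equal(segs$source, "A2")
  # chromosome shorter than the window yields a single whole-chromosome window
  man_short <- toy_manifest(50)
  win_short <- window_scan(g[1:50], g[1:50], man_short, cfg)
  expect_equal(nrow(win_short), 1)
  expect_equal(win_short$end_ord, 50L)
})

test_that("A2 purity filter removes segments sharing below threshold", {
  man <- toy_manifest(100, spacing_mbp = 0.3)
  cfg <- detector_config()
  g <- rep(c(0L, 1L, 2L, 1L), 25)
  h <- g
  h[seq(5, 33, by = 4)] <- 2L - g[seq(5, 33, by = 4)]  # 8 opposite homozygotes
  segs <- detect_a2(g, h, man, cfg)
  if (nrow(segs)) expect_true(all(segs$purity >= 0.95))
  # identical profiles never lose purity
  expect_equal(detect_a2(g, g, man, cfg)$purity, 1)
})

test_that("detected segments are sorted, disjoint and deterministic", {
  man <- fixture_panel()
  map <- fixture_map()
  spec <- relationship_catalogue()[["full-siblings"]]
  f <- simulate_founders(man, length(spec$founders), seed = 31)
  d <- gene_drop_pair(spec, f, map, man, seed = 32)
  cfg <- detector_config()
  info <- snp_informativity(concordance_runs(d$genotypes[1, ], d$genotypes[2, ], man), man)
  for (detect in list(
    function() detect_a1(d$genotypes[1, ], d$genotypes[2, ], man, info, cfg),
    function() detect_a2(d$genotypes[1, ], d$genotypes[2, ], man, cfg))) {
    s1 <- detect(); s2 <- detect()
    expect_identical(s1, s2)
    expect_gt(nrow(s1), 0)
    by_chrom <- split(s1, s1$chrom)
    for (sc in by_chrom) {
      expect_true(all(diff(sc$start_ord) > 0))
      if (nrow(sc) > 1)
        expect_true(all(sc$start_ord[-1] > sc$end_ord[-nrow(sc)]))
    }
    expect_true(all(s1$n_snps >= 2))
    expect_true(all(s1$length_mbp > 0))
  }
})

test_that("A1 on identical profiles recovers nearly the whole panel span", {
  man <- fixture_panel()
  f <- simulate_founders(man, 1, seed = 41)
  g <- f[1, ]
  runs <- concordance_runs(g, g, man)
  info <- snp_informativity(runs, man)
  segs <- detect_a1(g, g, man, info, detector_config())
  covered <- sum(segs$length_mbp)
  expect_gte(covered / genome_span_mbp(man), 0.95)
})
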