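# Shared fixtures for the test suite. Everything is generated in code.

# A tiny hand-laid manifest: `n` SNPs on one chromosome at 1, 2, ... n Mbp,
# all alt_freq 0.5.
toy_manifest <- function(n = 10, chrom = 1, freq = 0.5, spacing_mbp = 1) {
  df <- data.frame(chrom = chrom,
                   pos = seq_len(n) * spacing_mbp * 1e6,
                   id = sprintf("snp%02d_c%d", seq_len(n), chrom),
                   ref = "A", alt = "G",
                   category = "kiSNP",
                   alt_freq = freq,
                   stringsAsFactors = FALSE)
  kinsnp:::validate_panel_manifest(df)
}

# Manifest spanning several chromosomes, n SNPs each.
toy_manifest_multi <- function(n_per_chrom = 10, chroms = 1:2, freq = 0.5) {
  df <- do.call(rbind, lapply(chroms, function(ci)
    as.data.frame(toy_manifest(n_per_chrom, chrom = ci, freq = freq))))
  kinsnp:::validate_panel_manifest(df)
}

write_manifest_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# An informativity map with every SNP at a constant MI (Is == mi * n_snps).
flat_info <- function(manifest, mi = 1) {
  structure(list(ic = rep(1L, nrow(manifest)),
                 mi = rep(mi, nrow(manifest)),
                 med_ic = 1),
            class = "informativity_map")
}

# Cache heavyweight simulated objects across test files within one run.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) assign(key, expr, envir = .test_cache)
  get(key, envir = .test_cache)
}

# The standard 10,030-SNP fixture panel and its uniform map.
fixture_panel <- function() cached("panel", generate_panel_fixture(10030, 22, seed = 1))
fixture_map <- function() cached("map", uniform_genetic_map(fixture_panel()))

# Scaled-down end-to-end benchmark shared by the acceptance tests:
# 18 related types + unrelated, 20 reference + 20 test pairs per type,
# 10^-3 noise, both detectors, all retained methods plus gamma.
fixture_benchmark <- function() {
  cached("benchmark",
         run_benchmark(manifest = fixture_panel(), map = fixture_map(),
                       pairs_per_type = 40, split = 0.5,
                       noise = noise_config(1e-3, 1e-3),
                       include_gamma = TRUE, seed = 1))
}
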