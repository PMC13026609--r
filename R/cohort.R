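# Cohort simulation: per relationship type, simulate pairs, add genotyping
# noise, and split into reference (model calibration) and test halves.

#' Noise configuration
#'
#' Per-SNP missingness and genotype error rates applied independently to
#' every genotype call. Defaults are 10^-3 for both, the conventional
#' simulation setting for medium-density forensic panels.
#'
#' @param missing_rate Probability a call is dropped to missing.
#' @param error_rate Probability a (non-missing) call is replaced by one of
#'   the other two dosage codes, uniformly.
#' @param seed Optional integer seed used when the config is applied.
#' @return A `noise_config` list.
#' @export
noise_config <- function(missing_rate = 1e-3, error_rate = 1e-3, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, error_rate >= 0, error_rate <= 1)
  structure(list(missing_rate = missing_rate, error_rate = error_rate, seed = seed),
            class = "noise_config")
}

#' Inject missingness and genotype error
#'
#' Independently per cell: with probability `missing_rate` the call becomes
#' missing; otherwise with probability `error_rate` the dosage is replaced by
#' one of the other two codes chosen uniformly (an error never reproduces
#' the original code). Deterministic under the seed.
#'
#' @param codes Integer genotype matrix (or vector).
#' @param cfg A `noise_config`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return Matrix of the same shape.
#' @export
inject_noise <- function(codes, cfg, seed = cfg$seed) {
  with_seed(seed, {
    n <- length(codes)
    u <- stats::runif(n)
    miss <- u < cfg$missing_rate
    err <- !miss & u < cfg$missing_rate + cfg$error_rate & !is.na(codes)
    if (any(err)) {
      shift <- sample(1:2, sum(err), replace = TRUE)
      codes[err] <- (codes[err] + shift) %% 3L
    }
    codes[miss] <- NA_integer_
    codes
  })
}

#' Simulate a reference/test cohort of sample pairs
#'
#' For every relationship in `catalogue`, simulates `pairs_per_type`
#' independent pairs by gene dropping (unrelated pairs are two independent
#' HWE founders), injects genotyping noise, and splits each type into
#' reference and test sets by `split` (reference fraction). The truth table
#' records the relationship name and degree ordinal of every pair.
#'
#' @param catalogue List of `relationship_spec` (see
#'   [relationship_catalogue()]).
#' @param pairs_per_type Number of pairs per relationship type (>= 2).
#' @param split Reference fraction in (0, 1); default 0.5.
#' @param manifest A `panel_manifest`.
#' @param map A `genetic_map`.
#' @param noise A `noise_config` (use rates 0 for error-free pairs).
#' @param seed Integer seed.
#' @return List with `pairs` (data frame `pair_id, sample_a, sample_b,
#'   relationship, degree, role`), `genotypes` (samples x loci integer
#'   matrix), and `true_ibd` (named list of per-pair IBD data frames).
#' @export
simulate_cohort <- function(catalogue, pairs_per_type, split = 0.5, manifest,
                            map, noise = noise_config(), seed = 1) {
  stopifnot(pairs_per_type >= 2, split > 0, split < 1)
  n_ref <- max(1L, round(pairs_per_type * split))
  if (n_ref >= pairs_per_type) n_ref <- pairs_per_type - 1L
  n_total <- length(catalogue) * pairs_per_type
  seeds <- derive_seeds(seed, 2L * n_total + 1L)
  noise_seed <- seeds[length(seeds)]
  pair_rows <- list()
  geno_rows <- list()
  true_ibd <- list()
  s <- 0L
  for (spec in catalogue) {
    for (j in seq_len(pairs_per_type)) {
      s <- s + 1L
      pair_id <- sprintf("%s_%03d", spec$name, j)
      founders <- simulate_founders(manifest, length(spec$founders),
                                    seed = seeds[2L * s - 1L])
      drop <- gene_drop_pair(spec, founders, map, manifest,
                             seed = seeds[2L * s])
      g <- drop$genotypes
      rownames(g) <- paste0(pair_id, c("_a", "_b"))
      pair_rows[[s]] <- data.frame(
        pair_id = pair_id,
        sample_a = rownames(g)[1], sample_b = rownames(g)[2],
        relationship = spec$name, degree = spec$degree,
        role = if (j <= n_ref) "reference" else "test",
        stringsAsFactors = FALSE)
      geno_rows[[s]] <- g
      true_ibd[[pair_id]] <- drop$ibd
    }
  }
  genotypes <- do.call(rbind, geno_rows)
  genotypes <- inject_noise(genotypes, noise, seed = noise_seed)
  list(pairs = do.call(rbind, pair_rows),
       genotypes = genotypes,
       true_ibd = true_ibd)
}

# Convenience: the two genotype vectors of one pair from a cohort.
cohort_pair_genotypes <- function(cohort, pair_id) {
  row <- cohort$pairs[cohort$pairs$pair_id == pair_id, ]
  if (!nrow(row)) stop_input("unknown pair id %s", pair_id)
  list(a = cohort$genotypes[row$sample_a, ],
       b = cohort$genotypes[row$sample_b, ])
}
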