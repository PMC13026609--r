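# End-to-end benchmark: simulate a cohort, calibrate reference models for
# both detectors, classify the test pairs with every method, and evaluate.

#' Run the full simulation benchmark
#'
#' Simulates a reference/test cohort over the relationship catalogue,
#' calibrates the SNP-informativity map and both detectors' reference
#' models on the reference half, runs A1 and A2 detection plus all
#' classifiers on the test half, and scores the results. The seven retained
#' algorithm-method combinations are `A1.mean_length`, `A1.conditional`,
#' `A1.ibd0`, `A2.mean_length`, `A2.conditional`, `A2.ibd0` and `king`;
#' `A1.gamma`/`A2.gamma` are added when `include_gamma = TRUE`.
#'
#' @param manifest A `panel_manifest` (default: the 10,030-SNP fixture).
#' @param map A `genetic_map` (default: uniform 1 cM/Mbp over the panel).
#' @param catalogue Relationship catalogue.
#' @param pairs_per_type Pairs per relationship type.
#' @param split Reference fraction.
#' @param noise A `noise_config`.
#' @param cfg A `detector_config`; if its `masks` is `NULL`, the panel's
#'   coverage-gap mask (5 Mbp threshold) is derived and used.
#' @param include_gamma Also run the gamma profile-distance classifier.
#' @param seed Integer seed driving the whole run.
#' @return List with `cohort`, `info` (informativity map), `models`
#'   (per detector), `segments` (per detector, named by pair id), `results`
#'   (all methods), `truth`, and `reports` / `reports_collapsed`
#'   (per-method `evaluation_report`s, without and with the >= 6th-degree
#'   unrelated collapse).
#' @export
run_benchmark <- function(manifest = generate_panel_fixture(seed = seed),
                          map = uniform_genetic_map(manifest),
                          catalogue = relationship_catalogue(),
                          pairs_per_type = 40, split = 0.5,
                          noise = noise_config(),
                          cfg = detector_config(),
                          include_gamma = FALSE,
                          seed = 1) {
  if (is.null(cfg$masks)) cfg$masks <- derive_gap_mask(manifest)
  genome_mbp <- genome_span_mbp(manifest)
  cohort <- simulate_cohort(catalogue, pairs_per_type, split, manifest, map,
                            noise, seed = seed)
  pairs <- cohort$pairs
  ref_ids <- pairs$pair_id[pairs$role == "reference"]
  test_ids <- pairs$pair_id[pairs$role == "test"]

  # --- calibration: base runs of the reference half -> informativity map
  base_runs <- lapply(ref_ids, function(pid) {
    g <- cohort_pair_genotypes(cohort, pid)
    concordance_runs(g$a, g$b, manifest)
  })
  info <- snp_informativity(do.call(rbind, base_runs), manifest)

  detect_with <- function(detector, ids) {
    segs <- lapply(ids, function(pid) {
      g <- cohort_pair_genotypes(cohort, pid)
      if (detector == "A1") detect_a1(g$a, g$b, manifest, info, cfg)
      else detect_a2(g$a, g$b, manifest, cfg)
    })
    names(segs) <- ids
    segs
  }

  models <- list()
  segments <- list()
  for (detector in c("A1", "A2")) {
    ref_segs <- detect_with(detector, ref_ids)
    test_segs <- detect_with(detector, test_ids)
    rel <- pairs$relationship[match(ref_ids, pairs$pair_id)]
    deg <- pairs$degree[match(ref_ids, pairs$pair_id)]
    models[[detector]] <- build_reference_model(
      ref_segs, rel, deg, info = if (detector == "A1") info else NULL,
      cfg = cfg, genome_mbp = genome_mbp)
    segments[[detector]] <- list(reference = ref_segs, test = test_segs)
  }

  # --- classify test pairs
  res_rows <- list()
  for (detector in c("A1", "A2")) {
    model <- models[[detector]]
    for (pid in test_ids) {
      segs <- segments[[detector]]$test[[pid]]
      total <- total_shared_length(segs)
      rows <- list(classify_mean_length(total, model),
                   classify_conditional(total, model),
                   ibd0_classify(total, genome_mbp))
      if (include_gamma) rows <- c(rows, list(classify_gamma(segs, model)))
      rows <- do.call(rbind, rows)
      rows$method <- paste(detector, rows$method, sep = ".")
      rows$pair_id <- pid
      res_rows[[length(res_rows) + 1L]] <- rows
    }
  }
  for (pid in test_ids) {
    g <- cohort_pair_genotypes(cohort, pid)
    row <- king_classify(king_phi(g$a, g$b)$phi)
    row$pair_id <- pid
    res_rows[[length(res_rows) + 1L]] <- row
  }
  results <- do.call(rbind, res_rows)
  results <- results[, c("pair_id", "method", "inferred_class", "degree",
                         "score", "abstained")]
  rownames(results) <- NULL

  truth <- pairs[pairs$role == "test", c("pair_id", "relationship", "degree")]
  methods <- unique(results$method)
  reports <- lapply(methods, function(m)
    evaluation_report(results[results$method == m, ], truth))
  reports_collapsed <- lapply(methods, function(m)
    evaluation_report(results[results$method == m, ], truth, collapse = TRUE))
  names(reports) <- names(reports_collapsed) <- methods

  list(cohort = cohort, info = info, models = models, segments = segments,
       results = results, truth = truth, reports = reports,
       reports_collapsed = reports_collapsed, genome_mbp = genome_mbp,
       seed = seed)
}

#' Accuracy of every method at one true degree
#'
#' Convenience accessor over a [run_benchmark()] result: per method, the
#' accuracy at the given true degree (optionally after the unrelated
#' collapse).
#'
#' @param bench A [run_benchmark()] result.
#' @param degree True degree ordinal (10 = unrelated).
#' @param collapsed Use the collapsed reports.
#' @return Named numeric vector of accuracies (proportions).
#' @export
benchmark_degree_accuracy <- function(bench, degree, collapsed = FALSE) {
  reports <- if (collapsed) bench$reports_collapsed else bench$reports
  vapply(reports, function(r) {
    acc <- r$accuracy
    i <- match(degree, acc$degree)
    if (is.na(i)) NA_real_ else acc$accuracy[i]
  }, numeric(1))
}
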