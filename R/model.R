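# Per-relationship reference models calibrated from the reference pair set:
# mean total segment lengths, pooled gamma segment-length fits, and the
# conditional-probability table of relationship given total sharing.

#' Total shared segment length
#'
#' @param segments Segment data frame for one pair.
#' @return Sum of segment lengths in Mbp (0 for none).
#' @export
total_shared_length <- function(segments) {
  if (is.null(segments) || !nrow(segments)) return(0)
  sum(segments$length_mbp)
}

COND_BIN_WIDTH <- 50
COND_MAX_MBP <- 3000

# Bin index of a total length over [0,50), [50,100), ..., [2950,3000);
# totals at or beyond the top edge clamp into the last bin.
cond_bin_of <- function(total) {
  pmin(pmax(floor(total / COND_BIN_WIDTH), 0) + 1L,
       as.integer(COND_MAX_MBP / COND_BIN_WIDTH))
}

#' Build a reference model from detected reference segments
#'
#' Calibrates the classifier reference quantities from the per-pair segment
#' sets of the reference cohort: mean total shared length MS per
#' relationship; a gamma fit to the pooled segment lengths of each
#' relationship; and the conditional-probability table P(relationship |
#' total-sharing bin) over 50 Mbp bins spanning 0-3000 Mbp. Relationships
#' with no detected segments keep MS = 0 and no gamma fit.
#'
#' @param pair_segments Named list: per reference pair, its segment data
#'   frame.
#' @param relationships Character vector parallel to `pair_segments`: the
#'   true relationship name of each pair.
#' @param degrees Integer vector parallel to `pair_segments`: true degree
#'   ordinals (10 = unrelated).
#' @param info Optional `informativity_map` used by the detector (stored for
#'   provenance/serialisation).
#' @param cfg Optional `detector_config` (stored).
#' @param genome_mbp Genome span in Mbp used by the IBD0 classifier.
#' @return A `reference_model`.
#' @export
build_reference_model <- function(pair_segments, relationships, degrees,
                                  info = NULL, cfg = NULL, genome_mbp = NULL) {
  stopifnot(length(pair_segments) == length(relationships),
            length(pair_segments) == length(degrees))
  totals <- vapply(pair_segments, total_shared_length, numeric(1))
  rel_names <- unique(relationships)
  degree_of <- vapply(rel_names, function(r)
    as.integer(degrees[match(r, relationships)]), integer(1))
  ms <- vapply(rel_names, function(r) mean(totals[relationships == r]), numeric(1))
  gamma_fits <- lapply(rel_names, function(r) {
    lens <- unlist(lapply(pair_segments[relationships == r],
                          function(s) s$length_mbp), use.names = FALSE)
    fit_gamma(lens)
  })
  names(gamma_fits) <- rel_names
  n_miss <- sum(vapply(gamma_fits, is.null, logical(1)))
  if (n_miss > 0)
    message(sprintf("gamma fit unavailable for %d relationship(s) (fewer than two segments)", n_miss))
  n_bins <- as.integer(COND_MAX_MBP / COND_BIN_WIDTH)
  counts <- matrix(0L, nrow = n_bins, ncol = length(rel_names),
                   dimnames = list(NULL, rel_names))
  bins <- cond_bin_of(totals)
  for (k in seq_along(totals))
    counts[bins[k], relationships[k]] <- counts[bins[k], relationships[k]] + 1L
  bin_tot <- rowSums(counts)
  probs <- counts / ifelse(bin_tot > 0, bin_tot, 1)
  structure(list(
    relationships = rel_names,
    degree_of = stats::setNames(degree_of, rel_names),
    ms = stats::setNames(ms, rel_names),
    gamma = gamma_fits,
    cond_counts = counts,
    cond_probs = probs,
    cond_edges = seq(0, COND_MAX_MBP, by = COND_BIN_WIDTH),
    info = info,
    cfg = cfg,
    genome_mbp = genome_mbp,
    king = king_ranges(),
    ibd0 = ibd0_ranges()),
    class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %d relationships; MS range %.1f-%.1f Mbp; %d/%d gamma fits; genome %.0f Mbp\n",
              length(x$relationships), min(x$ms), max(x$ms),
              sum(!vapply(x$gamma, is.null, logical(1))), length(x$gamma),
              x$genome_mbp %||% NA))
  invisible(x)
}

# -- JSON serialisation -------------------------------------------------------

#' Serialise a reference model to JSON
#' @param model A `reference_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_model <- function(model, path) {
  obj <- list(
    relationships = model$relationships,
    degree_of = as.list(model$degree_of),
    ms = as.list(model$ms),
    gamma = lapply(model$gamma, function(g)
      if (is.null(g)) NULL else list(shape = g$shape, scale = g$scale)),
    cond_counts = as.data.frame(model$cond_counts),
    cond_edges = model$cond_edges,
    genome_mbp = model$genome_mbp,
    info = if (is.null(model$info)) NULL else
      list(ic = model$info$ic, mi = model$info$mi, med_ic = model$info$med_ic),
    cfg = if (is.null(model$cfg)) NULL else
      model$cfg[c("min_len_mbp", "min_informativity", "window_len",
                  "window_phi_threshold", "min_purity")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a reference model from JSON
#' @param path JSON path written by [write_reference_model()].
#' @return A `reference_model`.
#' @export
read_reference_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel <- obj$relationships
  # cond_counts serialised row-wise as a data frame (one column per type)
  counts <- as.matrix(obj$cond_counts[, rel, drop = FALSE])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, rel)
  bin_tot <- rowSums(counts)
  gamma_fits <- lapply(rel, function(r) {
    g <- obj$gamma[[r]]
    if (is.null(g) || is.null(g$shape)) NULL
    else structure(list(shape = g$shape, scale = g$scale), class = "gamma_params")
  })
  names(gamma_fits) <- rel
  info <- if (!is.null(obj$info))
    structure(list(ic = as.integer(obj$info$ic), mi = as.numeric(obj$info$mi),
                   med_ic = obj$info$med_ic), class = "informativity_map")
  cfg <- if (!is.null(obj$cfg))
    do.call(detector_config, obj$cfg)
  structure(list(
    relationships = rel,
    degree_of = stats::setNames(as.integer(unlist(obj$degree_of[rel])), rel),
    ms = stats::setNames(as.numeric(unlist(obj$ms[rel])), rel),
    gamma = gamma_fits,
    cond_counts = counts,
    cond_probs = counts / ifelse(bin_tot > 0, bin_tot, 1),
    cond_edges = as.numeric(obj$cond_edges),
    info = info,
    cfg = cfg,
    genome_mbp = obj$genome_mbp,
    king = king_ranges(),
    ibd0 = ibd0_ranges()),
    class = "reference_model")
}
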