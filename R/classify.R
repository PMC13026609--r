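# Kinship classifiers. Every classifier returns an inference-result row;
# abstentions are first-class results and score as incorrect in evaluation.
# All argmin/argmax ties resolve toward the higher degree ordinal (the more
# conservative claim of relatedness).

#' Inference result row
#'
#' @param method Method tag (e.g. `"mean_length"`, `"king"`).
#' @param inferred_class Inferred relationship label (or `NA` on
#'   abstention).
#' @param degree Inferred degree ordinal (1-9, 10 = unrelated, `NA` on
#'   abstention).
#' @param score Method score backing the call (distance, probability,
#'   coefficient, ...).
#' @param abstained Logical abstention flag.
#' @return One-row data frame
#'   `method, inferred_class, degree, score, abstained`.
#' @export
inference_result <- function(method, inferred_class, degree, score,
                             abstained = FALSE) {
  data.frame(method = method, inferred_class = inferred_class,
             degree = as.integer(degree), score = score,
             abstained = abstained, stringsAsFactors = FALSE)
}

# Pick index minimising `value`; ties resolve to the highest degree ordinal.
argmin_pref_distant <- function(value, degree) {
  best <- which(value == min(value))
  best[which.max(degree[best])]
}

#' Classify by nearest mean total segment length
#'
#' Infers the relationship whose reference mean total shared length MS is
#' closest (smallest absolute difference) to the pair's total shared length.
#'
#' @param total Pair's total shared segment length (Mbp).
#' @param model A `reference_model`.
#' @return Inference-result row (`method = "mean_length"`).
#' @export
classify_mean_length <- function(total, model) {
  d <- abs(total - model$ms)
  i <- argmin_pref_distant(d, model$degree_of)
  inference_result("mean_length", model$relationships[i],
                   model$degree_of[[i]], d[[i]])
}

#' Classify by conditional probability of relationship given total sharing
#'
#' Locates the 50 Mbp bin containing the pair's total shared length (totals
#' beyond the table clamp into the last bin) and infers the relationship
#' with the greatest conditional probability in that bin. An empty bin
#' falls back to the nearest populated bin (ties toward the lower bin).
#'
#' @inheritParams classify_mean_length
#' @return Inference-result row (`method = "conditional"`).
#' @export
classify_conditional <- function(total, model) {
  bin <- cond_bin_of(total)
  pop <- which(rowSums(model$cond_counts) > 0)
  if (!length(pop))
    return(inference_result("conditional", NA_character_, NA_integer_,
                            NA_real_, abstained = TRUE))
  if (!(bin %in% pop)) bin <- pop[which.min(abs(pop - bin))]  # lower on ties
  p <- model$cond_probs[bin, ]
  best <- which(p == max(p))
  i <- best[which.max(model$degree_of[best])]
  inference_result("conditional", model$relationships[i],
                   model$degree_of[[i]], p[[i]])
}

#' Classify by gamma segment-length profile distance
#'
#' Fits a gamma distribution to the pair's own segment lengths and infers
#' the relationship whose reference gamma profile has the smallest mean
#' absolute profile distance. Abstains when the pair shares fewer than two
#' segments (or the fit degenerates).
#'
#' @param segments The pair's segment data frame.
#' @param model A `reference_model`.
#' @param x_max Profile grid upper end (Mbp).
#' @return Inference-result row (`method = "gamma"`).
#' @export
classify_gamma <- function(segments, model, x_max = 150) {
  fit <- fit_gamma(segments$length_mbp)
  have <- !vapply(model$gamma, is.null, logical(1))
  if (is.null(fit) || !any(have))
    return(inference_result("gamma", NA_character_, NA_integer_, NA_real_,
                            abstained = TRUE))
  prof_p <- gamma_profile(fit, x_max)
  d <- vapply(model$relationships[have], function(r)
    gamma_distance(prof_p, gamma_profile(model$gamma[[r]], x_max)), numeric(1))
  deg <- model$degree_of[have]
  i <- argmin_pref_distant(d, deg)
  inference_result("gamma", names(d)[i], deg[[i]], d[[i]])
}

#' IBD0 inference ranges
#'
#' The expected proportion of the genome with zero IBD sharing and its
#' inference interval per class: parent-child expects 0 (interval
#' \[0, 0.1\]), siblings 0.25 ((0.1, 0.365\]), and degree d >= 2 expects
#' 1 - 2^(1-d) over (1 - 2^(-(2d-3)/2), 1 - 2^(-(2d-1)/2)\]; proportions
#' above 1 - 2^(-17/2) are unrelated. Upper bounds are inclusive and the
#' intervals tile \[0, 1\].
#'
#' @return Data frame `class, degree, expected, lower, upper`.
#' @export
ibd0_ranges <- function() {
  d <- 2:9
  data.frame(
    class = c("parent-child", "siblings", sprintf("degree-%d", d), "unrelated"),
    degree = c(1L, 1L, d, UNRELATED_ORDINAL),
    expected = c(0, 0.25, 1 - 2^(1 - d), 1),
    lower = c(-Inf, 0.1, 0.365, (1 - 2^(-(2 * d[-1] - 3) / 2)), 1 - 2^(-17 / 2)),
    upper = c(0.1, 0.365, (1 - 2^(-(2 * d - 1) / 2)), Inf))
}

#' Expected IBD0 proportion for a degree of kinship
#'
#' @param degree Degree ordinal (>= 1); parent-child is degree 1 with
#'   expectation 0 (the sibling expectation 0.25 is the degree-1
#'   special case tabulated in [ibd0_ranges()]).
#' @return 1 - 2^(1 - degree).
#' @export
ibd0_expected <- function(degree) {
  1 - 2^(1 - degree)
}

#' Classify by IBD0 proportion
#'
#' Computes the IBD0 proportion (genome length minus total shared length,
#' over genome length) and matches it to the unique inference interval of
#' [ibd0_ranges()] (upper bounds inclusive).
#'
#' @param total Pair's total shared segment length (Mbp).
#' @param genome_mbp Genome span (Mbp); defaults to the model's.
#' @param model A `reference_model` (used for `genome_mbp` default only).
#' @param ranges IBD0 range table.
#' @return Inference-result row (`method = "ibd0"`, score = the
#'   proportion).
#' @export
ibd0_classify <- function(total, genome_mbp = model$genome_mbp, model = NULL,
                          ranges = ibd0_ranges()) {
  if (is.null(genome_mbp))
    stop_input("ibd0_classify needs a genome length")
  if (total > genome_mbp)
    stop_input("total shared length %.1f exceeds genome length %.1f",
               total, genome_mbp)
  prop <- (genome_mbp - total) / genome_mbp
  hit <- which(prop > ranges$lower & prop <= ranges$upper)
  if (!length(hit)) hit <- 1L  # prop <= min bound: most-related class
  i <- hit[1]
  inference_result("ibd0", ranges$class[i], ranges$degree[i], prop)
}
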