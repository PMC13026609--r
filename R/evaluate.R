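# Scoring inference results against truth: degree-level accuracy, the
# unrelated-collapse rule, confusion matrices and margin-sweep ROC/AUROC.

# Results frames carry pair_id, method, inferred_class, degree, score,
# abstained; truth frames carry pair_id, relationship, degree.

#' Per-degree accuracy
#'
#' A call is correct when the inferred degree ordinal equals the true degree
#' ordinal (relationships within the same degree are interchangeable);
#' abstentions are incorrect.
#'
#' @param results Results data frame (one method).
#' @param truth Truth data frame.
#' @return Data frame `degree, n, n_correct, accuracy` sorted by degree
#'   (degree 10 = unrelated).
#' @export
degree_accuracy <- function(results, truth) {
  i <- match(results$pair_id, truth$pair_id)
  if (anyNA(i))
    stop_input("pair id %s has no truth row", results$pair_id[which(is.na(i))[1]])
  true_deg <- truth$degree[i]
  correct <- !results$abstained & !is.na(results$degree) &
    results$degree == true_deg
  agg <- tapply(correct, true_deg, function(x) c(n = length(x), k = sum(x)))
  degs <- as.integer(names(agg))
  n <- vapply(agg, `[[`, numeric(1), "n")
  k <- vapply(agg, `[[`, numeric(1), "k")
  out <- data.frame(degree = degs, n = as.integer(n), n_correct = as.integer(k),
                    accuracy = k / n)
  out[order(out$degree), ]
}

#' Collapse distant inferences to unrelated
#'
#' Applies the unrelated-collapse rule: every inference of degree
#' `cutoff_degree` or more distant is relabelled unrelated (ordinal 10).
#' Inferences below the cutoff, and abstentions, are unchanged.
#'
#' @param results Results data frame.
#' @param cutoff_degree Collapse threshold (default 6).
#' @return Modified results data frame.
#' @export
collapse_unrelated <- function(results, cutoff_degree = 6) {
  hit <- !results$abstained & !is.na(results$degree) &
    results$degree >= cutoff_degree
  results$degree[hit] <- UNRELATED_ORDINAL
  results$inferred_class[hit] <- "unrelated"
  results
}

#' Margin-sweep ROC and AUROC
#'
#' For each margin t in `margins`, a related pair counts as a true positive
#' when its inferred degree is within t of the true degree (abstentions
#' never match); an unrelated pair counts as a false positive when its
#' inferred ordinal is below 10 - t (i.e. not within t of unrelated). The
#' resulting (FPR, TPR) points, augmented with (0,0) and (1,1), give the
#' ROC; AUROC is the trapezoid area over FPR-sorted points.
#'
#' @param results Results data frame (one method).
#' @param truth Truth data frame (must contain related and unrelated
#'   pairs).
#' @param margins Integer margins (default 0:5).
#' @return List with `points` (data frame `margin, fpr, tpr`, including the
#'   augmentation rows with `NA` margin) and `auroc`.
#' @export
margin_roc <- function(results, truth, margins = 0:5) {
  i <- match(results$pair_id, truth$pair_id)
  if (anyNA(i))
    stop_input("pair id %s has no truth row", results$pair_id[which(is.na(i))[1]])
  true_deg <- truth$degree[i]
  related <- true_deg < UNRELATED_ORDINAL
  if (!any(related) || all(related))
    stop_input("margin ROC needs both related and unrelated pairs in truth")
  inf_deg <- results$degree
  inf_deg[results$abstained | is.na(inf_deg)] <- NA_integer_
  pts <- do.call(rbind, lapply(margins, function(t) {
    tpr <- mean(!is.na(inf_deg[related]) &
                  abs(inf_deg[related] - true_deg[related]) <= t)
    fpr <- mean(!is.na(inf_deg[!related]) &
                  inf_deg[!related] < UNRELATED_ORDINAL - t)
    data.frame(margin = t, fpr = fpr, tpr = tpr)
  }))
  pts <- rbind(data.frame(margin = NA, fpr = 0, tpr = 0),
               pts,
               data.frame(margin = NA, fpr = 1, tpr = 1))
  ord <- order(pts$fpr, pts$tpr)
  x <- pts$fpr[ord]; y <- pts$tpr[ord]
  auroc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  list(points = pts, auroc = auroc)
}

#' Full evaluation report
#'
#' Bundles per-degree accuracy, the confusion matrix (true degree x
#' inferred degree, abstentions in column `"abstain"`), margin-sweep ROC
#' and abstention counts for one method's results.
#'
#' @param results Results data frame (one method).
#' @param truth Truth data frame.
#' @param margins Margins for the ROC sweep.
#' @param collapse If `TRUE`, apply [collapse_unrelated()] first.
#' @param cutoff_degree Collapse threshold.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(results, truth, margins = 0:5,
                              collapse = FALSE, cutoff_degree = 6) {
  if (is.null(results) || !nrow(results))
    stop_input("empty results")
  if (collapse) results <- collapse_unrelated(results, cutoff_degree)
  i <- match(results$pair_id, truth$pair_id)
  true_deg <- truth$degree[i]
  inf_lab <- ifelse(results$abstained | is.na(results$degree), "abstain",
                    as.character(results$degree))
  confusion <- table(true = true_deg, inferred = inf_lab)
  roc <- margin_roc(results, truth, margins)
  structure(list(
    method = results$method[1],
    accuracy = degree_accuracy(results, truth),
    confusion = confusion,
    roc = roc$points,
    auroc = roc$auroc,
    n_abstained = sum(results$abstained)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> method %s; AUROC %.3f; %d abstentions\n",
              x$method, x$auroc, x$n_abstained))
  acc <- x$accuracy
  acc$degree <- ifelse(acc$degree >= UNRELATED_ORDINAL, "unrel", acc$degree)
  print(acc, row.names = FALSE)
  invisible(x)
}
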