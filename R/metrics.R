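# Confusion-count metrics, rank-based AUC, cascade aggregation.

#' Confusion-matrix metrics for a binary classifier
#'
#' Computes accuracy `(tp+tn)/(tp+tn+fp+fn)`, precision `tp/(tp+fp)`,
#' recall `tp/(tp+fn)`, specificity `tn/(tn+fp)`, negative predictive value
#' `tn/(tn+fn)` and F1 `2*precision*recall/(precision+recall)` from the
#' true/false positive/negative counts. A metric whose denominator is zero
#' is reported as `NA` (undefined, never coerced to 0) and named in the
#' `undefined` attribute.
#'
#' @param tp,tn,fp,fn Non-negative integer counts. Alternatively `tp` may be
#'   a one-row data frame/list with fields `tp`, `tn`, `fp`, `fn`.
#' @param scope Optional label (node name or `"cascade"`).
#' @return One-row tibble with the counts and the six metrics; attribute
#'   `undefined` lists metrics with zero denominators.
#' @export
#' @examples
#' binary_metrics(tp = 3, tn = 5, fp = 1, fn = 1)
binary_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL,
                           scope = NA_character_) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) {
    rlang::abort("All confusion counts are zero", class = "gait_schema_error")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  out <- tibble::tibble(
    scope = scope, tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    specificity = safe_div(tn, tn + fp),
    npv = safe_div(tn, tn + fn),
    f1 = f1
  )
  metric_cols <- c("accuracy", "precision", "recall", "specificity",
                   "npv", "f1")
  attr(out, "undefined") <- metric_cols[is.na(unlist(out[1, metric_cols]))]
  class(out) <- c("gait_metrics", class(out))
  out
}

#' Confusion counts from binary labels and thresholded scores
#'
#' @param labels 0/1 truth vector.
#' @param scores Predicted probabilities.
#' @param threshold Decision cut-off (class 1 iff `score >= threshold`).
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1 & labels == 1),
       tn = sum(pred == 0 & labels == 0),
       fp = sum(pred == 1 & labels == 0),
       fn = sum(pred == 0 & labels == 1))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half. Equivalent to
#' pairwise comparison of every positive/negative score pair.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores Numeric scores (higher = more class 1).
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class is
#'   present.
#' @export
#' @examples
#' auc_score(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::warn("AUC undefined: only one class present",
                class = "gait_degenerate_metric")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report for one binary model
#'
#' @param labels 0/1 truth vector.
#' @param scores Predicted probabilities.
#' @param threshold Decision cut-off for the confusion counts.
#' @param scope Optional label.
#' @return One-row `gait_metrics` tibble including `auc`.
#' @export
binary_report <- function(labels, scores, threshold = 0.5,
                          scope = NA_character_) {
  counts <- confusion_counts(labels, scores, threshold)
  out <- binary_metrics(counts, scope = scope)
  out$auc <- if (length(unique(labels)) < 2) NA_real_
             else auc_score(labels, scores)
  out
}

#' Aggregate cascade performance over the six events
#'
#' Six-class accuracy is the fraction of exact event matches. Per-event
#' discrimination is a one-vs-rest AUC on the path-derived event scores
#' (product of branch probabilities to each leaf), macro-averaged over the
#' events present in the truth; events absent from the truth are excluded
#' with a warning.
#'
#' @param results Tibble from [predict_windows()] (columns `event`,
#'   `event_pred` and `score_<event>`), or built manually.
#' @return List with `accuracy`, `macro_auc`, `per_event` (tibble of
#'   one-vs-rest AUCs), `confusion` (6 x 6 table, truth in rows) and `n`.
#' @export
cascade_metrics <- function(results) {
  stopifnot(nrow(results) > 0,
            all(c("event", "event_pred") %in% names(results)))
  events <- gait_events()
  accuracy <- mean(results$event == results$event_pred)
  confusion <- table(
    truth = factor(results$event, levels = events),
    predicted = factor(results$event_pred, levels = events)
  )
  per_event <- purrr::map(events, function(ev) {
    col <- paste0("score_", ev)
    if (!col %in% names(results)) return(NULL)
    if (!any(results$event == ev)) {
      rlang::warn(paste0("Event '", ev,
                         "' absent from truth; excluded from macro AUC"),
                  class = "gait_degenerate_metric")
      return(tibble::tibble(event = ev, auc = NA_real_,
                            n_positive = 0L))
    }
    tibble::tibble(
      event = ev,
      auc = auc_score(as.integer(results$event == ev), results[[col]]),
      n_positive = sum(results$event == ev)
    )
  }) |> dplyr::bind_rows()
  macro_auc <- if (nrow(per_event) > 0) {
    mean(per_event$auc, na.rm = TRUE)
  } else {
    NA_real_
  }
  out <- list(accuracy = accuracy, macro_auc = macro_auc,
              per_event = per_event, confusion = confusion,
              n = nrow(results))
  class(out) <- "gait_cascade_metrics"
  out
}

#' @export
print.gait_cascade_metrics <- function(x, ...) {
  cat("<cascade metrics>  n =", x$n, "\n")
  cat("  six-class accuracy:", round(x$accuracy, 4), "\n")
  cat("  macro one-vs-rest AUC:", round(x$macro_auc, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Render a metric report as a text table (one column per model)
#'
#' @param reports A `gait_metrics` tibble (rows = models/nodes).
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
format_metric_table <- function(reports) {
  metric_rows <- c("accuracy", "auc", "precision", "recall", "f1",
                   "specificity", "npv")
  metric_rows <- intersect(metric_rows, names(reports))
  m <- t(as.matrix(reports[, metric_rows]))
  colnames(m) <- reports$scope
  txt <- utils::capture.output(print(round(m, 3), na.print = "undef"))
  cat(txt, sep = "\n")
  invisible(txt)
}
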