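# F1 for one label from binary truth/prediction vectors; 0/0 convention
f1_one <- function(truth, pred) {
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  if (tp == 0 && fp == 0 && fn == 0) {
    warning("label with no true and no predicted positives: F1 set to 0", call. = FALSE)
    return(0)
  }
  if (tp == 0) {
    return(0)
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Compute test-set metrics for one run record
#'
#' Per-label F1, macro F1 (the unweighted mean of per-label F1, insensitive
#' to class imbalance) and accuracy are computed from binarized predictions
#' (task 1: threshold 0.5; task 2: argmax over the seven class
#' probabilities); AUC (task 1 only) from the raw probabilities. Labels
#' absent from the truth are excluded from the macro average with a
#' warning.
#'
#' @param record A one-row run record from [run_cell()] / [run_grid()], or
#'   its `predictions` tibble.
#' @param truth Optional truth vector aligned with the predictions;
#'   defaults to the `truth` column of the record.
#' @return A long tibble: `task`, `architecture`, `padding`, `fold`,
#'   `metric` (`"f1"`, `"macro_f1"`, `"accuracy"`, `"auc"`), `label`
#'   (per-label F1 rows only) and `value`.
#' @export
compute_metrics <- function(record, truth = NULL) {
  if (is.data.frame(record) && "predictions" %in% names(record)) {
    stopifnot(nrow(record) == 1)
    pred <- record$predictions[[1]]
    meta_cols <- intersect(c("task", "architecture", "padding", "fold"), names(record))
    meta <- record[, meta_cols]
    task <- record$task
  } else {
    pred <- record
    meta <- NULL
    task <- if ("prob" %in% names(pred)) 1L else 2L
  }
  truth <- truth %||% pred$truth
  if (task == 1L) {
    labels <- c(0L, 1L)
    hard <- as.integer(pred$prob > 0.5)
  } else {
    labels <- 1:7
    probs <- as.matrix(pred[, paste0("prob_", 1:7)])
    hard <- max.col(probs, ties.method = "first")
  }
  present <- labels %in% truth
  if (any(!present)) {
    warning(
      "labels absent from truth excluded from macro F1: ",
      paste(labels[!present], collapse = ", "),
      call. = FALSE
    )
  }
  f1s <- vapply(
    labels[present],
    function(l) f1_one(truth == l, hard == l),
    numeric(1)
  )
  rows <- tibble::tibble(
    metric = c(rep("f1", sum(present)), "macro_f1", "accuracy"),
    label = c(as.character(labels[present]), NA_character_, NA_character_),
    value = c(f1s, mean(f1s), mean(hard == truth))
  )
  if (task == 1L) {
    auc <- as.numeric(pROC::auc(
      response = truth, predictor = pred$prob,
      levels = c(0, 1), direction = "<", quiet = TRUE
    ))
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(metric = "auc", label = NA_character_, value = auc)
    )
  }
  if (!is.null(meta)) rows <- dplyr::bind_cols(meta[rep(1, nrow(rows)), ], rows)
  rows
}

#' Metrics for every record of a benchmark grid
#'
#' Maps [compute_metrics()] over the rows of a [run_grid()] result,
#' skipping failed cells, and binds the long rows — one row per
#' (task, architecture, padding, fold, metric, label). This is the input
#' format of the explanatory models.
#'
#' @param records A [run_grid()] tibble.
#' @return The long metrics tibble.
#' @export
metrics_table <- function(records) {
  ok <- if ("error" %in% names(records)) is.na(records$error) else rep(TRUE, nrow(records))
  rows <- purrr::map(which(ok), function(i) compute_metrics(records[i, ]))
  dplyr::bind_rows(rows)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares a metric between two conditions paired by fold. Uses the exact
#' signed-rank distribution for n <= 25 pairs (when ties and zero
#' differences permit), otherwise the normal approximation with continuity
#' correction. When every difference is zero the test is degenerate and is
#' reported as p = 1 with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length >= 5, paired by position.
#' @return A one-row tibble: `statistic` (V), `p_value`, `n`, `degenerate`.
#' @export
#' @examples
#' paired_wilcoxon(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 3, 4, 5))
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- x - y
  if (all(d == 0)) {
    return(tibble::tibble(
      statistic = 0, p_value = 1, n = length(d), degenerate = TRUE
    ))
  }
  exact <- length(d) <= 25 && all(d != 0) && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y,
      paired = TRUE, alternative = "two.sided",
      exact = exact, correct = TRUE
    )
  )
  tibble::tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    n = length(d), degenerate = FALSE
  )
}

#' Write a long metrics table as CSV
#'
#' @param metrics A [metrics_table()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}
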