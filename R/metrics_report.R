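#' Build a confusion matrix from label vectors
#'
#' @param truth,predicted equal-length label vectors.
#' @param class_names ordered class list; every label must be a member.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_from_labels <- function(truth, predicted, class_names) {
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  bad <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(bad)) stop("labels outside class_names: ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = class_names)
  pf <- factor(predicted, levels = class_names)
  cm <- table(tf, pf)
  m <- matrix(as.integer(cm), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  m
}

#' Per-class classification metrics
#'
#' For each class, treating it as positive: recall (sensitivity)
#' = 100 TP / (TP + FN), precision = 100 TP / (TP + FP), specificity
#' = 100 TN / (TN + FP), FPR = 100 - specificity, FDR = 100 - precision,
#' FNR = 100 - recall, F1 = harmonic mean of precision and recall. All values
#' are percentages at full precision; see [format_metrics_table()] for the
#' 2-decimal truncated rendering.
#'
#' @param cm confusion matrix from [confusion_from_labels()].
#' @return data.frame, one row per class plus the metric columns.
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  classes <- rownames(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
      warning("class ", classes[i], " has no true samples; recall is NA")
      NA_real_
    }
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
      warning("class ", classes[i], " was never predicted; precision is NA")
      NA_real_
    }
    specificity <- 100 * tn / (tn + fp)
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(class = classes[i], recall = recall, precision = precision,
               specificity = specificity, fpr = 100 - specificity,
               fdr = 100 - precision, fnr = 100 - recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm confusion matrix.
#' @return `100 * trace / total`, a percentage.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Truncate to a fixed number of decimals
#'
#' `trunc_decimals(99.4281, 2)` is 99.42 and `trunc_decimals(42.857, 2)` is
#' 42.85: digits beyond the cut are dropped, not rounded, matching the
#' convention used by the reported per-class tables.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @export
trunc_decimals <- function(x, digits = 2) {
  s <- 10^digits
  trunc(x * s + 1e-9) / s
}

#' Render the per-class metrics table in report layout
#'
#' Column order: per-class recall (printed first, as the per-class accuracy),
#' precision, specificity, FPR, FDR, FNR, F1 — each truncated to two decimals.
#'
#' @param metrics output of [per_class_metrics()].
#' @return data.frame of truncated percentages.
#' @export
format_metrics_table <- function(metrics) {
  data.frame(class = metrics$class,
             accuracy = trunc_decimals(metrics$recall),
             sensitivity = trunc_decimals(metrics$precision),
             specificity = trunc_decimals(metrics$specificity),
             fpr = trunc_decimals(metrics$fpr),
             fdr = trunc_decimals(metrics$fdr),
             fnr = trunc_decimals(metrics$fnr),
             f1 = trunc_decimals(metrics$f1),
             stringsAsFactors = FALSE)
}

#' Write a report for one or more classifier results
#'
#' Produces `metrics.csv` (per-classifier blocks of the formatted per-class
#' table), `confusion.json` (all confusion matrices) and `summary.txt` (an
#' overall-accuracy comparison line per classifier, one decimal).
#'
#' @param results named list; each element a [train_eval()] result.
#' @param output_dir directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, output_dir) {
  if (length(results) == 0) stop("no results to report")
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list (one name per classifier)")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- lapply(names(results), function(nm) {
    tab <- format_metrics_table(per_class_metrics(results[[nm]]$confusion))
    cbind(classifier = nm, tab)
  })
  metrics_path <- file.path(output_dir, "metrics.csv")
  write.csv(do.call(rbind, blocks), metrics_path, row.names = FALSE)

  conf_path <- file.path(output_dir, "confusion.json")
  jsonlite::write_json(
    lapply(results, function(r) {
      list(class_names = rownames(r$confusion),
           counts = unname(apply(r$confusion, 1, as.integer, simplify = FALSE)))
    }),
    conf_path, auto_unbox = TRUE, digits = NA)

  summary_path <- file.path(output_dir, "summary.txt")
  lines <- vapply(names(results), function(nm) {
    sprintf("%s\t%.1f", nm, round(results[[nm]]$accuracy, 1))
  }, "")
  writeLines(c("classifier\taccuracy_pct", lines), summary_path)
  invisible(c(metrics_path, conf_path, summary_path))
}
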