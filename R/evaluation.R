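#' Build a 6 x 6 confusion matrix
#'
#' Rows are actual classes, columns predicted, both in the canonical order
#' LC, RC, LL, LR, WB, SS.
#'
#' @param actual,predicted Equal-length character vectors of class labels.
#' @param classes Class order (default [posture_classes()]).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
build_confusion <- function(actual, predicted, classes = posture_classes()) {
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: %d actual vs %d predicted",
                 length(actual), length(predicted)), call. = FALSE)
  }
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad) > 0L) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Confusion matrix from explicit counts
#'
#' @param counts 6 x 6 non-negative integer matrix, rows actual, columns
#'   predicted.
#' @param classes Class order for the dimnames.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts, classes = posture_classes()) {
  stopifnot(is.matrix(counts), nrow(counts) == length(classes),
            ncol(counts) == length(classes), all(counts >= 0))
  cm <- matrix(as.integer(round(counts)), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' One-vs-rest reduction of a confusion matrix
#'
#' For one class: TP is its diagonal cell, FN the rest of its row, FP the
#' rest of its column, TN everything else; the four counts always sum to the
#' grand total.
#'
#' @param cm A `confusion_matrix`.
#' @param cls Class name.
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest <- function(cm, cls) {
  classes <- rownames(cm)
  if (!(cls %in% classes)) {
    stop(sprintf("unknown class '%s'", cls), call. = FALSE)
  }
  tp <- cm[cls, cls]
  fn <- sum(cm[cls, ]) - tp
  fp <- sum(cm[, cls]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Per-class and overall classification metrics
#'
#' One-vs-rest precision `TP/(TP+FP)` and recall `TP/(TP+FN)` per class,
#' their unweighted macro averages, per-class one-vs-rest accuracy
#' `(TP+TN)/total`, and overall accuracy `trace/total` (the quantity the
#' headline accuracy tables report). A zero denominator yields 0 with the
#' corresponding `flagged` entry set.
#'
#' @param cm A non-empty `confusion_matrix`.
#' @return Object of class `spr_metrics`: list with `per_class` (data.frame:
#'   class, TP, FP, FN, TN, precision, recall, ovr_accuracy, flagged),
#'   `macro_precision`, `macro_recall`, `accuracy`, `total`.
#' @export
confusion_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  per <- data.frame(class = classes, TP = 0, FP = 0, FN = 0, TN = 0,
                    precision = 0, recall = 0, ovr_accuracy = 0,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    v <- one_vs_rest(cm, classes[i])
    per$TP[i] <- v["TP"]; per$FP[i] <- v["FP"]
    per$FN[i] <- v["FN"]; per$TN[i] <- v["TN"]
    pden <- v["TP"] + v["FP"]
    rden <- v["TP"] + v["FN"]
    per$precision[i] <- if (pden > 0) v["TP"] / pden else 0
    per$recall[i] <- if (rden > 0) v["TP"] / rden else 0
    per$flagged[i] <- pden == 0 || rden == 0
    per$ovr_accuracy[i] <- (v["TP"] + v["TN"]) / total
  }
  structure(list(per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 accuracy = sum(diag(cm)) / total,
                 total = total),
            class = "spr_metrics")
}

#' @export
print.spr_metrics <- function(x, ...) {
  per <- x$per_class
  cat("Per-class metrics (%):\n")
  out <- data.frame(class = per$class,
                    precision = sprintf("%.2f", round_half_up(100 * per$precision)),
                    recall = sprintf("%.2f", round_half_up(100 * per$recall)))
  print(out, row.names = FALSE)
  cat(sprintf("Macro precision: %.2f%%  Macro recall: %.2f%%\n",
              round_half_up(100 * x$macro_precision),
              round_half_up(100 * x$macro_recall)))
  cat(sprintf("Overall accuracy: %.2f%% (n = %d)\n",
              round_half_up(100 * x$accuracy), x$total))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(format_confusion(x), sep = "\n")
  invisible(x)
}

#' Format a confusion matrix in the published table layout
#'
#' Rows = actual with a Total and Recall column; a Total row and a Precision
#' row close the table. Percentages are printed with two decimals, rounded
#' half-up.
#'
#' @param cm A `confusion_matrix`.
#' @return Character vector of formatted lines.
#' @export
format_confusion <- function(cm) {
  met <- confusion_metrics(cm)
  classes <- rownames(cm)
  header <- c("", classes, "Total", "Recall")
  rows <- list(header)
  for (i in seq_along(classes)) {
    rows[[length(rows) + 1L]] <- c(
      classes[i], as.character(cm[i, ]), as.character(sum(cm[i, ])),
      sprintf("%.2f%%", round_half_up(100 * met$per_class$recall[i])))
  }
  rows[[length(rows) + 1L]] <- c("Total", as.character(colSums(cm)), "", "")
  rows[[length(rows) + 1L]] <- c(
    "Precision",
    sprintf("%.2f%%", round_half_up(100 * met$per_class$precision)), "", "")
  mat <- do.call(rbind, rows)
  widths <- apply(nchar(mat), 2L, max)
  apply(mat, 1L, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = " ")
  })
}

#' Stratified train/test split
#'
#' Shuffles within each class under the seed and assigns
#' `round(train_fraction * n_class)` samples (clamped so both sides of every
#' class are non-empty) to the training set.
#'
#' @param labels Character class labels.
#' @param train_fraction Fraction per class assigned to training
#'   (default 0.55).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
train_test_split <- function(labels, train_fraction = 0.55, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop(sprintf("class(es) with fewer than 2 samples: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0)
    test <- integer(0)
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train <- c(train, idx[seq_len(n_train)])
      test <- c(test, idx[-seq_len(n_train)])
    }
    list(train = sort(train), test = sort(test))
  })
}
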