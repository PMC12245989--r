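# Classifier evaluation: confusion counts, exact accuracy CI, the
# no-information-rate test, and an exact McNemar test on discordant pairs.

#' Evaluate classifier predictions
#'
#' Accuracy with an exact (Clopper-Pearson) 95% binomial interval;
#' sensitivity and specificity with `"eCO2"` (the second factor level) as the
#' positive class; the no-information rate (NIR, the larger class frequency)
#' with a one-sided exact binomial test of accuracy > NIR; and McNemar's
#' test computed exactly as a two-sided binomial test on the discordant
#' pairs.
#'
#' @param predictions Factor/character of predicted labels.
#' @param truth Factor/character of true labels, same length.
#' @return Object of class `confusion_stats`: `table` (confusion matrix,
#'   truth in columns), `n`, `accuracy`, `accuracy_ci`, `sensitivity`,
#'   `specificity`, `nir`, `nir_p_value`, `mcnemar_p_value`.
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) == 0) stopf("empty predictions")
  if (length(predictions) != length(truth)) {
    stopf("predictions (%d) and truth (%d) differ in length",
          length(predictions), length(truth))
  }
  lev <- levels(plsda_levels(truth))
  truth <- factor(as.character(truth), levels = lev)
  predictions <- factor(as.character(predictions), levels = lev)
  if (anyNA(predictions)) stopf("predictions contain labels outside %s",
                                paste(lev, collapse = "/"))
  pos <- lev[2]; neg <- lev[1]
  tab <- table(predicted = predictions, truth = truth)
  tp <- tab[pos, pos]; tn <- tab[neg, neg]
  fp <- tab[pos, neg]; fn <- tab[neg, pos]
  n <- length(truth)
  correct <- tp + tn
  acc_test <- stats::binom.test(correct, n)
  nir <- max(table(truth)) / n
  nir_p <- stats::binom.test(correct, n, p = nir,
                             alternative = "greater")$p.value
  disc <- fp + fn
  mcnemar_p <- if (disc == 0) 1 else {
    stats::binom.test(fn, disc, p = 0.5)$p.value
  }
  structure(
    list(table = tab, n = n, accuracy = correct / n,
         accuracy_ci = as.numeric(acc_test$conf.int),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         nir = nir, nir_p_value = nir_p, mcnemar_p_value = mcnemar_p,
         positive = pos),
    class = "confusion_stats"
  )
}

#' @export
print.confusion_stats <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy %.3f (95%% CI %.3f-%.3f), sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
              x$sensitivity, x$specificity))
  cat(sprintf("NIR %.3f (P[acc > NIR] = %.3g), McNemar exact P = %.3g\n",
              x$nir, x$nir_p_value, x$mcnemar_p_value))
  invisible(x)
}

#' @export
as.list.confusion_stats <- function(x, ...) {
  list(n = x$n, accuracy = x$accuracy,
       accuracy_ci_lower = x$accuracy_ci[1],
       accuracy_ci_upper = x$accuracy_ci[2],
       sensitivity = x$sensitivity, specificity = x$specificity,
       nir = x$nir, nir_p_value = x$nir_p_value,
       mcnemar_p_value = x$mcnemar_p_value,
       confusion = as.data.frame(x$table))
}
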