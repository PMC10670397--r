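# S3 methods for the evaluation report object.

#' @export
print.sleep_eval <- function(x, ...) {
  cat(sprintf("<sleep_eval> %d subjects, %d epochs, seed %d\n",
              length(x$subjects), x$n_epochs, x$seed))
  cat(sprintf("  %d feature set(s) x %d task(s)\n",
              length(x$feature_sets), length(x$tasks)))
  for (task in x$tasks) {
    cat("\nKappa (mean +/- SD across subjects), task ", task, ":\n", sep = "")
    for (s in names(x$feature_sets)) {
      res <- x$results[[paste(s, task, sep = " | ")]]
      if (!is.null(res))
        cat(sprintf("  %-22s %.2f +/- %.2f\n", s, res$kappa_mean,
                    res$kappa_sd))
    }
  }
  invisible(x)
}

#' @export
summary.sleep_eval <- function(object, task = "AS-QS-CTW", ...) {
  cat("Per-subject kappa, task ", task, ":\n", sep = "")
  print(kappa_table(object, task))
  for (s in names(object$feature_sets)) {
    res <- object$results[[paste(s, task, sep = " | ")]]
    if (is.null(res)) next
    cat("\nPooled confusion matrix (rows = truth), ", s, ":\n", sep = "")
    print(res$pooled_cm)
    cat(sprintf("pooled accuracy %.3f, pooled kappa %.3f\n",
                res$pooled_metrics$accuracy, res$pooled_kappa))
  }
  invisible(object)
}

#' Box plot of the top Gini importances across folds
#'
#' @param x a \code{sleep_eval}.
#' @param feature_set,task experiment cell to plot.
#' @param top number of features.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.sleep_eval <- function(x, feature_set = names(x$feature_sets)[1],
                            task = x$tasks[1], top = 10, ...) {
  imp <- gini_importance(x, feature_set, task, top)
  m <- attr(imp, "per_fold")
  graphics::boxplot(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    horizontal = TRUE, las = 1,
                    names = rev(imp$feature),
                    xlab = "Gini importance (per-fold, normalized)",
                    main = paste(feature_set, task, sep = " - "), ...)
  invisible(imp)
}
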