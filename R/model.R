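# Modeling: LOSO folds, SMOTE balancing, extremely-randomized-trees
# classification, and evaluation metrics.

#' Classifier configuration
#'
#' Extremely-randomized-trees hyperparameters: random split thresholds, no
#' bootstrap (each tree sees the full training sample), and by default the
#' full feature set as split candidates at every node.
#'
#' @param num_trees ensemble size.
#' @param mtry candidate features per split; \code{NULL} uses all features.
#' @param min_node minimum terminal node size.
#' @param smote_k SMOTE neighbor count.
#' @export
et_config <- function(num_trees = 100, mtry = NULL, min_node = 1,
                      smote_k = 5) {
  structure(list(num_trees = num_trees, mtry = mtry, min_node = min_node,
                 smote_k = smote_k), class = "et_config")
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's epochs form the test set and every
#' other subject's epochs form the training set, so no subject ever appears
#' on both sides of a split.
#'
#' @param features feature data frame with a \code{subject_id} column.
#' @return named list of folds, each \code{list(subject, train, test)} with
#'   row indices.
#' @export
loso_folds <- function(features) {
  subs <- unique(features$subject_id)
  if (length(subs) < 2) stop("leave-one-subject-out needs at least 2 subjects")
  out <- lapply(subs, function(s) {
    te <- which(features$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(features)), te), test = te)
  })
  names(out) <- subs
  out
}

# median imputation fitted on the training rows only
impute_fit <- function(x) apply(x, 2, median, na.rm = TRUE)
impute_apply <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- if (is.na(med[j])) 0 else med[j]
  }
  x
}

#' SMOTE oversampling
#'
#' Brings every class up to the majority-class count by interpolating
#' synthetic rows between a minority observation and one of its k nearest
#' same-class neighbors (Euclidean distance on globally standardized
#' features; interpolation in the original feature space). Must only ever be
#' applied to training partitions; [run_experiment()] enforces this
#' structurally.
#'
#' @param x numeric feature matrix without missing values.
#' @param y class factor or character vector.
#' @param k neighbor count; automatically reduced for classes with fewer than
#'   k + 1 members. A singleton class falls back to duplication with a
#'   warning.
#' @param seed optional RNG seed.
#' @return list with balanced \code{x} and \code{y}.
#' @export
smote_oversample <- function(x, y, k = 5, seed = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("SMOTE requires complete features; impute first")
  y <- as.character(y)
  cnt <- table(y)
  maj <- max(cnt)
  if (all(cnt == maj)) return(list(x = x, y = y))
  sds <- apply(x, 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1
  xs <- sweep(x, 2, sds, "/")
  with_local_seed(seed, {
    add_x <- NULL; add_y <- character(0)
    for (cl in names(cnt)[cnt < maj]) {
      idx <- which(y == cl)
      need <- maj - length(idx)
      if (length(idx) == 1) {
        warning("class '", cl, "' has a single member; duplicating it")
        add_x <- rbind(add_x, x[rep(idx, need), , drop = FALSE])
        add_y <- c(add_y, rep(cl, need))
        next
      }
      keff <- min(k, length(idx) - 1)
      d <- as.matrix(dist(xs[idx, , drop = FALSE]))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(keff)]))
      base <- idx[1 + (seq_len(need) - 1) %% length(idx)]
      picks <- vapply(seq_len(need), function(s) {
        bi <- 1 + (s - 1) %% length(idx)
        idx[nn[bi, sample.int(keff, 1)]]
      }, 0L)
      u <- runif(need)
      synth <- x[base, , drop = FALSE] +
        u * (x[picks, , drop = FALSE] - x[base, , drop = FALSE])
      add_x <- rbind(add_x, synth)
      add_y <- c(add_y, rep(cl, need))
    }
    list(x = rbind(x, add_x), y = c(y, add_y))
  })
}

#' Train an extremely-randomized-trees classifier
#'
#' Probability forest with random split points (\code{splitrule =
#' "extratrees"}), no bootstrap, and impurity (Gini) importances.
#'
#' @param x feature matrix, \code{y} class labels of the (balanced) training
#'   set.
#' @param y class labels.
#' @param config an [et_config()].
#' @param seed RNG seed for the forest.
#' @return a \code{ranger} fit.
#' @export
train_classifier <- function(x, y, config = et_config(), seed = 1L) {
  y <- factor(y)
  if (!length(y)) stop("empty training set")
  ranger::ranger(x = as.data.frame(x), y = y,
                 num.trees = config$num_trees,
                 mtry = config$mtry %||% ncol(x),
                 min.node.size = config$min_node,
                 splitrule = "extratrees", num.random.splits = 1,
                 replace = FALSE, sample.fraction = 1,
                 probability = TRUE, importance = "impurity",
                 seed = seed, num.threads = 1, verbose = FALSE)
}

# per-class probability scores on new data
predict_scores <- function(fit, x) {
  p <- stats::predict(fit, data = as.data.frame(x),
                      num.threads = 1)$predictions
  colnames(p) <- fit$forest$levels %||% colnames(p)
  p
}

#' Confusion matrix with a fixed class order
#'
#' @param truth,pred class labels.
#' @param classes class order for rows (truth) and columns (predicted).
#' @return square integer table.
#' @export
confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Cohen's kappa from a confusion matrix
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o = trace /
#' total and chance agreement p_e from the row/column marginals. Defined as 0
#' when p_e = 1.
#'
#' @param cm square count matrix (rows = truth).
#' @return value in [-1, 1].
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve via the Mann-Whitney formulation, with the
#' mid-rank tie correction.
#'
#' @param scores positive-class scores.
#' @param positive logical vector marking positive-class observations.
#' @return AUC in [0, 1]; \code{NA} when either class is absent.
#' @export
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy plus one-vs-rest sensitivity, precision and specificity per
#' class. Classes absent from the test truth yield \code{NA} sensitivity.
#'
#' @param cm square count matrix, rows = truth.
#' @return list with \code{accuracy} and a per-class data frame.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  cls <- rownames(cm)
  per <- do.call(rbind, lapply(seq_along(cls), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = cls[i],
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  list(accuracy = sum(diag(cm)) / n, per_class = per)
}

# map raw labels to a task's classes; NA drops the row
task_labels <- function(labels, task) {
  switch(task,
         "AS-QS-CTW" = ifelse(labels %in% c("AS", "QS", "CTW"), labels,
                              NA_character_),
         "AS-QS" = ifelse(labels %in% c("AS", "QS"), labels, NA_character_),
         "QS-CTW" = ifelse(labels %in% c("QS", "CTW"), labels, NA_character_),
         "AS-CTW" = ifelse(labels %in% c("AS", "CTW"), labels, NA_character_),
         "Sleep-CTW" = ifelse(labels %in% c("AS", "QS"), "Sleep",
                              ifelse(labels == "CTW", "CTW", NA_character_)),
         stop("unknown task: ", task))
}

task_classes <- function(task) {
  switch(task,
         "AS-QS-CTW" = c("AS", "QS", "CTW"),
         "AS-QS" = c("AS", "QS"),
         "QS-CTW" = c("QS", "CTW"),
         "AS-CTW" = c("AS", "CTW"),
         "Sleep-CTW" = c("Sleep", "CTW"))
}

#' Built-in feature sets
#'
#' The three feature combinations evaluated by the pipeline: motion only,
#' cardiorespiratory (cardiac + respiratory + CRI), and their union.
#' @export
default_feature_sets <- function() {
  list("Motion" = "motion",
       "ECG-Resp-CRI" = c("cardiac", "respiratory", "cri"),
       "ECG-Resp-CRI-Motion" = c("cardiac", "respiratory", "cri", "motion"))
}

#' Run the full LOSO classification experiment
#'
#' For every feature set and classification task: leave-one-subject-out
#' cross-validation with per-fold median imputation (fitted on the training
#' partition and applied to both partitions) and per-fold SMOTE balancing of
#' the training partition only, an extremely-randomized-trees classifier, and
#' per-fold metrics (kappa, accuracy, AUC), pooled confusion matrices and
#' Gini importance distributions.
#'
#' @param features feature data frame from [assemble_features()].
#' @param feature_sets named list mapping set names to feature families
#'   (see [default_feature_sets()]).
#' @param tasks subset of \code{c("AS-QS-CTW", "AS-QS", "QS-CTW", "AS-CTW",
#'   "Sleep-CTW")}.
#' @param config an [et_config()].
#' @param seed master seed; all fold-level randomness derives from it.
#' @return an object of class \code{sleep_eval}.
#' @export
run_experiment <- function(features,
                           feature_sets = default_feature_sets(),
                           tasks = c("AS-QS-CTW", "AS-QS", "QS-CTW",
                                     "AS-CTW", "Sleep-CTW"),
                           config = et_config(), seed = 1L) {
  results <- list()
  for (si in seq_along(feature_sets)) {
    set_name <- names(feature_sets)[si]
    cols <- feature_names(feature_sets[[si]])
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      classes <- task_classes(task)
      y_all <- task_labels(features$label, task)
      keep <- !is.na(y_all)
      df <- features[keep, , drop = FALSE]
      y <- y_all[keep]
      folds <- loso_folds(df)
      per_fold <- list()
      pooled <- matrix(0L, length(classes), length(classes),
                       dimnames = list(classes, classes))
      imp <- matrix(NA_real_, length(cols), length(folds),
                    dimnames = list(cols, names(folds)))
      for (fi in seq_along(folds)) {
        fold <- folds[[fi]]
        stopifnot(length(intersect(df$subject_id[fold$train],
                                   df$subject_id[fold$test])) == 0)
        xtr <- as.matrix(df[fold$train, cols, drop = FALSE])
        xte <- as.matrix(df[fold$test, cols, drop = FALSE])
        ytr <- y[fold$train]; yte <- y[fold$test]
        med <- impute_fit(xtr)
        xtr <- impute_apply(xtr, med)
        xte <- impute_apply(xte, med)
        fseed <- (seed + 7717L * si + 331L * ti + 17L * fi) %%
          .Machine$integer.max
        bal <- smote_oversample(xtr, ytr, k = config$smote_k, seed = fseed)
        fit <- train_classifier(bal$x, bal$y, config, seed = fseed + 1L)
        sc <- predict_scores(fit, xte)
        pred <- colnames(sc)[max.col(sc, ties.method = "first")]
        cm <- confusion_matrix(yte, pred, classes)
        pooled <- pooled + cm
        auc <- if (length(classes) == 2) {
          if (classes[2] %in% colnames(sc))
            auc_rank(sc[, classes[2]], yte == classes[2])
          else NA_real_
        } else {
          mean(vapply(intersect(classes, colnames(sc)), function(cl)
            auc_rank(sc[, cl], yte == cl), 0.0), na.rm = TRUE)
        }
        mets <- classification_metrics(cm)
        imp[, fi] <- fit$variable.importance[cols] /
          sum(fit$variable.importance)
        per_fold[[fi]] <- list(subject = fold$subject, cm = cm,
                               kappa = cohen_kappa(cm),
                               accuracy = mets$accuracy, auc = auc,
                               per_class = mets$per_class,
                               n_train_before = table(factor(ytr, classes)),
                               n_train_after = table(factor(bal$y, classes)))
      }
      kap <- vapply(per_fold, `[[`, 0.0, "kappa")
      results[[paste(set_name, task, sep = " | ")]] <- list(
        feature_set = set_name, task = task, classes = classes,
        folds = per_fold,
        fold_table = data.frame(
          subject = vapply(per_fold, `[[`, "", "subject"),
          kappa = kap,
          accuracy = vapply(per_fold, `[[`, 0.0, "accuracy"),
          auc = vapply(per_fold, `[[`, 0.0, "auc")),
        pooled_cm = pooled,
        pooled_metrics = classification_metrics(pooled),
        pooled_kappa = cohen_kappa(pooled),
        kappa_mean = mean(kap), kappa_sd = sd(kap),
        importance = imp)
    }
  }
  structure(list(results = results, feature_sets = feature_sets,
                 tasks = tasks, config = config, seed = seed,
                 n_epochs = nrow(features),
                 subjects = unique(features$subject_id)),
            class = "sleep_eval")
}

#' Mean Gini importance ranking across folds
#'
#' @param eval a \code{sleep_eval}.
#' @param feature_set,task which experiment cell to rank.
#' @param top number of features to return.
#' @return data frame \code{feature}, \code{mean_importance},
#'   \code{sd_importance}, sorted decreasing; the per-fold importance matrix
#'   is attached as attribute \code{"per_fold"}.
#' @export
gini_importance <- function(eval, feature_set = "ECG-Resp-CRI-Motion",
                            task = "AS-QS-CTW", top = 10) {
  res <- eval$results[[paste(feature_set, task, sep = " | ")]]
  if (is.null(res)) stop("no such feature set / task in this evaluation")
  mi <- rowMeans(res$importance)
  o <- order(mi, decreasing = TRUE)[seq_len(min(top, length(mi)))]
  out <- data.frame(feature = rownames(res$importance)[o],
                    mean_importance = mi[o],
                    sd_importance = apply(res$importance, 1, sd)[o],
                    row.names = NULL)
  attr(out, "per_fold") <- res$importance[o, , drop = FALSE]
  out
}

#' Per-subject kappa table for one task
#'
#' Rows are subjects plus Mean and SD rows; one column per feature set.
#'
#' @param eval a \code{sleep_eval}.
#' @param task the classification task.
#' @export
kappa_table <- function(eval, task = "AS-QS-CTW") {
  sets <- names(eval$feature_sets)
  cols <- lapply(sets, function(s) {
    res <- eval$results[[paste(s, task, sep = " | ")]]
    if (is.null(res)) return(NULL)
    c(res$fold_table$kappa, res$kappa_mean, res$kappa_sd)
  })
  keep <- !vapply(cols, is.null, TRUE)
  res1 <- eval$results[[paste(sets[keep][1], task, sep = " | ")]]
  out <- data.frame(subject = c(res1$fold_table$subject, "Mean", "SD"))
  for (i in which(keep)) out[[sets[i]]] <- round(cols[[i]], 3)
  out
}

#' Null-calibration experiment
#'
#' Shuffles the epoch labels (breaking any label-feature association while
#' keeping the class mix) and reruns the LOSO evaluation; the mean kappa
#' should sit near 0.
#'
#' @param features feature data frame.
#' @param feature_set families to use.
#' @param config an [et_config()].
#' @param seed RNG seed for both the shuffle and the evaluation.
#' @return mean LOSO kappa under shuffled labels.
#' @export
null_kappa <- function(features, feature_set = c("cardiac", "respiratory",
                                                 "cri", "motion"),
                       config = et_config(), seed = 1L) {
  shuffled <- features
  shuffled$label <- with_local_seed(seed, sample(features$label))
  ev <- run_experiment(shuffled, feature_sets = list(null = feature_set),
                       tasks = "AS-QS-CTW", config = config, seed = seed)
  ev$results[[1]]$kappa_mean
}
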