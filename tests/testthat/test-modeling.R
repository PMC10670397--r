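# a small, fast synthetic feature table with a learnable structure
toy_features <- function(n_subj = 4, n_per = 40, seed = 100) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subj), function(s) {
    lab <- sample(c("AS", "QS", "CTW"), n_per, replace = TRUE,
                  prob = c(0.6, 0.2, 0.2))
    mu <- c(AS = 0, QS = 2, CTW = -2)[lab]
    data.frame(subject_id = sprintf("S%d", s),
               epoch_index = seq_len(n_per) - 1L,
               label = lab,
               f1 = mu + rnorm(n_per, 0, 0.8),
               f2 = rnorm(n_per),
               f3 = as.numeric(lab == "CTW") * 3 + rnorm(n_per, 0, 0.6))
  })
  do.call(rbind, rows)
}

test_that("loso_folds partitions by subject with no leakage", {
  ft <- toy_features()
  folds <- loso_folds(ft)
  expect_length(folds, 4)
  for (f in folds) {
    expect_setequal(c(f$train, f$test), seq_len(nrow(ft)))
    expect_length(intersect(f$train, f$test), 0)
    expect_identical(unique(ft$subject_id[f$test]), f$subject)
    expect_false(f$subject %in% ft$subject_id[f$train])
  }
  expect_error(loso_folds(ft[ft$subject_id == "S1", ]), "at least 2")
})

test_that("smote_oversample balances classes by interpolation", {
  set.seed(101)
  x <- rbind(matrix(rnorm(200, 0), 100),
             matrix(rnorm(30, 5), 15))
  y <- rep(c("big", "small"), c(100, 15))
  bal <- smote_oversample(x, y, k = 5, seed = 1)
  expect_equal(unname(table(bal$y)), c(100, 100), ignore_attr = TRUE)
  # synthetic rows lie within the convex hull of the minority coordinates
  new_rows <- bal$x[(nrow(x) + 1):nrow(bal$x), , drop = FALSE]
  rng <- apply(x[y == "small", ], 2, range)
  expect_true(all(new_rows[, 1] >= rng[1, 1] - 1e-9 &
                    new_rows[, 1] <= rng[2, 1] + 1e-9))
  # original rows pass through unchanged
  expect_identical(bal$x[seq_len(nrow(x)), ], x)
  # already balanced input is returned untouched
  bal0 <- smote_oversample(x[1:30, ], rep(c("a", "b"), each = 15))
  expect_equal(nrow(bal0$x), 30)
  # determinism
  bal2 <- smote_oversample(x, y, k = 5, seed = 1)
  expect_identical(bal$x, bal2$x)
  expect_error(smote_oversample(rbind(x, NA), c(y, "big")), "impute")
  expect_warning(smote_oversample(x[1:11, ], rep(c("a", "b"), c(10, 1))),
                 "single member")
})

test_that("cohen_kappa matches the oracle and known values", {
  set.seed(102)
  truth <- sample(c("A", "B", "C"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth,
                 sample(c("A", "B", "C"), 200, replace = TRUE))
  cm <- confusion_matrix(truth, pred, c("A", "B", "C"))
  expect_equal(cohen_kappa(cm), oracle_kappa(truth, pred), tolerance = 1e-12)
  # perfect agreement -> 1; independent marginals -> ~0
  expect_equal(cohen_kappa(diag(5) * 10), 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
})

test_that("auc_rank matches the pair-counting oracle, with ties", {
  set.seed(103)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    sc <- round(runif(n), 2)            # rounding forces ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(sc, pos), oracle_auc(sc, pos), tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_true(is.na(auc_rank(1:4, rep(TRUE, 4))))
})

test_that("classification_metrics agree with hand-computed values", {
  cm <- matrix(c(50, 5, 3,
                 4, 20, 6,
                 2, 1, 9), 3, byrow = TRUE,
               dimnames = list(c("AS", "QS", "CTW"), c("AS", "QS", "CTW")))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, (50 + 20 + 9) / sum(cm))
  expect_equal(m$per_class$sensitivity[1], 50 / 58)
  expect_equal(m$per_class$precision[2], 20 / 26)
  # CTW: tn = total - truth-CTW row (12) - false positives (3 + 6)
  expect_equal(m$per_class$specificity[3], (sum(cm) - 12 - 9) /
                 (sum(cm) - 12))
})

test_that("task_labels maps and excludes correctly", {
  lab <- c("AS", "QS", "CTW")
  expect_identical(neosleep:::task_labels(lab, "AS-QS-CTW"), lab)
  expect_identical(neosleep:::task_labels(lab, "AS-QS"), c("AS", "QS", NA))
  expect_identical(neosleep:::task_labels(lab, "Sleep-CTW"),
                   c("Sleep", "Sleep", "CTW"))
  expect_error(neosleep:::task_labels(lab, "bogus"), "unknown task")
})

test_that("run_experiment learns the toy structure and reports sane output", {
  ft <- toy_features()
  sets <- list(toy = c("cardiac"))
  # bypass the registry: run on explicit columns via a small shim
  ev <- run_experiment(
    cbind(ft[1:3], setNames(ft[c("f1", "f2", "f3")],
                            feature_names("cardiac")[1:3]),
          as.data.frame(matrix(0, nrow(ft), 88,
                               dimnames = list(NULL, setdiff(feature_names(),
                                 feature_names("cardiac")[1:3]))))),
    feature_sets = list(toy = "cardiac"),
    tasks = c("AS-QS-CTW", "Sleep-CTW"),
    config = et_config(num_trees = 50), seed = 7)
  expect_s3_class(ev, "sleep_eval")
  res <- ev$results[["toy | AS-QS-CTW"]]
  expect_gt(res$kappa_mean, 0.5)        # strongly separable toy problem
  expect_equal(nrow(res$fold_table), 4)
  expect_equal(sum(res$pooled_cm), nrow(ft))
  # importance columns are normalized per fold
  expect_equal(colSums(res$importance), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the informative features dominate the constant fillers
  imp <- gini_importance(ev, "toy", "AS-QS-CTW", top = 5)
  expect_true(all(feature_names("cardiac")[c(1, 3)] %in% imp$feature[1:3]))
  # binary task also runs with AUC defined
  res2 <- ev$results[["toy | Sleep-CTW"]]
  expect_true(all(is.finite(res2$fold_table$auc)))
  expect_gt(mean(res2$fold_table$auc), 0.8)
})

test_that("run_experiment is deterministic in the seed", {
  ft <- toy_features(n_subj = 3, n_per = 25)
  shim <- cbind(ft[1:3], setNames(ft[c("f1", "f2", "f3")],
                                  feature_names("motion")[1:3]),
                as.data.frame(matrix(0, nrow(ft), 88,
                  dimnames = list(NULL, setdiff(feature_names(),
                    feature_names("motion")[1:3])))))
  e1 <- run_experiment(shim, feature_sets = list(m = "motion"),
                       tasks = "AS-QS-CTW", config = et_config(num_trees = 30),
                       seed = 11)
  e2 <- run_experiment(shim, feature_sets = list(m = "motion"),
                       tasks = "AS-QS-CTW", config = et_config(num_trees = 30),
                       seed = 11)
  expect_identical(e1$results[[1]]$fold_table, e2$results[[1]]$fold_table)
  e3 <- run_experiment(shim, feature_sets = list(m = "motion"),
                       tasks = "AS-QS-CTW", config = et_config(num_trees = 30),
                       seed = 12)
  expect_false(identical(e1$results[[1]]$fold_table$kappa,
                         e3$results[[1]]$fold_table$kappa))
})

test_that("median imputation is fitted on training data only", {
  x <- matrix(c(1, 2, 3, NA), 4, 1)
  med <- neosleep:::impute_fit(x[1:3, , drop = FALSE])
  expect_equal(unname(med), 2)
  filled <- neosleep:::impute_apply(x, med)
  expect_equal(filled[4, 1], 2)
  # all-NA column falls back to 0
  filled0 <- neosleep:::impute_apply(matrix(NA_real_, 2, 1), NA_real_)
  expect_equal(filled0[, 1], c(0, 0))
})

test_that("kappa_table and the S3 methods run on a tiny evaluation", {
  ft <- toy_features(n_subj = 3, n_per = 20)
  shim <- cbind(ft[1:3], setNames(ft[c("f1", "f2", "f3")],
                                  feature_names("cri")[1:3]),
                as.data.frame(matrix(0, nrow(ft), 88,
                  dimnames = list(NULL, setdiff(feature_names(),
                    feature_names("cri")[1:3])))))
  ev <- run_experiment(shim, feature_sets = list(c = "cri"),
                       tasks = "AS-QS-CTW", config = et_config(num_trees = 20),
                       seed = 3)
  kt <- kappa_table(ev)
  expect_equal(nrow(kt), 5)             # 3 subjects + Mean + SD
  expect_identical(tail(kt$subject, 2), c("Mean", "SD"))
  expect_output(print(ev), "sleep_eval")
  expect_output(summary(ev), "confusion")
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(ev, feature_set = "c"))
})
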