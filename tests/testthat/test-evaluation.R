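test_that("confusion counts tally the 2x2 table", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  allpos <- confusion_counts(c(1, 0), c(1, 1))
  expect_equal(unclass(allpos)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  cc <- structure(list(tp = 8L, fn = 2L, tn = 3L, fp = 7L), class = "confusion_counts")
  expect_equal(sensitivity(cc), 0.8)
  expect_equal(specificity(cc), 0.3)
  expect_equal(balanced_accuracy(cc), 0.55)
  expect_equal(balanced_accuracy(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # constant classifier scores exactly chance whenever both classes exist
  set.seed(8)
  for (i in 1:20) {
    y <- c(1, 0, rbinom(sample(3:30, 1), 1, 0.5))
    expect_equal(balanced_accuracy(y, rep(1, length(y))), 0.5)
    expect_equal(balanced_accuracy(y, rep(0, length(y))), 0.5)
  }
  expect_error(sensitivity(confusion_counts(c(0, 0), c(1, 0))), "undefined")
})

test_that("multiclass accuracy is the fraction of correct predictions", {
  expect_equal(multiclass_accuracy(c("a", "b", "c", "a"), c("a", "b", "c", "b")), 0.75)
  expect_equal(multiclass_accuracy(letters[1:5], letters[1:5]), 1)
  expect_equal(multiclass_accuracy(c("a", "b"), c("b", "a")), 0)
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1)
  expect_equal(auc(c(1, 0, 0, 1), c(0.9, 0.2, 0.8, 0.3)), 0.75)
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # plenty of ties
    expect_equal(auc(y, s), auc_oracle(y, s), tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  y <- c(1, 0, 1, 0, 0, 1); s <- c(0.3, 0.1, 0.9, 0.5, 0.2, 0.5)
  expect_equal(auc(y, s), auc(y, exp(4 * s)))
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("binary task enumeration yields one task per subtype pair", {
  y5 <- factor(rep(SUBTYPE_LEVELS, 3), levels = SUBTYPE_LEVELS)
  tasks <- make_binary_tasks(y5)
  expect_length(tasks, choose(5, 2))
  expect_length(tasks, 10L)
  ids <- vapply(tasks, `[[`, "", "task_id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(tasks[[1]]$task_id, "luminal_A_vs_luminal_B")
  expect_equal(tasks[[1]]$positive, "luminal_A")
  y2 <- factor(c("tnbc", "unclear"))
  expect_length(make_binary_tasks(y2), 1L)
  expect_error(make_binary_tasks(factor(rep("tnbc", 3))), "two subtypes")
})

test_that("stratified folds partition the samples and preserve class proportions", {
  set.seed(3)
  y <- factor(rep(c("a", "b", "c"), c(40, 25, 10)))
  fold <- omixnet:::stratified_folds(y, 5)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), 75L)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), length(levels(y)))
  for (cl in levels(y)) {
    per_fold <- table(fold[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(omixnet:::stratified_folds(factor(rep(c("a", "b"), c(20, 3))), 5),
               "fewer than k_folds")
})

test_that("cross-validation reports per-fold metrics and is reproducible", {
  sim <- tiny_dataset(seed = 29, classes = c(luminal_A = 40, tnbc = 30),
                      n_genes = 200)
  cfg <- omixnet_config(epochs = 15, hidden_dim = 16)
  r1 <- cross_validate(sim$dataset, c("luminal_A", "tnbc"), cfg,
                       k_features = 50, seed = 6)
  expect_s3_class(r1, "eval_report")
  expect_equal(r1$n_folds, 5L)
  expect_equal(r1$mean_accuracy, mean(r1$per_fold$accuracy))
  expect_equal(r1$mean_auc, mean(r1$per_fold$auc))
  expect_true(all(r1$per_fold$accuracy >= 0 & r1$per_fold$accuracy <= 1))
  n_eval <- with(r1$confusion, tp + fp + tn + fn)
  expect_equal(n_eval, 70L)
  r2 <- cross_validate(sim$dataset, c("luminal_A", "tnbc"), cfg,
                       k_features = 50, seed = 6)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(cross_validate(sim$dataset, "luminal_A_vs_her2_pos"), "valid tasks")
})

test_that("holdout evaluation enforces disjoint samples and skips impossible tasks", {
  simA <- tiny_dataset(seed = 31, classes = c(luminal_A = 30, tnbc = 20), n_genes = 150)
  simB <- simulate_multiomics(synthetic_config(
    scale = "test", class_counts = c(luminal_A = 12, tnbc = 8), n_genes = 150, seed = 32))
  test_ds <- preprocess_dataset(simB$dataset)
  # distinct IDs for the holdout cohort
  rename <- function(d, pre) {
    names(d$labels) <- paste0(pre, names(d$labels))
    d$matrices <- lapply(d$matrices, function(m) {
      colnames(m) <- paste0(pre, colnames(m)); m })
    d
  }
  test_ds <- rename(test_ds, "T")
  cfg <- omixnet_config(epochs = 15, hidden_dim = 16)
  rep <- evaluate_holdout(simA$dataset, test_ds, c("luminal_A", "tnbc"), cfg,
                          k_features = 50, seed = 2)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n_folds, 1L)
  expect_error(evaluate_holdout(simA$dataset, simA$dataset, c("luminal_A", "tnbc")),
               "overlap")
  # a task class absent from the test data is skipped with a warning
  expect_warning(
    skipped <- evaluate_holdout(simA$dataset,
                                subset_samples(test_ds, names(test_ds$labels)[test_ds$labels == "tnbc"]),
                                c("luminal_A", "tnbc"), cfg, k_features = 50),
    "skipped")
  expect_null(skipped)
})

test_that("leave-one-subtype-out ablation produces one report per removed class", {
  sim <- tiny_dataset(seed = 37,
                      classes = c(luminal_A = 25, luminal_B = 25, tnbc = 25, unclear = 25),
                      n_genes = 150)
  cfg <- omixnet_config(epochs = 10, hidden_dim = 8)
  reports <- ablation_remove_subtype(sim$dataset, cfg, k_folds = 3,
                                     k_features = 40, seed = 4)
  expect_length(reports, 4L)
  expect_named(reports, c("luminal_A", "luminal_B", "tnbc", "unclear"))
  for (r in reports) expect_equal(r$kind, "multiclass")
  expect_error(ablation_remove_subtype(
    subset_samples(sim$dataset,
                   names(sim$dataset$labels)[sim$dataset$labels %in% c("luminal_A", "tnbc")])),
    "three subtypes")
})

test_that("evaluation reports serialize to JSON and flat TSV", {
  pf <- data.frame(fold = 1:2, accuracy = c(0.8, 0.9), auc = c(0.7, 0.95))
  rep <- omixnet:::new_eval_report("luminal_A_vs_tnbc", "binary", pf,
                                   confusion_counts(c(1, 0), c(1, 0)))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, jf, tf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$luminal_A_vs_tnbc$mean_accuracy, 0.85)
  tab <- read.delim(tf)
  expect_setequal(unique(tab$metric), c("accuracy", "auc"))
  expect_equal(nrow(tab), 4L)
})
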