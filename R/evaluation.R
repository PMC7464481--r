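# Metrics (sensitivity / specificity / balanced accuracy, multiclass
# accuracy, rank-based AUC), pairwise task enumeration, stratified k-fold
# cross-validation, holdout evaluation, and the leave-one-subtype-out
# ablation.

#' 2x2 confusion counts
#'
#' @param y_true,y_pred Binary vectors (0/1, logical, or a common two-level
#'   factor where the first level is positive) of equal length.
#' @return A `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  b <- function(v) {
    if (is.factor(v)) return(as.integer(v) == 1L)
    if (is.logical(v)) return(v)
    if (all(v %in% c(0, 1))) return(v == 1)
    stop("binary vectors must be 0/1, logical, or two-level factors")
  }
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred differ in length")
  if (!length(y_true)) stop("empty input")
  t_ <- b(y_true); p_ <- b(y_pred)
  structure(list(tp = sum(t_ & p_), fp = sum(!t_ & p_),
                 tn = sum(!t_ & !p_), fn = sum(t_ & !p_)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity and balanced accuracy
#'
#' Sensitivity = tp / (tp + fn); specificity = tn / (tn + fp); balanced
#' accuracy is their mean, the chance-corrected accuracy for imbalanced
#' binary problems (a constant classifier scores 0.5).
#'
#' @param x A `confusion_counts` object, or the true binary vector.
#' @param y_pred Predicted binary vector when `x` is a vector.
#' @return A single number in \[0, 1\].
#' @export
balanced_accuracy <- function(x, y_pred = NULL) {
  c_ <- if (inherits(x, "confusion_counts")) x else confusion_counts(x, y_pred)
  (sensitivity(c_) + specificity(c_)) / 2
}

#' @rdname balanced_accuracy
#' @export
sensitivity <- function(x, y_pred = NULL) {
  c_ <- if (inherits(x, "confusion_counts")) x else confusion_counts(x, y_pred)
  if (c_$tp + c_$fn == 0) stop("no positive samples; sensitivity undefined")
  c_$tp / (c_$tp + c_$fn)
}

#' @rdname balanced_accuracy
#' @export
specificity <- function(x, y_pred = NULL) {
  c_ <- if (inherits(x, "confusion_counts")) x else confusion_counts(x, y_pred)
  if (c_$tn + c_$fp == 0) stop("no negative samples; specificity undefined")
  c_$tn / (c_$tn + c_$fp)
}

#' Multiclass accuracy
#'
#' Fraction of correctly predicted samples.
#'
#' @param y_true,y_pred Class vectors of equal length.
#' @return A single number in \[0, 1\].
#' @export
multiclass_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred differ in length")
  if (!length(y_true)) stop("empty input")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of positive-negative score
#' pairs ranked concordantly, tied pairs counting one half. Invariant under
#' strictly increasing transforms of the scores.
#'
#' @param y_true Binary vector (1/TRUE/first factor level = positive); both
#'   classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(y_true, scores) {
  pos <- if (is.factor(y_true)) as.integer(y_true) == 1L
         else if (is.logical(y_true)) y_true
         else y_true == 1
  if (length(pos) != length(scores)) stop("y_true and scores differ in length")
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)                         # midranks handle ties
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}

#' Enumerate pairwise binary tasks
#'
#' One task per unordered pair of subtypes present in the labels (e.g. 10
#' tasks for 5 subtypes). The first-listed subtype of each pair (in level
#' order) is the positive class.
#'
#' @param labels Factor of subtype labels (named by sample ID when sample
#'   subsets are wanted).
#' @return List of tasks; each is a list with `task_id`, `positive`,
#'   `negative`, and `samples` (names of the labels belonging to the pair,
#'   `NULL` when `labels` is unnamed).
#' @export
make_binary_tasks <- function(labels) {
  y <- droplevels(as.factor(labels))
  present <- levels(y)
  if (length(present) < 2) stop("at least two subtypes must be present")
  out <- list()
  for (i in seq_len(length(present) - 1)) {
    for (j in seq((i + 1), length(present))) {
      pos <- present[i]; neg <- present[j]
      keep <- y %in% c(pos, neg)
      out[[length(out) + 1L]] <- list(
        task_id = paste0(pos, "_vs_", neg), positive = pos, negative = neg,
        samples = if (!is.null(names(labels))) names(labels)[keep] else NULL)
    }
  }
  out
}

# stratified fold assignment: within each class, shuffled members are dealt
# round-robin over folds, so fold sizes differ by at most one per class
stratified_folds <- function(y, k_folds) {
  y <- droplevels(as.factor(y))
  counts <- table(y)
  small <- names(counts)[counts < k_folds]
  if (length(small))
    stop("class '", small[1], "' has ", counts[small[1]],
         " member(s), fewer than k_folds = ", k_folds)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

# one train/test pass shared by CV folds and the holdout path: min-max
# scaling and (optionally) chi2 selection are fit on the training samples
# only, then an omixnet is trained and applied to the test samples
fit_eval_split <- function(data, train_ids, test_ids, config, k_features,
                           feature_selection, selection_scope, omics, seed,
                           task_id, positive = NULL) {
  mats <- data$matrices[omics]
  y_train <- droplevels(data$labels[train_ids])
  y_test <- factor(as.character(data$labels[test_ids]),
                   levels = unique(c(levels(y_train), as.character(data$labels[test_ids]))))
  x_train <- list(); x_test <- list()
  for (o in omics) {
    vals <- unclass(mats[[o]])
    fit <- minmax_fit(vals[, train_ids, drop = FALSE])
    sc_train <- minmax_apply(vals[, train_ids, drop = FALSE], fit)
    sc_test <- minmax_apply(vals[, test_ids, drop = FALSE], fit)
    if (feature_selection) {
      sel_samples <- if (selection_scope == "all") c(train_ids, test_ids) else train_ids
      sel_vals <- if (selection_scope == "all")
        minmax_apply(vals[, sel_samples, drop = FALSE], minmax_fit(vals[, sel_samples, drop = FALSE]))
      else sc_train
      m_sel <- omics_matrix(sel_vals, attr(mats[[o]], "omics_type"), beta_values = FALSE)
      rk <- rank_features(m_sel, data$labels[sel_samples], task_id = task_id)
      genes <- suppressWarnings(select_top_k(rk, k_features))
    } else {
      genes <- rownames(vals)
    }
    x_train[[o]] <- t(sc_train[genes, , drop = FALSE])
    x_test[[o]] <- t(sc_test[genes, , drop = FALSE])
  }
  if (!is.null(positive)) {
    lev <- c(positive, setdiff(levels(y_train), positive))
    y_train <- factor(as.character(y_train), levels = lev)
    y_test <- factor(as.character(y_test), levels = lev)
  }
  model <- omixnet(x_train, y_train, config, seed = seed)
  probs <- predict(model, x_test, type = "prob")
  pred <- predict(model, x_test, type = "class")
  list(model = model, y_test = y_test, probs = probs, pred = pred)
}

new_eval_report <- function(task_id, kind, per_fold, confusion = NULL) {
  structure(list(task_id = task_id, kind = kind, per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_auc = if ("auc" %in% names(per_fold)) mean(per_fold$auc) else NA_real_,
                 confusion = confusion, n_folds = nrow(per_fold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s (%s), %d fold(s)>\n", x$task_id, x$kind, x$n_folds))
  cat(sprintf("  mean accuracy: %.3f", x$mean_accuracy))
  if (!is.na(x$mean_auc)) cat(sprintf("; mean AUC: %.3f", x$mean_auc))
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the late-integration classifier
#'
#' Splits the samples into stratified folds, and within every fold fits the
#' min-max scaling and the chi-squared feature ranking on the training
#' portion only (unless `selection_scope = "all"`, which reproduces
#' whole-dataset selection), trains the network, and evaluates the held-out
#' fold. Binary tasks report balanced accuracy and AUC; multiclass reports
#' accuracy.
#'
#' @param data A complete (no missing values) `multi_omics` dataset.
#' @param task `"multiclass"` (default), a task id like
#'   `"luminal_A_vs_tnbc"`, or a length-2 character vector of subtypes. For
#'   a binary task the first subtype is the positive class.
#' @param config An [omixnet_config()].
#' @param k_folds Number of folds (default 5); every class must have at
#'   least `k_folds` members.
#' @param k_features Genes kept per omics type by chi-squared selection
#'   (default 5000, clamped to the gene count).
#' @param feature_selection Set `FALSE` to train on all genes.
#' @param selection_scope `"fold"` (default, leakage-free) or `"all"`
#'   (selection on the full dataset before splitting).
#' @param omics Optional omics type(s) to use (default: all in the dataset);
#'   a single type gives the single-omics model.
#' @param seed Integer seed controlling fold assignment and training.
#' @return An `eval_report` with per-fold and mean metrics (and the
#'   aggregate confusion counts for binary tasks).
#' @export
cross_validate <- function(data, task = "multiclass", config = omixnet_config(),
                           k_folds = 5, k_features = 5000,
                           feature_selection = TRUE,
                           selection_scope = c("fold", "all"),
                           omics = NULL, seed = 1L) {
  stopifnot(inherits(data, "multi_omics"))
  selection_scope <- match.arg(selection_scope)
  if (is.null(omics)) omics <- names(data$matrices)
  if (!all(omics %in% names(data$matrices)))
    stop("unknown omics type(s): ", paste(setdiff(omics, names(data$matrices)), collapse = ", "))
  for (o in omics)
    if (anyNA(unclass(data$matrices[[o]])))
      stop("matrix '", o, "' has missing values; run preprocess_dataset() first")

  spec <- resolve_task(data$labels, task)
  if (!is.null(spec$samples)) data <- subset_samples(data, spec$samples)
  y <- droplevels(data$labels)
  set.seed(seed)
  fold <- stratified_folds(y, k_folds)
  ids <- names(y)

  rows <- list(); conf <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (f in seq_len(k_folds)) {
    res <- fit_eval_split(data, ids[fold != f], ids[fold == f], config,
                          k_features, feature_selection, selection_scope,
                          omics, seed = seed + f, task_id = spec$task_id,
                          positive = spec$positive)
    if (spec$kind == "binary") {
      yt <- as.integer(res$y_test) == 1L
      yp <- as.integer(res$pred) == 1L
      cc <- confusion_counts(yt, yp)
      for (nm in names(conf)) conf[[nm]] <- conf[[nm]] + cc[[nm]]
      rows[[f]] <- data.frame(fold = f, accuracy = balanced_accuracy(cc),
                              auc = auc(yt, res$probs[, 1]))
    } else {
      rows[[f]] <- data.frame(fold = f,
                              accuracy = multiclass_accuracy(res$y_test, res$pred))
    }
  }
  per_fold <- do.call(rbind, rows)
  new_eval_report(spec$task_id, spec$kind, per_fold,
                  confusion = if (spec$kind == "binary")
                    structure(conf, class = "confusion_counts") else NULL)
}

# normalise the task argument into (kind, task_id, positive, samples)
resolve_task <- function(labels, task) {
  y <- droplevels(as.factor(labels))
  if (identical(task, "multiclass"))
    return(list(kind = "multiclass", task_id = "multiclass",
                positive = NULL, samples = NULL))
  pair <- if (length(task) == 2) task else strsplit(task, "_vs_", fixed = TRUE)[[1]]
  if (length(pair) != 2 || !all(pair %in% levels(y))) {
    valid <- vapply(make_binary_tasks(y), `[[`, "", "task_id")
    stop("unknown task '", paste(task, collapse = ","),
         "'; valid tasks: multiclass, ", paste(valid, collapse = ", "))
  }
  keep <- names(labels)[y %in% pair]
  list(kind = "binary", task_id = paste0(pair[1], "_vs_", pair[2]),
       positive = pair[1], samples = keep)
}

#' Run every pairwise binary task under cross-validation
#'
#' Convenience wrapper calling [cross_validate()] for each task of
#' [make_binary_tasks()].
#'
#' @inheritParams cross_validate
#' @return Named list of `eval_report`s, one per pair.
#' @export
cross_validate_all_pairs <- function(data, config = omixnet_config(),
                                     k_folds = 5, k_features = 5000,
                                     feature_selection = TRUE,
                                     selection_scope = c("fold", "all"),
                                     omics = NULL, seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  tasks <- make_binary_tasks(data$labels)
  out <- list()
  for (tk in tasks)
    out[[tk$task_id]] <- cross_validate(data, c(tk$positive, tk$negative),
                                        config, k_folds, k_features,
                                        feature_selection, selection_scope,
                                        omics, seed)
  out
}

#' Train on one dataset, evaluate on an independent one
#'
#' Feature selection and scaling are fit on the training data only; the
#' sample sets must be disjoint. Binary tasks whose test split lacks one of
#' the two classes are skipped with a warning and return `NULL`.
#'
#' @param train_data,test_data Complete `multi_omics` datasets over the same
#'   omics types and gene spaces.
#' @inheritParams cross_validate
#' @return An `eval_report` with a single "fold", or `NULL` when skipped.
#' @export
evaluate_holdout <- function(train_data, test_data, task = "multiclass",
                             config = omixnet_config(), k_features = 5000,
                             feature_selection = TRUE, omics = NULL, seed = 1L) {
  stopifnot(inherits(train_data, "multi_omics"), inherits(test_data, "multi_omics"))
  overlap <- intersect(names(train_data$labels), names(test_data$labels))
  if (length(overlap))
    stop("train and test sample sets overlap (", length(overlap), " shared sample(s))")
  if (is.null(omics)) omics <- names(train_data$matrices)

  spec <- resolve_task(train_data$labels, task)
  if (spec$kind == "binary") {
    pair <- c(spec$positive, sub(".*_vs_", "", spec$task_id))
    test_present <- pair %in% as.character(test_data$labels)
    if (!all(test_present)) {
      warning("test data lack class '", pair[!test_present][1],
              "'; task ", spec$task_id, " skipped")
      return(NULL)
    }
    train_data <- subset_samples(train_data, spec$samples)
    test_keep <- names(test_data$labels)[as.character(test_data$labels) %in% pair]
    test_data <- subset_samples(test_data, test_keep)
  }
  genes_ok <- all(vapply(omics, function(o)
    all(rownames(train_data$matrices[[o]]) %in% rownames(test_data$matrices[[o]])), TRUE))
  if (!genes_ok) stop("test data lack genes present in the training data")
  # merge into one container so fit_eval_split can slice by sample ID
  mats <- lapply(omics, function(o) {
    tr <- unclass(train_data$matrices[[o]])
    te <- unclass(test_data$matrices[[o]])[rownames(tr), , drop = FALSE]
    omics_matrix(cbind(tr, te), attr(train_data$matrices[[o]], "omics_type"),
                 beta_values = FALSE)
  })
  names(mats) <- omics
  labels <- factor(c(as.character(train_data$labels), as.character(test_data$labels)),
                   levels = levels(train_data$labels))
  names(labels) <- c(names(train_data$labels), names(test_data$labels))
  merged <- multi_omics(mats, labels)
  set.seed(seed)
  res <- fit_eval_split(merged, names(train_data$labels), names(test_data$labels),
                        config, k_features, feature_selection, "fold", omics,
                        seed = seed, task_id = spec$task_id, positive = spec$positive)
  if (spec$kind == "binary") {
    yt <- as.integer(res$y_test) == 1L
    yp <- as.integer(res$pred) == 1L
    cc <- confusion_counts(yt, yp)
    per_fold <- data.frame(fold = 1L, accuracy = balanced_accuracy(cc),
                           auc = auc(yt, res$probs[, 1]))
    new_eval_report(spec$task_id, "binary", per_fold, confusion = cc)
  } else {
    per_fold <- data.frame(fold = 1L,
                           accuracy = multiclass_accuracy(res$y_test, res$pred))
    new_eval_report("multiclass", "multiclass", per_fold)
  }
}

#' Leave-one-subtype-out ablation
#'
#' Removes all samples of one subtype at a time and re-runs multiclass
#' cross-validation on the remaining classes, probing the stability of the
#' imbalance-weighted training.
#'
#' @inheritParams cross_validate
#' @return Named list: removed subtype -> multiclass `eval_report`.
#' @export
ablation_remove_subtype <- function(data, config = omixnet_config(),
                                    k_folds = 5, k_features = 5000,
                                    feature_selection = TRUE, omics = NULL,
                                    seed = 1L) {
  y <- droplevels(data$labels)
  present <- levels(y)
  if (length(present) < 3) stop("ablation requires at least three subtypes")
  out <- list()
  for (cl in present) {
    keep <- names(data$labels)[y != cl]
    sub <- subset_samples(data, keep)
    sub$labels <- droplevels(sub$labels)
    out[[cl]] <- cross_validate(sub, "multiclass", config, k_folds, k_features,
                                feature_selection, "fold", omics, seed)
  }
  out
}

#' Serialize an evaluation report
#'
#' Writes JSON (full report) and/or a flat TSV (`task_id`, `fold`, `metric`,
#' `value`).
#'
#' @param report An `eval_report` or a list of them.
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  reports <- if (inherits(report, "eval_report")) list(report) else report
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r)
      list(task_id = r$task_id, kind = r$kind, per_fold = r$per_fold,
           mean_accuracy = r$mean_accuracy,
           mean_auc = if (!is.na(r$mean_auc)) r$mean_auc,
           confusion = if (!is.null(r$confusion)) unclass(r$confusion),
           n_folds = r$n_folds))
    names(payload) <- vapply(reports, `[[`, "", "task_id")
    jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE, null = "null")
  }
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(reports, function(r) {
      long <- utils::stack(r$per_fold[setdiff(names(r$per_fold), "fold")])
      data.frame(task_id = r$task_id, fold = rep(r$per_fold$fold, length.out = nrow(long)),
                 metric = as.character(long$ind), value = long$values)
    }))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
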