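# Chi-squared (class-sum) feature scoring and top-k selection.

#' Chi-squared class-sum score for one feature
#'
#' Scores a non-negative feature against class labels using the class-sum
#' form of the chi-squared statistic: observed counts are the per-class sums
#' of the feature values, expected counts are the class relative frequencies
#' times the total sum, and the statistic is `sum((obs - exp)^2 / exp)` with
#' `n_classes - 1` degrees of freedom. This binning-free form is the
#' standard feature-selection convention for non-negative features; the
#' chi-squared reference distribution is exact-in-spirit only for
#' Poisson-like count features (see the methods vignette), and for scaled
#' continuous features the statistic is used as a ranking score.
#'
#' @param x Non-negative numeric vector (one feature over samples).
#' @param labels Class labels (factor or vector), same length as `x`; at
#'   least two classes must be present.
#' @return List with elements `statistic` and `p.value`.
#' @export
chi2_score <- function(x, labels) {
  if (any(is.na(x))) stop("feature has missing values")
  if (any(x < 0))
    stop("feature values must be non-negative; rescale with scale_nonnegative()")
  labels <- droplevels(as.factor(labels))
  if (length(x) != length(labels)) stop("x and labels differ in length")
  if (nlevels(labels) < 2) stop("at least two classes must be present")
  if (sum(x) <= 0) stop("feature has zero total sum; statistic undefined")
  obs <- tapply(x, labels, sum)
  freq <- tabulate(labels) / length(labels)
  expd <- freq * sum(x)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = unname(stat),
       p.value = stats::pchisq(stat, df = nlevels(labels) - 1, lower.tail = FALSE))
}

# vectorised class-sum chi2 over the rows (genes) of a values matrix;
# genes with zero total sum get statistic 0 / p 1 so they rank last
chi2_scores_matrix <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  ind <- matrix(0, length(labels), k)
  ind[cbind(seq_along(labels), as.integer(labels))] <- 1
  obs <- values %*% ind                       # genes x classes
  tot <- rowSums(obs)
  freq <- colMeans(ind)
  expd <- tot %o% freq
  stat <- rowSums((obs - expd)^2 / ifelse(expd == 0, 1, expd))
  stat[tot == 0] <- 0
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  p[tot == 0] <- 1
  list(statistic = stat, p.value = p)
}

#' Rank genes by chi-squared score for one classification task
#'
#' Computes [chi2_score()] for every gene on exactly the task's samples and
#' orders genes by ascending p-value, breaking ties by larger statistic and
#' then lexicographic gene symbol (fully deterministic).
#'
#' @param m An [omics_matrix()] without missing values; values must be
#'   non-negative (apply [scale_nonnegative()] first).
#' @param labels Named factor of class labels covering the task samples.
#' @param task_samples Optional character vector restricting the scoring to
#'   a sample subset (e.g. the two subtypes of a binary task); default: all
#'   samples of `m`.
#' @param task_id Optional task identifier stored on the result; default is
#'   derived from the classes present.
#' @return A `feature_ranking`: data frame with columns `gene`, `chi2_stat`,
#'   `p_value`, `rank`, ordered best-first.
#' @export
rank_features <- function(m, labels, task_samples = NULL, task_id = NULL) {
  if (anyNA(unclass(m))) stop("matrix has missing values; impute first")
  if (is.null(task_samples)) task_samples <- colnames(m)
  if (!length(task_samples)) stop("task_samples is empty")
  missing <- setdiff(task_samples, colnames(m))
  if (length(missing)) stop("task sample(s) absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  vals <- unclass(m)[, task_samples, drop = FALSE]
  if (any(vals < 0))
    stop("feature values must be non-negative; rescale with scale_nonnegative()")
  y <- droplevels(as.factor(labels[task_samples]))
  if (nlevels(y) < 2) stop("task subset contains a single class")
  sc <- chi2_scores_matrix(vals, y)
  ord <- order(sc$p.value, -sc$statistic, rownames(vals))
  out <- data.frame(gene = rownames(vals)[ord],
                    chi2_stat = sc$statistic[ord],
                    p_value = sc$p.value[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (is.null(task_id))
    task_id <- if (nlevels(y) == 2) paste(levels(y), collapse = "_vs_") else "multiclass"
  structure(out, class = c("feature_ranking", "data.frame"),
            omics_type = attr(m, "omics_type"), task_id = task_id)
}

#' Select the top-k genes of a ranking
#'
#' @param ranking A `feature_ranking` from [rank_features()].
#' @param k Number of genes to keep (default 5000, the conventional input
#'   width per omics type). Clamped to the number of ranked genes with a
#'   warning.
#' @return Character vector of gene symbols, best rank first.
#' @export
select_top_k <- function(ranking, k = 5000) {
  stopifnot(inherits(ranking, "feature_ranking"), k >= 1)
  if (k > nrow(ranking)) {
    warning(sprintf("k = %d exceeds the %d ranked genes; returning all", k, nrow(ranking)))
    k <- nrow(ranking)
  }
  ranking$gene[seq_len(k)]
}

#' Write a feature ranking as TSV
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @export
write_feature_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
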