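# Shared fixtures and independent oracles for the test suite.

# desk-scale analysis configuration used by the cross-validation checks:
# 40 epochs and top-100 genes per omics (the generator plants 100
# informative genes per omics at the test scale)
fast_config <- function(...) omixnet_config(epochs = 40, ...)
K_DESK <- 100

# small complete dataset for unit tests
tiny_dataset <- function(seed = 3, classes = c(luminal_A = 60, tnbc = 40),
                         n_genes = 300, effect_size = 1.5,
                         signal_mode = "shared", missing_rate = 0.02) {
  sim <- simulate_multiomics(synthetic_config(
    scale = "test", class_counts = classes, n_genes = n_genes,
    effect_size = effect_size, missing_rate = missing_rate,
    signal_mode = signal_mode, seed = seed))
  list(dataset = preprocess_dataset(sim$dataset), truth = sim$ground_truth)
}

# brute-force AUC: enumerate every positive-negative score pair
auc_oracle <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

# direct arithmetic from the sensitivity/specificity definitions
balanced_accuracy_oracle <- function(y, p) {
  sen <- sum(y == 1 & p == 1) / sum(y == 1)
  spe <- sum(y == 0 & p == 0) / sum(y == 0)
  (sen + spe) / 2
}

# contingency-sum chi-squared oracle, written as an explicit loop over
# classes (independent of the vectorised implementation)
chi2_oracle <- function(x, labels) {
  labels <- as.factor(labels)
  total <- sum(x)
  stat <- 0
  for (cl in levels(labels)) {
    obs <- sum(x[labels == cl])
    expd <- mean(labels == cl) * total
    stat <- stat + (obs - expd)^2 / expd
  }
  list(statistic = stat,
       p.value = pchisq(stat, df = nlevels(labels) - 1, lower.tail = FALSE))
}

# sample-level x list (samples x features per omics) from a complete dataset
as_model_input <- function(data, k = NULL, labels = data$labels) {
  out <- list()
  for (o in names(data$matrices)) {
    sc <- unclass(scale_nonnegative(data$matrices[[o]]))
    genes <- rownames(sc)
    if (!is.null(k)) {
      m <- omics_matrix(sc, attr(data$matrices[[o]], "omics_type"), beta_values = FALSE)
      genes <- select_top_k(rank_features(m, labels), k)
    }
    out[[o]] <- t(sc[genes, , drop = FALSE])
  }
  out
}

# permute the labels of a dataset in place (fixed RNG state assumed set)
permute_labels <- function(data) {
  ids <- names(data$labels)
  data$labels[] <- sample(data$labels)
  names(data$labels) <- ids
  data
}
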