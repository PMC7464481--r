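# Seeded generator of aligned three-omics datasets with planted, per-omics
# class signal. Emulates the value ranges of the three platforms: log-normal
# expression, beta-valued methylation, and discretized copy-number calls.

#' Configuration of the synthetic multi-omics generator
#'
#' The paper-scale defaults mirror a 606-sample breast-cancer cohort with
#' five imbalanced subtypes (277 / 40 / 11 / 70 / 208) and the per-platform
#' gene counts 13,195 (mRNA), 14,285 (methylation) and 15,186 (CNV); the
#' test scale keeps the same class proportions at 300 samples and 2,000
#' genes per omics so the whole pipeline runs in minutes.
#'
#' @param scale `"paper"` (default) or `"test"`; chooses the default
#'   `n_samples`, `class_counts` and `n_genes`.
#' @param n_samples Total samples; must equal `sum(class_counts)`.
#' @param class_counts Named integer vector: subtype -> count.
#' @param n_genes Named integer vector: omics type -> gene count, or a
#'   single number used for all three.
#' @param informative_fraction Fraction of genes per omics that carry class
#'   signal (default 0.05).
#' @param effect_size Class mean shift of informative genes, in units of the
#'   within-class standard deviation on the transformed (log / logit /
#'   latent) scale (default 1.5).
#' @param missing_rate Completely-at-random missing-value rate (default 0.02).
#' @param signal_mode `"shared"` (default): every class contrast is planted
#'   in all omics types. `"split"`: each omics type is blind to one subtype
#'   pair (the pair shares its shift pattern there), so no single omics
#'   separates all classes but their union does.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(scale = c("paper", "test"), n_samples = NULL,
                             class_counts = NULL, n_genes = NULL,
                             informative_fraction = 0.05, effect_size = 1.5,
                             missing_rate = 0.02,
                             signal_mode = c("shared", "split"), seed = 1L) {
  scale <- match.arg(scale)
  signal_mode <- match.arg(signal_mode)
  if (is.null(class_counts)) {
    class_counts <- if (scale == "paper")
      c(luminal_A = 277, luminal_B = 40, her2_pos = 11, tnbc = 70, unclear = 208)
    else
      c(luminal_A = 137, luminal_B = 20, her2_pos = 5, tnbc = 35, unclear = 103)
    if (!is.null(n_samples) && n_samples != sum(class_counts)) {
      # keep the cohort's class proportions at the requested size
      raw <- class_counts / sum(class_counts) * n_samples
      class_counts <- pmax(1, floor(raw))
      rem <- n_samples - sum(class_counts)
      if (rem != 0) {
        ord <- order(raw - floor(raw), decreasing = rem > 0)
        for (i in seq_len(abs(rem)))
          class_counts[ord[(i - 1) %% length(ord) + 1]] <-
            class_counts[ord[(i - 1) %% length(ord) + 1]] + sign(rem)
      }
    }
  }
  if (is.null(n_samples)) n_samples <- sum(class_counts)
  if (is.null(n_genes))
    n_genes <- if (scale == "paper")
      c(mrna = 13195, methylation = 14285, cnv = 15186)
    else
      c(mrna = 2000, methylation = 2000, cnv = 2000)
  if (length(n_genes) == 1 && is.null(names(n_genes)))
    n_genes <- c(mrna = n_genes, methylation = n_genes, cnv = n_genes)
  if (sum(class_counts) != n_samples)
    stop("class_counts sum to ", sum(class_counts), ", not n_samples = ", n_samples)
  stopifnot(informative_fraction > 0, informative_fraction < 1,
            effect_size >= 0, missing_rate >= 0, missing_rate < 1,
            all(n_genes >= 1), length(class_counts) >= 2)
  structure(list(n_samples = as.integer(n_samples),
                 class_counts = class_counts, n_genes = n_genes,
                 informative_fraction = informative_fraction,
                 effect_size = effect_size, missing_rate = missing_rate,
                 signal_mode = signal_mode, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config: %d samples, %s mode, effect %.2f, seed %d>\n",
              x$n_samples, x$signal_mode, x$effect_size, x$seed))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                          collapse = ", "), "\n")
  cat("  genes:  ", paste(sprintf("%s=%d", names(x$n_genes), x$n_genes),
                          collapse = ", "), "\n")
  invisible(x)
}

# in split mode each omics type cannot tell one subtype pair apart; the
# merged pairs are chosen so every pair stays separable in some other omics.
# For the canonical five subtypes the blinded pairs involve the large
# classes, so each single-omics model pays a visible accuracy cost.
split_merge_map <- function(classes) {
  if (all(c("luminal_A", "tnbc", "unclear") %in% classes))
    return(list(mrna = c("luminal_A", "unclear"),
                methylation = c("luminal_A", "tnbc"),
                cnv = c("tnbc", "unclear")))
  k <- length(classes)
  merges <- list()
  for (i in seq_len(min(3, max(0, k - 1))))
    merges[[i]] <- classes[c(i, ((i %% k) + 1))]
  names(merges) <- OMICS_TYPES[seq_along(merges)]
  merges
}

# per-gene class shift pattern in {-1, 0, 1}, guaranteed non-constant over
# the effective classes so every informative gene carries some contrast
draw_patterns <- function(n_genes, n_eff) {
  pat <- matrix(sample(c(-1, 0, 1), n_genes * n_eff, replace = TRUE,
                       prob = c(0.25, 0.5, 0.25)), n_genes, n_eff)
  flat <- which(apply(pat, 1, function(r) length(unique(r)) == 1))
  for (i in flat) {
    j <- sample.int(n_eff, 2)
    pat[i, j] <- c(-1, 1)
  }
  pat
}

#' Generate a synthetic aligned three-omics dataset
#'
#' Draws mRNA values log-normally (Gaussian on the log2 scale with a
#' per-gene baseline), methylation beta values via a logistic transform of a
#' Gaussian (class shifts applied on the logit scale), and copy-number calls
#' in \{-2, ..., 2\} by thresholding a Gaussian log-ratio at
#' \eqn{\pm 0.5, \pm 1.5}. A fixed fraction of genes per omics is
#' informative: their transformed-scale class means are shifted by
#' `effect_size` times a per-gene pattern. Missing values are inserted
#' completely at random.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `multi_omics` with `NA` for missing
#'   values) and `ground_truth` (per omics: informative genes, their class
#'   shift matrix, the effective-class map; plus the label vector).
#' @export
simulate_multiomics <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_samples
  classes <- names(config$class_counts)
  y <- factor(rep(classes, config$class_counts), levels = classes)
  ids <- sprintf("S%04d", seq_len(n))
  names(y) <- ids

  merges <- if (config$signal_mode == "split") split_merge_map(classes) else list()
  mats <- list(); truth <- list()
  for (o in names(config$n_genes)) {
    G <- config$n_genes[[o]]
    genes <- sprintf("%s_g%05d", toupper(o), seq_len(G))
    n_inf <- round(config$informative_fraction * G)
    inf_idx <- sort(sample.int(G, n_inf))

    eff_class <- classes
    if (!is.null(merges[[o]])) {
      pair <- merges[[o]]
      eff_class[eff_class == pair[2]] <- pair[1]   # the pair is indistinguishable here
    }
    eff_levels <- unique(eff_class)
    pat <- draw_patterns(n_inf, length(eff_levels))
    colnames(pat) <- eff_levels
    shift_by_class <- pat[, match(eff_class, eff_levels), drop = FALSE] * config$effect_size
    colnames(shift_by_class) <- classes

    shift <- matrix(0, G, n)                      # genes x samples shift on latent scale
    shift[inf_idx, ] <- shift_by_class[, as.integer(y), drop = FALSE]

    noise <- matrix(stats::rnorm(G * n), G, n)
    vals <- switch(o,
      mrna = {
        base <- stats::rnorm(G, mean = 6, sd = 1.5)
        2^(base + shift + noise)
      },
      methylation = {
        base <- stats::rnorm(G, mean = 0, sd = 1.5)
        stats::plogis(base + shift + noise)
      },
      cnv = {
        lat <- shift + noise
        matrix(as.numeric(cut(lat, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                              labels = FALSE)) - 3, G, n)
      },
      stop("unknown omics type: ", o))
    if (config$missing_rate > 0)
      vals[stats::runif(G * n) < config$missing_rate] <- NA_real_
    dimnames(vals) <- list(genes, ids)
    mats[[o]] <- omics_matrix(vals, o)
    truth[[o]] <- list(informative_genes = genes[inf_idx],
                       class_shifts = structure(shift_by_class,
                                                dimnames = list(genes[inf_idx], classes)),
                       effective_class = stats::setNames(eff_class, classes))
  }
  list(dataset = multi_omics(mats, y),
       ground_truth = list(per_omics = truth, labels = y, config = config))
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Produces one TSV per omics type (readable by [read_omics_matrix()]), a
#' labels TSV (`sample_id`, `subtype`) and a ground-truth JSON.
#'
#' @param dataset A `multi_omics` from [simulate_multiomics()].
#' @param ground_truth The matching ground-truth list.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(dataset, ground_truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (o in names(dataset$matrices)) {
    f <- file.path(out_dir, paste0(o, ".tsv"))
    write_omics_matrix(dataset$matrices[[o]], f)
    files[o] <- f
  }
  lf <- file.path(out_dir, "labels.tsv")
  utils::write.table(data.frame(sample_id = names(dataset$labels),
                                subtype = as.character(dataset$labels)),
                     lf, sep = "\t", quote = FALSE, row.names = FALSE)
  files["labels"] <- lf
  gf <- file.path(out_dir, "ground_truth.json")
  gt <- list(labels = as.character(ground_truth$labels),
             sample_ids = names(ground_truth$labels),
             config = unclass(ground_truth$config),
             per_omics = lapply(ground_truth$per_omics, function(t)
               list(informative_genes = t$informative_genes,
                    class_shifts = t$class_shifts,
                    effective_class = as.list(t$effective_class))))
  jsonlite::write_json(gt, gf, digits = NA, auto_unbox = TRUE)
  files["ground_truth"] <- gf
  invisible(files)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()] (or hand-assembled:
#'   `<omics>.tsv` files plus `labels.tsv`).
#' @param omics Omics types to load (default: the three standard ones found).
#' @return A `multi_omics` dataset.
#' @export
read_fixture <- function(dir, omics = NULL) {
  if (is.null(omics))
    omics <- OMICS_TYPES[file.exists(file.path(dir, paste0(OMICS_TYPES, ".tsv")))]
  if (!length(omics)) stop("no omics TSVs found in ", dir)
  mats <- lapply(stats::setNames(omics, omics), function(o)
    read_omics_matrix(file.path(dir, paste0(o, ".tsv")), o))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"), stringsAsFactors = FALSE)
  labels <- factor(lab$subtype,
                   levels = unique(c(SUBTYPE_LEVELS, unique(lab$subtype))))
  names(labels) <- lab$sample_id
  align_samples(mats, labels)
}
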