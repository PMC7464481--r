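# Gene x sample containers and preprocessing for multi-omics subtype classification.

#' Recognised omics types, in canonical integration order
#' @keywords internal
OMICS_TYPES <- c("mrna", "methylation", "cnv")

#' Breast-cancer subtype labels, in canonical order
#'
#' Five-level subtype scheme defined from the three IHC markers ER, PR and
#' HER2: luminal A (ER/PR+, HER2-), luminal B (ER/PR+, HER2+), HER2-positive
#' (ER/PR-, HER2+), triple-negative (all three negative) and "unclear"
#' (markers missing).
#' @export
SUBTYPE_LEVELS <- c("luminal_A", "luminal_B", "her2_pos", "tnbc", "unclear")

#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric gene x sample matrix for a single omics
#' type. Rows are uniquely named genes, columns uniquely named samples, and
#' `NA` entries mark missing measurements (the missing mask).
#'
#' @param values Numeric matrix; rownames = gene symbols, colnames = sample
#'   IDs. `NA` marks missing values.
#' @param omics_type One of `"mrna"`, `"methylation"`, `"cnv"`.
#' @param beta_values Logical; when `TRUE`, observed values must lie in
#'   \[0, 1\] (methylation beta values). Defaults to `TRUE` for methylation.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics_type = c("mrna", "methylation", "cnv"),
                         beta_values = NULL) {
  omics_type <- match.arg(omics_type)
  if (is.null(beta_values)) beta_values <- omics_type == "methylation"
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || any(!nzchar(genes)))
    stop("all genes must have non-empty symbols (rownames)")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(samples) || any(!nzchar(samples)))
    stop("all samples must have non-empty IDs (colnames)")
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (beta_values) {
    obs <- values[!is.na(values)]
    if (length(obs) && (min(obs) < 0 || max(obs) > 1))
      stop("beta values must lie in [0, 1]; found values outside this range")
  }
  structure(values, class = c("omics_matrix", "matrix", "array"),
            omics_type = omics_type, beta_values = beta_values)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix %s: %d genes x %d samples, %d missing values>\n",
              attr(x, "omics_type"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @return `missing_mask()`: logical matrix, `TRUE` where the value is missing.
#' @export
missing_mask <- function(x) is.na(unclass(x))

# subsetting keeps class/attrs when the result is still a matrix
#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x), omics_type = attr(x, "omics_type"),
                     beta_values = attr(x, "beta_values"))
  out
}

#' Read a gene x sample matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of gene symbols.
#' Blank or non-numeric cells become missing values.
#'
#' @param path Path to a delimited text file.
#' @param omics_type One of `"mrna"`, `"methylation"`, `"cnv"`.
#' @param sep Field delimiter; `NULL` (default) infers `","` for `.csv`
#'   files and tab otherwise.
#' @param aggregate_duplicates If `TRUE`, duplicate gene rows are collapsed
#'   by their per-cell mean over observed values; if `FALSE` (default) they
#'   are an error.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, omics_type = c("mrna", "methylation", "cnv"),
                              sep = NULL, aggregate_duplicates = FALSE) {
  omics_type <- match.arg(omics_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  if (!length(lines)) stop("parse error at line 1 of ", path, ": empty file")
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops a single trailing empty field (missing value in the last
  # column); restore it
  trail <- endsWith(lines, sep)
  fields[trail] <- lapply(fields[trail], c, "")
  header <- fields[[1]]
  if (length(header) < 2)
    stop("parse error at line 1 of ", path, ": header must contain at least one sample ID")
  samples <- trimws(header[-1])
  # tolerate a labelled or empty gene-symbol column header
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  n_col <- length(header)
  body <- fields[-1]
  bad <- which(lengths(body) != n_col)
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, " of ", path, ": expected ",
         n_col, " fields, found ", lengths(body)[bad[1]])
  genes <- trimws(vapply(body, `[`, "", 1L))
  vals <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(lapply(body, `[`, -1L)))),
           nrow = length(body), ncol = n_col - 1L, byrow = TRUE))
  rownames(vals) <- NULL
  if (anyDuplicated(genes)) {
    if (!aggregate_duplicates)
      stop("duplicate gene rows: ", paste(unique(genes[duplicated(genes)]), collapse = ", "),
           " (set aggregate_duplicates = TRUE to collapse by mean)")
    grp <- factor(genes, levels = unique(genes))
    obs <- rowsum(ifelse(is.na(vals), 0, vals), grp)
    cnt <- rowsum((!is.na(vals)) * 1, grp)
    vals <- obs / cnt                       # 0/0 -> NaN -> missing
    vals[cnt == 0] <- NA_real_
    vals[is.nan(vals)] <- NA_real_
    genes <- levels(grp)
  }
  dimnames(vals) <- list(genes, samples)
  omics_matrix(vals, omics_type)
}

#' Write a gene x sample matrix as TSV/CSV
#'
#' Inverse of [read_omics_matrix()]; missing values are written as empty
#' cells.
#'
#' @param m An [omics_matrix()].
#' @param path Output path.
#' @param sep Field delimiter (tab default).
#' @param digits Significant digits written (default 15, round-trip safe for
#'   practical purposes).
#' @export
write_omics_matrix <- function(m, path, sep = "\t", digits = 15) {
  vals <- formatC(unclass(m), digits = digits, format = "g")
  vals[is.na(unclass(m))] <- ""
  out <- cbind(gene = rownames(m), vals)
  writeLines(c(paste(c("gene", colnames(m)), collapse = sep),
               apply(out, 1, paste, collapse = sep)), path)
  invisible(path)
}

#' Assign breast-cancer subtypes from IHC marker status
#'
#' Maps ER/PR/HER2 immunohistochemistry status to the five-class subtype
#' scheme: luminal A = ER or PR positive, HER2 negative; luminal B = ER or
#' PR positive, HER2 positive; HER2(+) = ER and PR negative, HER2 positive;
#' TNBC = all three negative. Samples whose observed markers cannot resolve
#' one of those four classes (a required marker is missing) are "unclear".
#'
#' @param records Data frame with columns `sample_id`, `er`, `pr`, `her2`.
#'   Marker status may be coded `"pos"`/`"neg"`/`"missing"` or
#'   `"+"`/`"-"`/`NA`.
#' @return Named factor of subtypes (levels [SUBTYPE_LEVELS]), names =
#'   sample IDs.
#' @export
assign_subtypes <- function(records) {
  need <- c("sample_id", "er", "pr", "her2")
  names(records) <- tolower(names(records))
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(as.character(records$sample_id))))
    stop("sample_id must be non-empty")
  canon <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v %in% c("missing", "NA", "")] <- "missing"
    v[v %in% c("+", "pos", "positive")] <- "pos"
    v[v %in% c("-", "neg", "negative")] <- "neg"
    bad <- setdiff(unique(v), c("pos", "neg", "missing"))
    if (length(bad)) stop("unrecognised marker token(s): ", paste(bad, collapse = ", "))
    v
  }
  er <- canon(records$er); pr <- canon(records$pr); her2 <- canon(records$her2)
  erpr_pos <- er == "pos" | pr == "pos"          # one positive marker suffices
  erpr_neg <- er == "neg" & pr == "neg"          # both must be observed negative
  sub <- rep("unclear", length(er))
  known_her2 <- her2 != "missing"
  sub[erpr_pos & known_her2 & her2 == "neg"] <- "luminal_A"
  sub[erpr_pos & known_her2 & her2 == "pos"] <- "luminal_B"
  sub[erpr_neg & known_her2 & her2 == "pos"] <- "her2_pos"
  sub[erpr_neg & known_her2 & her2 == "neg"] <- "tnbc"
  structure(factor(sub, levels = SUBTYPE_LEVELS),
            names = as.character(records$sample_id))
}

#' Drop genes with too many missing values
#'
#' Removes every gene whose missing count exceeds
#' `max_missing_fraction * n_samples`, preserving gene order. The default
#' fraction 0.33 generalises the usual "more than 200 of 606 samples
#' missing" rule to any cohort size.
#'
#' @param m An [omics_matrix()].
#' @param max_missing_fraction Maximum tolerated fraction of missing samples
#'   per gene, in \[0, 1\].
#' @return Filtered `omics_matrix`.
#' @export
filter_missing_genes <- function(m, max_missing_fraction = 0.33) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  n_missing <- rowSums(is.na(unclass(m)))
  keep <- n_missing <= max_missing_fraction * ncol(m)
  if (!any(keep))
    stop("all genes exceed the missing-value threshold; raise max_missing_fraction")
  m[keep, , drop = FALSE]
}

#' Impute missing values
#'
#' @param m An [omics_matrix()].
#' @param strategy `"gene_mean"` replaces each missing value with the mean
#'   of the gene's observed values; `"zero"` replaces with 0.
#' @return `omics_matrix` with no missing values; observed values unchanged.
#' @export
impute_missing <- function(m, strategy = c("gene_mean", "zero")) {
  strategy <- match.arg(strategy)
  vals <- unclass(m)
  na <- is.na(vals)
  if (!any(na)) return(m)
  if (strategy == "gene_mean") {
    n_obs <- rowSums(!na)
    if (any(n_obs == 0))
      stop("gene(s) with no observed values cannot be mean-imputed: ",
           paste(utils::head(rownames(vals)[n_obs == 0], 5), collapse = ", "))
    fill <- rowMeans(vals, na.rm = TRUE)
    vals[na] <- fill[row(vals)[na]]
  } else {
    vals[na] <- 0
  }
  omics_matrix(vals, attr(m, "omics_type"), attr(m, "beta_values"))
}

#' Per-gene min-max rescaling to \[0, 1\]
#'
#' Rescales each gene linearly so its minimum maps to 0 and maximum to 1;
#' constant genes map to all-zero. Non-negativity is a prerequisite of the
#' class-sum chi-squared feature score.
#'
#' @param m An [omics_matrix()] without missing values.
#' @return Rescaled `omics_matrix`.
#' @export
scale_nonnegative <- function(m) {
  if (anyNA(unclass(m)))
    stop("matrix has missing values; run impute_missing() first")
  fit <- minmax_fit(unclass(m))
  vals <- minmax_apply(unclass(m), fit)
  omics_matrix(vals, attr(m, "omics_type"), beta_values = FALSE)
}

# min-max parameters per gene (rows); reused by the CV pipeline so the
# scaling can be fit on training samples and applied to held-out ones
minmax_fit <- function(values) {
  list(min = apply(values, 1, min), max = apply(values, 1, max))
}

minmax_apply <- function(values, fit, clip = TRUE) {
  rng <- fit$max - fit$min
  rng[rng == 0] <- 1                       # constant genes -> all zero
  out <- (values - fit$min) / rng
  out[fit$max == fit$min, ] <- 0
  if (clip) out[] <- pmin(pmax(out, 0), 1) # held-out values outside train range
  out
}

#' Bundle aligned omics matrices with sample labels
#'
#' Restricts each matrix and the label vector to the samples present in all
#' of them, in a single canonical (lexicographic) order.
#'
#' @param matrices Named list of [omics_matrix()] objects (names = omics
#'   types).
#' @param labels Named factor of subtype labels (names = sample IDs).
#' @return A `multi_omics` object: list with elements `matrices` and
#'   `labels`.
#' @export
align_samples <- function(matrices, labels) {
  if (!length(matrices)) stop("at least one omics matrix is required")
  if (is.null(names(labels))) stop("labels must be named by sample ID")
  common <- Reduce(intersect, c(lapply(matrices, colnames), list(names(labels))))
  if (!length(common)) stop("no samples are shared across all matrices and labels")
  common <- sort(common)
  for (nm in names(matrices)) {
    dropped <- ncol(matrices[[nm]]) - length(common)
    if (dropped > 0)
      message(sprintf("align_samples: dropping %d sample(s) from %s", dropped, nm))
    matrices[[nm]] <- matrices[[nm]][, common, drop = FALSE]
  }
  if (length(labels) > length(common))
    message(sprintf("align_samples: dropping %d labelled sample(s) absent from the matrices",
                    length(labels) - length(common)))
  multi_omics(matrices, labels[common])
}

#' @rdname align_samples
#' @export
multi_omics <- function(matrices, labels) {
  stopifnot(is.list(matrices), length(matrices) >= 1, is.factor(labels))
  samp <- names(labels)
  for (nm in names(matrices))
    if (!identical(colnames(matrices[[nm]]), samp))
      stop("matrix '", nm, "' is not sample-aligned with the labels")
  structure(list(matrices = matrices, labels = labels), class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("<multi_omics: %d samples, %d omics type(s)>\n",
              length(x$labels), length(x$matrices)))
  for (nm in names(x$matrices))
    cat(sprintf("  %-12s %5d genes (%d missing values)\n", nm,
                nrow(x$matrices[[nm]]), sum(is.na(unclass(x$matrices[[nm]])))))
  print(table(droplevels(x$labels)))
  invisible(x)
}

#' Subset a multi-omics dataset by sample
#' @param data A `multi_omics` object.
#' @param samples Character vector of sample IDs (order preserved).
#' @return A `multi_omics` over the requested samples.
#' @export
subset_samples <- function(data, samples) {
  stopifnot(inherits(data, "multi_omics"))
  missing <- setdiff(samples, names(data$labels))
  if (length(missing)) stop("unknown sample(s): ", paste(utils::head(missing, 5), collapse = ", "))
  mats <- lapply(data$matrices, function(m) m[, samples, drop = FALSE])
  multi_omics(mats, data$labels[samples])
}

#' Filter, impute and validate every matrix of a dataset
#'
#' Standard preprocessing applied before feature selection: per-omics
#' missing-gene filtering followed by imputation.
#'
#' @param data A `multi_omics` object.
#' @param max_missing_fraction Passed to [filter_missing_genes()].
#' @param strategy Passed to [impute_missing()].
#' @return A `multi_omics` object with complete matrices.
#' @export
preprocess_dataset <- function(data, max_missing_fraction = 0.33,
                               strategy = c("gene_mean", "zero")) {
  strategy <- match.arg(strategy)
  mats <- lapply(data$matrices, function(m)
    impute_missing(filter_missing_genes(m, max_missing_fraction), strategy))
  multi_omics(mats, data$labels)
}
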