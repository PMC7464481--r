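# Late-integration feedforward network: one encoding subnetwork per omics
# type (affine map -> batch norm -> ReLU -> dropout), concatenation with
# row-wise L2 normalization, and a linear classification head trained
# end-to-end by backpropagation with Adam.

#' Model configuration
#'
#' Hyperparameters of the late-integration network. The defaults are
#' deliberately moderate, untuned values.
#'
#' @param hidden_dim Output width K of every encoding subnetwork (default 64).
#' @param dropout Dropout probability applied after each encoder's ReLU and
#'   on the integrated representation before the head, in \[0, 1) (default 0.5).
#' @param weight_decay L2 penalty on the classification-layer weights only
#'   (default 1e-4); encoders are regularized by dropout and batch norm.
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 100); one epoch presents
#'   `n_samples` draws.
#' @param batch_size Mini-batch size (default 32). Batches smaller than 2
#'   are skipped while batch normalization is active.
#' @param balance_sampling If `TRUE` (default), mini-batches are drawn with
#'   replacement with per-sample probability proportional to the reciprocal
#'   of the sample's class size, so each class is drawn uniformly in
#'   expectation (simultaneous under/oversampling).
#' @param decision_threshold Probability threshold for the positive class in
#'   binary prediction (default 0.5; `p >= threshold` is positive).
#' @param bn_momentum Update rate of the batch-norm running statistics
#'   (default 0.1).
#' @param bn_eps Batch-norm variance floor (default 1e-5).
#' @return An `omixnet_config` list.
#' @export
omixnet_config <- function(hidden_dim = 64, dropout = 0.5, weight_decay = 1e-4,
                           learning_rate = 1e-3, epochs = 100, batch_size = 32,
                           balance_sampling = TRUE, decision_threshold = 0.5,
                           bn_momentum = 0.1, bn_eps = 1e-5) {
  stopifnot(hidden_dim >= 1, dropout >= 0, dropout < 1, weight_decay >= 0,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 balance_sampling = isTRUE(balance_sampling),
                 decision_threshold = decision_threshold,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "omixnet_config")
}

#' Reciprocal-class-count sampling weights
#'
#' Weight of a sample in class c is `1 / count(c)`, so sampling with
#' replacement under these weights draws every class with expected
#' probability `1 / n_classes` regardless of imbalance.
#'
#' @param labels Class labels (factor or vector); every class present must
#'   have at least one member.
#' @return Numeric vector of positive per-sample weights.
#' @export
compute_sampling_weights <- function(labels) {
  y <- droplevels(as.factor(labels))
  counts <- table(y)
  if (any(counts == 0)) stop("empty class: ", names(counts)[counts == 0][1])
  w <- as.numeric(1 / counts[as.integer(y)])
  names(w) <- names(labels)
  w
}

# canonical omics order for concatenation: mrna, methylation, cnv, then any
# other names alphabetically
canonical_omics_order <- function(nms) {
  c(intersect(OMICS_TYPES, nms), sort(setdiff(nms, OMICS_TYPES)))
}

#' Build an untrained late-integration network
#'
#' Creates one encoding subnetwork per omics type (affine `M_o -> K`, batch
#' normalization, ReLU, dropout) and a linear classification head over the
#' concatenated width `sum(K)`. Weights are drawn from a seeded generator
#' (He-scaled normal for encoders, 1/sqrt(D)-scaled for the head).
#'
#' @param input_dims Named integer vector or list: omics type -> number of
#'   input features.
#' @param classes Character vector of class labels in fixed order (length
#'   `>= 2`). Two classes select the binary (sigmoid / binary cross-entropy)
#'   head with `classes[1]` as positive; more select softmax /
#'   cross-entropy.
#' @param config An [omixnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An untrained object of class `omixnet`.
#' @export
build_omixnet <- function(input_dims, classes, config = omixnet_config(), seed = 1L) {
  dims <- unlist(input_dims)
  if (!length(dims)) stop("at least one omics type is required")
  if (is.null(names(dims)) || any(!nzchar(names(dims))))
    stop("input_dims must be named by omics type")
  if (any(dims < 1)) stop("all input dims must be >= 1")
  classes <- as.character(classes)
  if (length(classes) < 2) stop("at least two classes are required")
  task <- if (length(classes) == 2) "binary" else "multiclass"
  omics_order <- canonical_omics_order(names(dims))
  K <- config$hidden_dim
  set.seed(seed)
  encoders <- list()
  for (o in omics_order) {
    M <- dims[[o]]
    encoders[[o]] <- list(
      W = matrix(stats::rnorm(M * K, sd = sqrt(2 / M)), M, K),
      b = numeric(K),
      gamma = rep(1, K), beta = numeric(K),
      run_mean = numeric(K), run_var = rep(1, K))
  }
  D <- K * length(omics_order)
  n_out <- if (task == "binary") 1L else length(classes)
  head <- list(W = matrix(stats::rnorm(D * n_out, sd = sqrt(1 / D)), D, n_out),
               b = numeric(n_out))
  structure(list(encoders = encoders, head = head, config = config,
                 classes = classes, task = task, omics_order = omics_order,
                 input_dims = dims[omics_order], feature_names = NULL,
                 trained = FALSE, loss_history = numeric(0), seed = seed),
            class = "omixnet")
}

# ---- forward passes ---------------------------------------------------------

# deterministic (evaluation-mode) forward of one encoder
encoder_forward_eval <- function(enc, X, eps) {
  Z <- X %*% enc$W
  Z <- sweep(Z, 2, enc$run_mean - enc$b, "-")
  Z <- sweep(Z, 2, sqrt(enc$run_var + eps), "/")
  Z <- sweep(sweep(Z, 2, enc$gamma, "*"), 2, enc$beta, "+")
  pmax(Z, 0)
}

l2_normalize_rows <- function(H) {
  nrm <- sqrt(rowSums(H^2))
  safe <- ifelse(nrm > 0, nrm, 1)          # zero rows stay zero
  H / safe
}

#' Encode and integrate a multi-omics batch
#'
#' Applies each trained (or initialized) encoder in evaluation mode,
#' concatenates the per-omics representations in the model's fixed omics
#' order, and L2-normalizes every row (rows of norm zero are left as zero).
#'
#' @param model An `omixnet`.
#' @param batch Named list: omics type -> numeric matrix (samples x
#'   features) matching the model's input widths. The mapping order is
#'   irrelevant; the model's canonical order is used.
#' @return Numeric matrix, `n_samples x sum(K)`, unit-norm rows.
#' @export
encode_integrate <- function(model, batch) {
  stopifnot(inherits(model, "omixnet"))
  check_batch(model, batch)
  H <- do.call(cbind, lapply(model$omics_order, function(o)
    encoder_forward_eval(model$encoders[[o]], batch[[o]], model$config$bn_eps)))
  l2_normalize_rows(H)
}

check_batch <- function(model, batch) {
  missing <- setdiff(model$omics_order, names(batch))
  if (length(missing)) stop("batch lacks omics type(s): ", paste(missing, collapse = ", "))
  for (o in model$omics_order) {
    if (!is.matrix(batch[[o]])) stop("batch entry '", o, "' must be a matrix")
    if (ncol(batch[[o]]) != model$input_dims[[o]])
      stop(sprintf("width mismatch for omics '%s': expected %d features, got %d",
                   o, model$input_dims[[o]], ncol(batch[[o]])))
  }
  ns <- vapply(batch[model$omics_order], nrow, 0L)
  if (length(unique(ns)) != 1) stop("batch matrices have differing sample counts")
  invisible(TRUE)
}

# ---- training ---------------------------------------------------------------

adam_init <- function(p) list(m = p * 0, v = p * 0)

adam_step <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Fit a late-integration multi-omics classifier
#'
#' Trains the whole network (encoders and classification head) jointly by
#' mini-batch gradient descent with Adam. Binary tasks use a sigmoid output
#' with binary cross-entropy; multiclass tasks use softmax with
#' cross-entropy. Weight decay is applied to the classification layer only.
#' When `config$balance_sampling` is `TRUE`, each epoch draws `n_samples`
#' samples with replacement with probability proportional to the reciprocal
#' of their class size.
#'
#' @param x Named list: omics type -> numeric matrix (samples x features,
#'   rows aligned across omics types). Features are expected to be selected
#'   and scaled to \[0, 1\] already.
#' @param y Factor of class labels, one per sample. Two levels select the
#'   binary head (first level = positive class).
#' @param config An [omixnet_config()].
#' @param seed Integer seed controlling initialization, sampling and
#'   dropout; identical seed, data and config give identical fits.
#' @return A trained `omixnet` object with `loss_history` (mean epoch loss).
#' @examples
#' sim <- simulate_multiomics(synthetic_config(scale = "test", n_samples = 60,
#'   class_counts = c(luminal_A = 30, tnbc = 30), n_genes = 100, seed = 7))
#' ds <- preprocess_dataset(sim$dataset)
#' xs <- lapply(ds$matrices, function(m) t(unclass(scale_nonnegative(m))))
#' fit <- omixnet(xs, droplevels(ds$labels),
#'                omixnet_config(hidden_dim = 8, epochs = 5), seed = 1)
#' fit
#' @export
omixnet <- function(x, y, config = omixnet_config(), seed = 1L) {
  stopifnot(is.list(x), length(x) >= 1)
  y <- droplevels(as.factor(y))
  n <- length(y)
  for (o in names(x)) {
    if (!is.matrix(x[[o]]) || !is.numeric(x[[o]]))
      stop("x[['", o, "']] must be a numeric matrix (samples x features)")
    if (nrow(x[[o]]) != n)
      stop("x[['", o, "']] has ", nrow(x[[o]]), " rows but there are ", n, " labels")
  }
  if (nlevels(y) < 2) stop("at least two classes must be present in y")
  if (n < 2) stop("at least two samples are required")

  dims <- vapply(x, ncol, 0L)
  model <- build_omixnet(dims, levels(y), config, seed)
  model$feature_names <- lapply(x[model$omics_order], colnames)
  x <- lapply(x[model$omics_order], function(m) unname(m))

  cfg <- config
  K <- cfg$hidden_dim
  y_int <- as.integer(y)
  n_classes <- nlevels(y)
  binary <- model$task == "binary"
  y_pos <- as.numeric(y_int == 1L)         # positive class = first level
  Yhot <- matrix(0, n, n_classes)
  Yhot[cbind(seq_len(n), y_int)] <- 1

  w <- if (cfg$balance_sampling) compute_sampling_weights(y) else NULL

  # Adam state for every parameter
  st <- list()
  for (o in model$omics_order)
    for (p in c("W", "b", "gamma", "beta"))
      st[[paste(o, p)]] <- adam_init(model$encoders[[o]][[p]])
  st[["head W"]] <- adam_init(model$head$W)
  st[["head b"]] <- adam_init(model$head$b)

  eps <- cfg$bn_eps; mom <- cfg$bn_momentum
  keep <- 1 - cfg$dropout
  t_step <- 0L
  loss_history <- numeric(cfg$epochs)
  nO <- length(model$omics_order)

  for (epoch in seq_len(cfg$epochs)) {
    idx_all <- if (cfg$balance_sampling)
      sample.int(n, n, replace = TRUE, prob = w)
    else sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (s in starts) {
      idx <- idx_all[s:min(s + cfg$batch_size - 1L, n)]
      B <- length(idx)
      if (B < 2) next                      # batch-norm statistics undefined
      # forward
      cache <- vector("list", nO)
      H <- matrix(0, B, K * nO)
      for (j in seq_len(nO)) {
        o <- model$omics_order[j]
        enc <- model$encoders[[o]]
        Xb <- x[[o]][idx, , drop = FALSE]
        Z <- Xb %*% enc$W
        Z <- sweep(Z, 2, enc$b, "+")
        mu <- colMeans(Z)
        va <- colMeans(Z^2) - mu^2
        va[va < 0] <- 0
        enc$run_mean <- (1 - mom) * enc$run_mean + mom * mu
        enc$run_var <- (1 - mom) * enc$run_var + mom * va
        model$encoders[[o]] <- enc
        sdv <- sqrt(va + eps)
        xhat <- sweep(sweep(Z, 2, mu, "-"), 2, sdv, "/")
        A <- sweep(sweep(xhat, 2, enc$gamma, "*"), 2, enc$beta, "+")
        R <- pmax(A, 0)
        if (cfg$dropout > 0) {
          Dm <- matrix((stats::runif(B * K) < keep) / keep, B, K)
          Hj <- R * Dm
        } else {
          Dm <- NULL
          Hj <- R
        }
        H[, (j - 1) * K + seq_len(K)] <- Hj
        cache[[j]] <- list(Xb = Xb, xhat = xhat, sdv = sdv, A = A, Dm = Dm)
      }
      nrm <- sqrt(rowSums(H^2))
      safe <- ifelse(nrm > 0, nrm, 1)
      H2 <- H / safe
      logits <- H2 %*% model$head$W
      logits <- sweep(logits, 2, model$head$b, "+")
      if (binary) {
        p <- 1 / (1 + exp(-logits[, 1]))
        yb <- y_pos[idx]
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
        dlogits <- matrix((p - yb) / B, B, 1)
      } else {
        mx <- apply(logits, 1, max)
        el <- exp(logits - mx)
        P <- el / rowSums(el)
        Yb <- Yhot[idx, , drop = FALSE]
        loss <- -mean(log(pmax(rowSums(P * Yb), 1e-12)))
        dlogits <- (P - Yb) / B
      }
      if (!is.finite(loss))
        stop("training diverged (non-finite loss); lower learning_rate or check the inputs")
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      t_step <- t_step + 1L
      # backward: head (with weight decay), then through L2 normalization
      gW_head <- crossprod(H2, dlogits) + cfg$weight_decay * model$head$W
      gb_head <- colSums(dlogits)
      dH2 <- dlogits %*% t(model$head$W)
      dH <- (dH2 - H2 * rowSums(dH2 * H2)) / safe
      dH[nrm == 0, ] <- 0
      for (j in seq_len(nO)) {
        o <- model$omics_order[j]
        enc <- model$encoders[[o]]
        cj <- cache[[j]]
        dHj <- dH[, (j - 1) * K + seq_len(K), drop = FALSE]
        dR <- if (is.null(cj$Dm)) dHj else dHj * cj$Dm
        dA <- dR * (cj$A > 0)
        dgamma <- colSums(dA * cj$xhat)
        dbeta <- colSums(dA)
        dxhat <- sweep(dA, 2, enc$gamma, "*")
        # batch-norm backward (biased batch variance)
        sum_dx <- colSums(dxhat)
        sum_dxx <- colSums(dxhat * cj$xhat)
        dZ <- sweep(sweep(B * dxhat, 2, sum_dx, "-") -
                      sweep(cj$xhat, 2, sum_dxx, "*"),
                    2, B * cj$sdv, "/")
        gW <- crossprod(cj$Xb, dZ)
        gb <- colSums(dZ)
        for (p in c("W", "b", "gamma", "beta")) {
          g <- switch(p, W = gW, b = gb, gamma = dgamma, beta = dbeta)
          up <- adam_step(enc[[p]], g, st[[paste(o, p)]], cfg$learning_rate, t_step)
          enc[[p]] <- up$param; st[[paste(o, p)]] <- up$state
        }
        model$encoders[[o]] <- enc
      }
      up <- adam_step(model$head$W, gW_head, st[["head W"]], cfg$learning_rate, t_step)
      model$head$W <- up$param; st[["head W"]] <- up$state
      up <- adam_step(model$head$b, gb_head, st[["head b"]], cfg$learning_rate, t_step)
      model$head$b <- up$param; st[["head b"]] <- up$state
    }
    if (ep_n == 0) stop("no trainable batch of size >= 2; increase the sample count")
    loss_history[epoch] <- ep_loss / ep_n
  }
  model$trained <- TRUE
  model$loss_history <- loss_history
  model$call <- match.call()
  model
}

#' Predict from a fitted late-integration model
#'
#' Evaluation-mode forward pass: dropout off, batch normalization uses the
#' stored running statistics, so repeated calls are identical.
#'
#' @param object An `omixnet`.
#' @param newdata Named list: omics type -> matrix (samples x features)
#'   matching the training widths.
#' @param type `"class"` (default) for predicted labels, `"prob"` for an
#'   `n x n_classes` probability matrix whose rows sum to 1 (binary models
#'   return columns `[p, 1 - p]` in class order, positive class first).
#' @param threshold Positive-class probability threshold for binary class
#'   prediction; defaults to the config's `decision_threshold`. `p >=
#'   threshold` predicts the positive class. Multiclass uses argmax with
#'   first-index tie-break.
#' @param ... Unused.
#' @return Factor of classes or probability matrix, per `type`.
#' @export
predict.omixnet <- function(object, newdata, type = c("class", "prob"),
                            threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) threshold <- object$config$decision_threshold
  H2 <- encode_integrate(object, newdata)
  logits <- H2 %*% object$head$W
  logits <- sweep(logits, 2, object$head$b, "+")
  if (object$task == "binary") {
    p <- 1 / (1 + exp(-logits[, 1]))
    probs <- cbind(p, 1 - p)
  } else {
    mx <- apply(logits, 1, max)
    el <- exp(logits - mx)
    probs <- el / rowSums(el)
  }
  colnames(probs) <- object$classes
  rownames(probs) <- rownames(newdata[[object$omics_order[1]]])
  if (type == "prob") return(probs)
  cls <- if (object$task == "binary") {
    ifelse(probs[, 1] >= threshold, object$classes[1], object$classes[2])
  } else {
    object$classes[max.col(probs, ties.method = "first")]
  }
  factor(cls, levels = object$classes)
}

#' @export
print.omixnet <- function(x, ...) {
  cat(sprintf("<omixnet %s classifier (%s)>\n",
              x$task, if (x$trained) "trained" else "untrained"))
  cat("  encoders: ",
      paste(sprintf("%s (%d -> %d)", x$omics_order, x$input_dims, x$config$hidden_dim),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  integrated width: %d; classes: %s\n",
              x$config$hidden_dim * length(x$omics_order),
              paste(x$classes, collapse = ", ")))
  if (x$trained)
    cat(sprintf("  final training loss: %.4f after %d epochs\n",
                utils::tail(x$loss_history, 1), length(x$loss_history)))
  invisible(x)
}

#' @export
summary.omixnet <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$encoders, function(e)
    length(e$W) + length(e$b) + length(e$gamma) + length(e$beta), 0)) +
    length(object$head$W) + length(object$head$b)
  cat(sprintf("  parameters: %d; dropout %.2f; weight decay %g; lr %g; batch %d\n",
              n_par, object$config$dropout, object$config$weight_decay,
              object$config$learning_rate, object$config$batch_size))
  if (object$trained && length(object$loss_history) >= 2)
    cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                object$loss_history[1], utils::tail(object$loss_history, 1),
                length(object$loss_history)))
  invisible(object)
}

#' @export
coef.omixnet <- function(object, ...) {
  list(head = object$head,
       encoders = lapply(object$encoders, function(e) e[c("W", "b", "gamma", "beta")]))
}

# ---- checkpointing ----------------------------------------------------------

CHECKPOINT_FORMAT <- "omixnet-checkpoint/1"

#' Save / load a model checkpoint
#'
#' Serializes the configuration, class order, weights, batch-norm statistics
#' and (when present) the preprocessing recipe to a single versioned JSON
#' file.
#'
#' @param model An `omixnet`.
#' @param path Checkpoint file path.
#' @export
save_omixnet <- function(model, path) {
  stopifnot(inherits(model, "omixnet"))
  payload <- list(
    format = CHECKPOINT_FORMAT,
    config = unclass(model$config),
    classes = model$classes, task = model$task,
    omics_order = model$omics_order,
    input_dims = as.list(model$input_dims),
    feature_names = model$feature_names,
    trained = model$trained, seed = model$seed,
    loss_history = model$loss_history,
    encoders = lapply(model$encoders, function(e)
      list(W = e$W, b = e$b, gamma = e$gamma, beta = e$beta,
           run_mean = e$run_mean, run_var = e$run_var)),
    head = list(W = model$head$W, b = model$head$b),
    preproc = attr(model, "preproc"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_omixnet
#' @return `load_omixnet()` returns the restored `omixnet` object.
#' @export
load_omixnet <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, CHECKPOINT_FORMAT))
    stop("unrecognised checkpoint format: ", p$format %||% "<missing>")
  cfg <- do.call(omixnet_config, p$config[names(p$config) %in% names(formals(omixnet_config))])
  dims <- unlist(p$input_dims)
  model <- build_omixnet(dims, p$classes, cfg, seed = p$seed %||% 1L)
  for (o in model$omics_order) {
    e <- p$encoders[[o]]
    K <- cfg$hidden_dim
    model$encoders[[o]] <- list(
      W = matrix(unlist(e$W), dims[[o]], K), b = as.numeric(e$b),
      gamma = as.numeric(e$gamma), beta = as.numeric(e$beta),
      run_mean = as.numeric(e$run_mean), run_var = as.numeric(e$run_var))
  }
  n_out <- if (model$task == "binary") 1L else length(p$classes)
  model$head <- list(W = matrix(unlist(p$head$W), ncol = n_out), b = as.numeric(p$head$b))
  model$feature_names <- p$feature_names
  model$trained <- isTRUE(p$trained)
  model$loss_history <- as.numeric(p$loss_history)
  if (!is.null(p$preproc)) attr(model, "preproc") <- p$preproc
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
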