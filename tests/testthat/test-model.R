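test_that("three equal-width encoders integrate to a 3K representation", {
  cfg <- omixnet_config(hidden_dim = 64)
  m <- build_omixnet(c(mrna = 30, methylation = 25, cnv = 20),
                     c("a", "b"), cfg, seed = 1)
  expect_equal(ncol(m$head$W) * nrow(m$head$W), 192 * 1)
  expect_equal(nrow(m$head$W), 3 * 64)
  m1 <- build_omixnet(c(mrna = 30), c("a", "b"), cfg, seed = 1)
  expect_equal(nrow(m1$head$W), 64)
  expect_error(build_omixnet(list(), c("a", "b"), cfg), "at least one omics")
})

test_that("weight initialization is reproducible from the seed", {
  a <- build_omixnet(c(mrna = 10, cnv = 8), c("a", "b", "c"), seed = 77)
  b <- build_omixnet(c(mrna = 10, cnv = 8), c("a", "b", "c"), seed = 77)
  expect_identical(a$encoders, b$encoders)
  expect_identical(a$head, b$head)
  d <- build_omixnet(c(mrna = 10, cnv = 8), c("a", "b", "c"), seed = 78)
  expect_false(identical(a$head$W, d$head$W))
})

test_that("integrated rows have unit L2 norm and a canonical omics order", {
  set.seed(2)
  m <- build_omixnet(c(mrna = 12, methylation = 9, cnv = 7), c("a", "b"),
                     omixnet_config(hidden_dim = 8), seed = 5)
  batch <- list(cnv = matrix(runif(35), 5, 7),
                mrna = matrix(runif(60), 5, 12),
                methylation = matrix(runif(45), 5, 9))
  H <- encode_integrate(m, batch)
  expect_equal(dim(H), c(5L, 24L))
  nrm <- sqrt(rowSums(H^2))
  nonzero <- nrm > 0
  expect_true(all(abs(nrm[nonzero] - 1) < 1e-6))
  # input mapping order must not matter
  H2 <- encode_integrate(m, batch[c("mrna", "methylation", "cnv")])
  expect_identical(H, H2)
  expect_error(encode_integrate(m, list(mrna = batch$mrna)), "lacks omics")
  bad <- batch; bad$cnv <- bad$cnv[, 1:3]
  expect_error(encode_integrate(m, bad), "cnv")
})

test_that("L2 normalization reproduces the 3-4-5 example and zero rows stay zero", {
  H <- rbind(c(3, 4, 0, 0), c(0, 0, 0, 0))
  Hn <- omixnet:::l2_normalize_rows(H)
  expect_equal(Hn[1, ], c(0.6, 0.8, 0, 0))
  expect_equal(Hn[2, ], rep(0, 4))
})

test_that("sampling weights are reciprocal class counts and balance draws", {
  counts <- c(luminal_A = 277, luminal_B = 40, her2_pos = 11, tnbc = 70, unclear = 208)
  y <- factor(rep(names(counts), counts), levels = names(counts))
  w <- compute_sampling_weights(y)
  for (cl in names(counts))
    expect_equal(unique(w[y == cl]), 1 / counts[[cl]])
  # balanced two-class data: uniform weights
  expect_equal(unique(compute_sampling_weights(rep(c("a", "b"), 50))), 1 / 50)
  # 10,000 weighted draws from counts {90, 10}: each class 5000 +/- 3 sigma
  set.seed(1)
  y2 <- rep(c("big", "small"), c(90, 10))
  draws <- sample(y2, 10000, replace = TRUE, prob = compute_sampling_weights(y2))
  expect_lt(abs(sum(draws == "big") - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("training separates linearly separable classes and is seed-deterministic", {
  sim <- tiny_dataset(seed = 17, classes = c(luminal_A = 100, tnbc = 100),
                      n_genes = 200, effect_size = 3, missing_rate = 0)
  x <- as_model_input(sim$dataset, k = 50)
  y <- droplevels(sim$dataset$labels)
  cfg <- omixnet_config(epochs = 30, hidden_dim = 16)
  fit <- omixnet(x, y, cfg, seed = 4)
  pred <- predict(fit, x)
  expect_gte(balanced_accuracy(as.integer(y) == 1, as.integer(pred) == 1), 0.99)
  fit2 <- omixnet(x, y, cfg, seed = 4)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$head, fit2$head)
  fit3 <- omixnet(x, y, cfg, seed = 5)
  expect_false(identical(fit$loss_history, fit3$loss_history))
})

test_that("predicted probabilities are normalized and eval-mode deterministic", {
  sim <- tiny_dataset(seed = 19, classes = c(luminal_A = 30, luminal_B = 30, tnbc = 30),
                      n_genes = 120, missing_rate = 0)
  x <- as_model_input(sim$dataset, k = 40)
  y <- droplevels(sim$dataset$labels)
  fit <- omixnet(x, y, omixnet_config(epochs = 10, hidden_dim = 8), seed = 2)
  p <- predict(fit, x, type = "prob")
  expect_equal(dim(p), c(90L, 3L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_identical(p, predict(fit, x, type = "prob"))
  # zero head: exactly uniform probabilities
  fit$head$W[] <- 0; fit$head$b[] <- 0
  pu <- predict(fit, x, type = "prob")
  expect_true(all(abs(pu - 1 / 3) < 1e-12))
})

test_that("class prediction applies the documented threshold and tie-breaks", {
  m <- build_omixnet(c(mrna = 2), c("pos", "neg"), omixnet_config(hidden_dim = 2), seed = 1)
  # force p = 0.5 exactly: zero head gives logit 0
  m$head$W[] <- 0; m$head$b[] <- 0
  x <- list(mrna = matrix(runif(6), 3, 2))
  expect_true(all(predict(m, x) == "pos"))       # p >= threshold is positive
  mm <- build_omixnet(c(mrna = 2), c("a", "b", "c"), omixnet_config(hidden_dim = 2), seed = 1)
  mm$head$W[] <- 0; mm$head$b[] <- c(0, 1, 1)    # tie between b and c
  expect_true(all(predict(mm, x) == "b"))        # first-index tie-break
  expect_true(all(predict(mm, x, type = "prob")[, "b"] ==
                    predict(mm, x, type = "prob")[, "c"]))
})

test_that("checkpoints round-trip the model bit-faithfully for prediction", {
  sim <- tiny_dataset(seed = 23, classes = c(luminal_A = 25, tnbc = 25),
                      n_genes = 80, missing_rate = 0)
  x <- as_model_input(sim$dataset, k = 30)
  y <- droplevels(sim$dataset$labels)
  fit <- omixnet(x, y, omixnet_config(epochs = 5, hidden_dim = 8), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_omixnet(fit, f)
  back <- load_omixnet(f)
  expect_equal(predict(back, x, type = "prob"), predict(fit, x, type = "prob"))
  expect_identical(back$classes, fit$classes)
  expect_error(load_omixnet({
    bad <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(format = "other/9"), bad, auto_unbox = TRUE)
    bad
  }), "format")
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- list(mrna = matrix(runif(20), 10, 2))
  expect_error(omixnet(x, factor(rep("a", 10))), "two classes")
  expect_error(omixnet(list(mrna = matrix(1, 1, 2)), factor("a")), "two")
  fit_x <- list(mrna = matrix(runif(8), 4, 2))
  fit <- omixnet(fit_x, factor(c("a", "a", "b", "b")),
                 omixnet_config(epochs = 2, hidden_dim = 2, dropout = 0), seed = 1)
  expect_error(predict(fit, list(mrna = matrix(1, 2, 5))), "width mismatch")
})
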