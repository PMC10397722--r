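# Small separable fixture shared by the model-contract tests: two classes
# with disjoint marker blocks, plenty of signal, modest size so every model
# trains in well under a second (CNN a few seconds).
separable_fixture <- function(n_per_class = 30, F = 80, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * F), n, F,
              dimnames = list(sprintf("s%03d", 1:n),
                              sprintf("ENSG%05d", 1:F)))
  w <- max(1, F %/% 8)
  x[1:n_per_class, 1:w] <- x[1:n_per_class, 1:w] + 3
  x[(n_per_class + 1):n, (w + 1):(2 * w)] <-
    x[(n_per_class + 1):n, (w + 1):(2 * w)] + 3
  labeled_dataset(x, rep(c("tumA", "tumB"), each = n_per_class))
}

test_that("one-hot encoding is exact and invertible", {
  oh <- one_hot_encode(c("A", "B", "A"), c("A", "B"))
  expect_equal(unname(oh), rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_equal(rowSums(oh), rep(1, 3))
  expect_identical(colnames(oh)[max.col(oh)], c("A", "B", "A"))
  expect_error(one_hot_encode(c("A", "C"), c("A", "B")), "C")
})

test_that("split_dataset partitions by the stated fractions", {
  ds <- separable_fixture(n_per_class = 50, F = 10)   # 100 samples
  sp <- split_dataset(ds, split_spec(seed = 4))
  expect_equal(vapply(sp, function(d) nrow(d$x), numeric(1)),
               c(train = 80, val = 10, test = 10))

  # determinism, disjointness, union — over several seeds and odd sizes
  for (seed in 1:5) {
    ds2 <- separable_fixture(n_per_class = 26 + seed, F = 8, seed = seed)
    a <- split_dataset(ds2, split_spec(seed = seed))
    b <- split_dataset(ds2, split_spec(seed = seed))
    expect_identical(lapply(a, `[[`, "labels"), lapply(b, `[[`, "labels"))
    ids <- unlist(lapply(a, function(d) rownames(d$x)), use.names = FALSE)
    expect_equal(sort(ids), sort(rownames(ds2$x)))   # union, no overlap
    # stratified: class share of every partition within 1 of proportional
    for (part in a) {
      for (k in ds2$classes) {
        got <- sum(part$labels == k)
        ideal <- sum(ds2$labels == k) * nrow(part$x) / nrow(ds2$x)
        expect_lte(abs(got - ideal), 1)
      }
    }
  }

  expect_error(split_spec(c(0.8, 0.1, 0.2)), "sum to 1")
  tiny <- labeled_dataset(matrix(rnorm(8), 4, 2,
                                 dimnames = list(paste0("s", 1:4),
                                                 c("f1", "f2"))),
                          c("A", "A", "A", "B"))
  expect_error(split_dataset(tiny, split_spec()), "class too small.*B")
})

test_that("all three model kinds honour the shared predict contract", {
  ds <- separable_fixture()
  sp <- split_dataset(ds, split_spec(c(0.6, 0.2, 0.2), seed = 2))
  specs <- list(
    cnn = model_spec("cnn1d", seed = 3, epochs = 50, patience = 10,
                     conv_filters = c(16L, 32L), kernel_size = 8L,
                     dense_units = 64L),
    rf = model_spec("random_forest", seed = 3, n_trees = 40),
    lr = model_spec("logistic_regression", seed = 3))
  for (nm in names(specs)) {
    m <- train_model(specs[[nm]], sp$train, sp$val)
    pr <- predict(m, sp$test$x)
    expect_equal(rowSums(pr$probabilities), rep(1, nrow(sp$test$x)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(colnames(pr$probabilities), m$classes)
    expect_gte(mean(pr$label == sp$test$labels), 0.9)
    # pure function: repeated calls identical
    expect_identical(pr$probabilities, predict(m, sp$test$x)$probabilities)
    # fingerprint mismatch fails loudly
    wrong <- sp$test$x[, c(2:ncol(sp$test$x), 1)]
    expect_error(predict(m, wrong), "fingerprint mismatch")
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- separable_fixture(n_per_class = 20, F = 60)
  sp <- split_dataset(ds, split_spec(c(0.6, 0.2, 0.2), seed = 5))
  spec <- model_spec("cnn1d", seed = 9, epochs = 6, patience = 3,
                     conv_filters = c(8L, 8L), kernel_size = 8L,
                     dense_units = 16L)
  m1 <- train_model(spec, sp$train, sp$val)
  m2 <- train_model(spec, sp$train, sp$val)
  expect_identical(predict(m1, sp$test$x)$probabilities,
                   predict(m2, sp$test$x)$probabilities)
  rf1 <- train_model(model_spec("random_forest", seed = 9, n_trees = 25),
                     sp$train)
  rf2 <- train_model(model_spec("random_forest", seed = 9, n_trees = 25),
                     sp$train)
  expect_identical(predict(rf1, sp$test$x)$probabilities,
                   predict(rf2, sp$test$x)$probabilities)
})

test_that("label-permuted training collapses to chance", {
  ds <- separable_fixture(n_per_class = 40, F = 40, seed = 11)
  set.seed(13)
  perm <- ds
  perm$labels <- sample(ds$labels)
  perm$onehot <- one_hot_encode(perm$labels, perm$classes)
  sp <- split_dataset(perm, split_spec(c(0.6, 0.2, 0.2), seed = 13))
  lr <- train_model(model_spec("logistic_regression", seed = 13), sp$train)
  acc <- mean(predict(lr, sp$test$x)$label == sp$test$labels)
  # binomial 99% band around 1/K for the held-out size
  n <- nrow(sp$test$x)
  band <- 2.576 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(acc - 0.5), band + 1e-9)
})

test_that("duplicating every training sample leaves LR/RF predictions stable", {
  ds <- separable_fixture(n_per_class = 15, F = 30, seed = 21)
  dup <- labeled_dataset(rbind(ds$x, ds$x), c(ds$labels, ds$labels))
  probe <- separable_fixture(n_per_class = 10, F = 30, seed = 22)$x
  lr1 <- train_model(model_spec("logistic_regression", seed = 1), ds)
  lr2 <- train_model(model_spec("logistic_regression", seed = 1), dup)
  expect_equal(predict(lr1, probe)$probabilities,
               predict(lr2, probe)$probabilities, tolerance = 1e-4)
  rf1 <- train_model(model_spec("random_forest", seed = 1, n_trees = 30), ds)
  rf2 <- train_model(model_spec("random_forest", seed = 1, n_trees = 30), dup)
  expect_identical(predict(rf1, probe)$label, predict(rf2, probe)$label)
})

test_that("models round-trip through save/load", {
  ds <- separable_fixture(n_per_class = 12, F = 30, seed = 31)
  sp <- split_dataset(ds, split_spec(c(0.6, 0.2, 0.2), seed = 31))
  m <- train_model(model_spec("random_forest", seed = 31, n_trees = 20),
                   sp$train)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(predict(m2, sp$test$x)$probabilities,
               predict(m, sp$test$x)$probabilities, tolerance = 1e-6)

  writeLines("not a model", p)
  expect_error(load_model(p), "cannot load|valid trained model")

  # wrong feature space still rejected at predict time after a reload
  expect_error(predict(m2, sp$test$x[, 1:10]), "fingerprint")
})

test_that("degenerate training inputs error early", {
  ds <- separable_fixture(n_per_class = 6, F = 20)
  empty <- ds; empty$x <- ds$x[0, , drop = FALSE]; empty$labels <- character(0)
  empty$onehot <- ds$onehot[0, , drop = FALSE]
  expect_error(train_model(model_spec("logistic_regression"), empty), "empty")
  one <- labeled_dataset(ds$x, rep("only", nrow(ds$x)))
  expect_error(train_model(model_spec("logistic_regression"), one),
               "at least 2 classes")
  expect_error(train_model(model_spec("cnn1d"), ds, NULL), "validation")
  expect_error(model_spec("cnn1d", nonsense = 2), "unknown")
})
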