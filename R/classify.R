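#' One-hot encode class labels
#'
#' @param labels character vector of class labels.
#' @param class_list ordered class vocabulary; every label must occur in it.
#' @return binary matrix (samples x K) with a single 1 per row at the
#'   label's class index; columns named by class.
#' @export
one_hot_encode <- function(labels, class_list) {
  i <- match(labels, class_list)
  if (anyNA(i))
    stop("label not in class list: ", labels[is.na(i)][1])
  m <- matrix(0L, length(labels), length(class_list),
              dimnames = list(names(labels), class_list))
  m[cbind(seq_along(i), i)] <- 1L
  m
}

#' Assemble a labeled dataset
#'
#' Binds a feature-space-aligned expression matrix to its class labels and
#' one-hot encoding. Samples are rows, features columns (the transpose of
#' the genes-by-samples file orientation), feature order is the feature
#' space order and is fingerprinted so that models can refuse misaligned
#' inputs later.
#'
#' @param x an [expr_matrix()] in `log10_tpm` (genes x samples), typically
#'   the output of [project_to_feature_space()] then [log10_transform()];
#'   or a plain samples-by-features matrix with feature column names.
#' @param labels named character vector (names = sample ids) or unnamed
#'   vector aligned with the samples.
#' @param class_list optional ordered class vocabulary; defaults to the
#'   sorted unique labels.
#' @return object of class `labeled_dataset` with elements `x` (samples x
#'   F), `labels`, `onehot`, `classes`, `fingerprint`.
#' @export
labeled_dataset <- function(x, labels, class_list = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (x$unit != "log10_tpm")
      stop("labeled datasets are built on log10_tpm matrices, got ", x$unit)
    m <- t(x$values)
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(names(labels))) {
    if (!all(rownames(m) %in% names(labels)))
      stop("labels missing for some samples")
    labels <- labels[rownames(m)]
  } else if (length(labels) != nrow(m)) {
    stop("labels length does not match sample count")
  }
  if (is.null(class_list)) class_list <- sort(unique(unname(labels)))
  structure(list(x = m, labels = unname(labels),
                 onehot = one_hot_encode(unname(labels), class_list),
                 classes = class_list,
                 fingerprint = feature_fingerprint(colnames(m))),
            class = "labeled_dataset")
}

#' @exportS3Method base::print
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$classes)))
  invisible(x)
}

#' Train/validation/test split specification
#'
#' @param fractions numeric length-3 vector `(train, val, test)` summing to
#'   1 within 1e-9; default `c(0.8, 0.1, 0.1)`.
#' @param seed RNG seed for the shuffle.
#' @param stratified preserve class proportions per partition (default
#'   `TRUE`; set `FALSE` for a fully random split).
#' @return list of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       stratified = TRUE) {
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be three values in (0,1)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "split_spec")
}

#' Split a labeled dataset into train/validation/test partitions
#'
#' Partitions are disjoint and their union is the input; partition sizes
#' match the requested fractions up to integer rounding, and in stratified
#' mode every class's share of each partition is within one sample of
#' proportional. Leftover units from rounding are placed by largest
#' remainder, ties going to the globally most under-filled partition, so
#' e.g. 100 samples at the default fractions always split 80/10/10.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [split_spec()].
#' @return named list of `labeled_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "split_spec"))
  n <- nrow(dataset$x)
  if (n < length(dataset$classes)) stop("fewer samples than classes")
  fr <- spec$fractions
  target <- c(round(n * fr[1]), round(n * fr[2]))
  target <- c(target, n - sum(target))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  part <- integer(n)
  if (!spec$stratified) {
    ord <- sample.int(n)
    part[ord] <- rep.int(1:3, times = target)
  } else {
    alloc_tot <- c(0, 0, 0)
    for (k in dataset$classes) {
      idx <- which(dataset$labels == k)
      nk <- length(idx)
      if (nk < 3)
        stop("class too small for a stratified 3-way split: ", k)
      ideal <- nk * fr
      base <- floor(ideal)
      rem <- ideal - base
      extra <- nk - sum(base)
      take <- base
      if (extra > 0) {
        deficit <- target - (alloc_tot + base)
        ord3 <- order(-rem, -deficit)
        take[ord3[seq_len(extra)]] <- take[ord3[seq_len(extra)]] + 1
      }
      idx <- sample(idx)
      part[idx] <- rep.int(1:3, times = take)
      alloc_tot <- alloc_tot + take
    }
  }
  subset_ld <- function(i) {
    structure(list(x = dataset$x[i, , drop = FALSE],
                   labels = dataset$labels[i],
                   onehot = dataset$onehot[i, , drop = FALSE],
                   classes = dataset$classes,
                   fingerprint = dataset$fingerprint),
              class = "labeled_dataset")
  }
  list(train = subset_ld(which(part == 1)),
       val = subset_ld(which(part == 2)),
       test = subset_ld(which(part == 3)))
}

#' Model specification
#'
#' Defaults for the 1D-CNN make the unstated interior of the published
#' architecture explicit and overridable: two conv blocks (32 then 64
#' filters, kernel 16, stride 1, max-pool 4, ReLU), dropout 0.3 on the
#' flattened activations, a 128-unit ReLU dense layer and a softmax head;
#' Adam at 1e-3, batch 32, early-stopping patience 5 within at most 50
#' epochs. The random forest and logistic regression are the conventional
#' library-default baselines: 100 Gini trees at `mtry = floor(sqrt(F))`,
#' and ridge-penalised multinomial regression at a fixed small lambda.
#'
#' @param kind `"cnn1d"`, `"random_forest"` or `"logistic_regression"`.
#' @param seed seed fanned out to initialisation, shuffling and resampling.
#' @param ... overrides of the kind-specific defaults listed above
#'   (`conv_filters`, `kernel_size`, `pool_size`, `dropout`, `dense_units`,
#'   `epochs`, `batch_size`, `learning_rate`, `patience`, `min_epochs` —
#'   a warm-up during which early stopping stays disarmed; `n_trees`,
#'   `mtry`, `max_depth`, `min_node`; `lambda`).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("cnn1d", "random_forest",
                                "logistic_regression"),
                       seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    cnn1d = list(conv_filters = c(32L, 64L), kernel_size = 16L,
                 pool_size = 4L, dropout = 0.3, dense_units = 128L,
                 epochs = 50L, batch_size = 32L, learning_rate = 1e-3,
                 patience = 5L, min_epochs = 10L),
    random_forest = list(n_trees = 100L, mtry = NULL, max_depth = 25L,
                         min_node = 2L),
    logistic_regression = list(lambda = 1e-3))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "model_spec")
}

#' Train a tumor-type classifier
#'
#' All three model kinds share the same contract: they consume a training
#' (and, for the CNN's early stopping, a validation) [labeled_dataset()]
#' and expose identical [predict()] behaviour. The CNN trains by mini-batch
#' Adam on categorical cross-entropy, keeping the weights of the epoch with
#' the lowest validation loss.
#'
#' @param spec a [model_spec()].
#' @param train training `labeled_dataset`.
#' @param val validation `labeled_dataset`; required for `cnn1d`, unused by
#'   the baselines.
#' @return object of class `trained_model` carrying the fitted predictor,
#'   the class list, the feature fingerprint and training metadata.
#' @importFrom glmnet glmnet
#' @export
train_model <- function(spec, train, val = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "labeled_dataset"))
  if (nrow(train$x) == 0) stop("empty training partition")
  if (length(train$classes) < 2) stop("need at least 2 classes")
  if (!is.null(val)) {
    if (!identical(val$classes, train$classes))
      stop("train and validation class lists differ")
    if (!identical(val$fingerprint, train$fingerprint))
      stop("train and validation feature spaces differ")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  meta <- list(seed = spec$seed, n_train = nrow(train$x))
  fit <- switch(spec$kind,
    cnn1d = {
      if (is.null(val) || nrow(val$x) == 0)
        stop("cnn1d requires a non-empty validation partition for early stopping")
      out <- cnn_train(train$x, train$onehot, val$x, val$onehot, spec)
      meta$epochs_run <- out$epochs_run
      meta$best_epoch <- out$best_epoch
      meta$val_accuracy <- out$val_acc
      out
    },
    random_forest = {
      y <- match(train$labels, train$classes)
      rf_fit(train$x, y, length(train$classes), n_trees = spec$n_trees,
             mtry = spec$mtry, max_depth = spec$max_depth,
             min_node = spec$min_node, seed = spec$seed)
    },
    logistic_regression = {
      set.seed(spec$seed)
      glmnet::glmnet(train$x, factor(train$labels, levels = train$classes),
                     family = "multinomial", alpha = 0,
                     lambda = spec$lambda, standardize = FALSE)
    })
  structure(list(kind = spec$kind, fit = fit, classes = train$classes,
                 fingerprint = train$fingerprint,
                 n_features = ncol(train$x), spec = spec, meta = meta),
            class = "trained_model")
}

#' @exportS3Method base::print
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model[%s]: %d features, %d classes (%s)\n", x$kind,
              x$n_features, length(x$classes),
              paste(utils::head(x$classes, 6), collapse = ", ")))
  invisible(x)
}

#' Predict tumor types with a trained model
#'
#' @param object a [train_model()] result.
#' @param newdata an [expr_matrix()] in `log10_tpm` aligned to the model's
#'   feature space (genes x samples), or a samples-by-features matrix with
#'   feature column names. A feature-fingerprint mismatch — wrong genes,
#'   wrong order, or an unprojected matrix — is an error, never a silent
#'   misprediction.
#' @param ... unused.
#' @return list with `probabilities` (samples x K, rows summing to 1) and
#'   `label` (argmax class per sample, ties broken by class-list order).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) {
    if (newdata$unit != "log10_tpm")
      stop("predict expects log10_tpm input, got ", newdata$unit)
    m <- t(newdata$values)
  } else {
    m <- as.matrix(newdata)
  }
  fp <- feature_fingerprint(colnames(m))
  if (!identical(fp, object$fingerprint))
    stop(sprintf(
      "feature fingerprint mismatch: model expects %s, received %s (project the matrix onto the model's feature space first)",
      object$fingerprint, fp))
  probs <- switch(object$kind,
    cnn1d = cnn_predict_probs(m, object$fit$params, object$spec),
    random_forest = rf_predict_probs(object$fit, m),
    logistic_regression = {
      p <- predict(object$fit, newx = m, type = "response")
      cls <- dimnames(p)[[2]]
      pm <- matrix(p, nrow(m), length(cls), dimnames = list(NULL, cls))
      pm[, object$classes, drop = FALSE]
    })
  dimnames(probs) <- list(rownames(m), object$classes)
  lab <- object$classes[max.col(probs, ties.method = "first")]
  names(lab) <- rownames(m)
  list(probabilities = probs, label = lab)
}

#' Save / load a trained model
#'
#' Serialises the full model object (weights, class list, feature
#' fingerprint, spec and metadata); a reloaded model yields identical
#' predictions. Corrupted or foreign files fail at load, and a model loaded
#' against the wrong feature space still fails at [predict()] via the
#' fingerprint check.
#'
#' @param model a `trained_model`.
#' @param path file path (RDS serialisation).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot load model from ", path, ": ", conditionMessage(e)))
  if (!inherits(obj, "trained_model") || is.null(obj$fingerprint))
    stop("file does not contain a valid trained model: ", path)
  obj
}
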