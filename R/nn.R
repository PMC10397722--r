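# 1D convolutional network for expression vectors, implemented on base R
# matrix algebra (BLAS does the heavy lifting). The network is the standard
# expression-classifier shape: stacked valid-mode 1D conv blocks
# (conv -> ReLU -> max-pool) over the ordered gene axis, a flatten,
# dropout, one ReLU dense layer and a softmax head, trained with Adam on
# categorical cross-entropy with early stopping on validation loss.
#
# Tensors are R arrays (batch, length, channels); convolutions are computed
# by im2col: unfold the k-window neighbourhoods into a
# (batch*out_len, k*channels) matrix and multiply by the
# (k*channels, filters) weight matrix.

conv1d_forward <- function(x, w, b, k) {
  dm <- dim(x); B <- dm[1]; L <- dm[2]; cin <- dm[3]
  lout <- L - k + 1
  if (lout < 1) stop(sprintf(
    "conv kernel (%d) larger than its input length (%d); use a smaller kernel or more features", k, L))
  xc <- matrix(0, B * lout, k * cin)
  for (j in seq_len(k))
    xc[, ((j - 1) * cin + 1):(j * cin)] <- x[, j:(j + lout - 1), , drop = FALSE]
  y <- xc %*% w
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(B, lout, ncol(w))), xc = xc, lout = lout)
}

conv1d_backward <- function(dy, cache, w, k, B, L, cin) {
  lout <- cache$lout
  dym <- matrix(dy, B * lout, dim(dy)[3])
  dw <- crossprod(cache$xc, dym)
  db <- colSums(dym)
  dxc <- tcrossprod(dym, w)
  dx <- array(0, c(B, L, cin))
  for (j in seq_len(k))
    dx[, j:(j + lout - 1), ] <- dx[, j:(j + lout - 1), , drop = FALSE] +
      array(dxc[, ((j - 1) * cin + 1):(j * cin)], c(B, lout, cin))
  list(dx = dx, dw = dw, db = db)
}

maxpool1d_forward <- function(x, p) {
  dm <- dim(x); B <- dm[1]; L <- dm[2]; ch <- dm[3]
  lout <- L %/% p
  if (lout < 1) stop("pool size larger than input length")
  idx <- seq(1, by = p, length.out = lout)
  y <- x[, idx, , drop = FALSE]
  arg <- array(1L, c(B, lout, ch))
  if (p > 1) for (j in 2:p) {
    cand <- x[, idx + (j - 1), , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(y = y, arg = arg, lin = L)
}

maxpool1d_backward <- function(dy, cache, p) {
  dm <- dim(dy); B <- dm[1]; lout <- dm[2]; ch <- dm[3]
  dx <- array(0, c(B, cache$lin, ch))
  idx <- seq(1, by = p, length.out = lout)
  for (j in seq_len(p))
    dx[, idx + (j - 1), ] <- dy * (cache$arg == j)
  dx
}

cnn_init <- function(n_features, n_classes, spec) {
  set.seed(spec$seed %% .Machine$integer.max)
  filters <- spec$conv_filters; k <- spec$kernel_size; p <- spec$pool_size
  params <- list(); cin <- 1L; len <- n_features
  for (i in seq_along(filters)) {
    fan_in <- k * cin
    params[[paste0("Wc", i)]] <- matrix(
      stats::rnorm(fan_in * filters[i], sd = sqrt(2 / fan_in)), fan_in, filters[i])
    params[[paste0("bc", i)]] <- rep(0, filters[i])
    len <- (len - k + 1) %/% p
    if (len < 1) stop("input too short for the configured conv/pool stack")
    cin <- filters[i]
  }
  flat <- len * cin
  params$Wd <- matrix(stats::rnorm(flat * spec$dense_units,
                                   sd = sqrt(2 / flat)), flat, spec$dense_units)
  params$bd <- rep(0, spec$dense_units)
  params$Wo <- matrix(stats::rnorm(spec$dense_units * n_classes,
                                   sd = sqrt(2 / spec$dense_units)),
                      spec$dense_units, n_classes)
  params$bo <- rep(0, n_classes)
  params
}

cnn_forward <- function(x, params, spec, dropout_mask = NULL) {
  # x: (batch, features) matrix
  B <- nrow(x)
  a <- array(x, c(B, ncol(x), 1L))
  caches <- list()
  cin <- 1L
  for (i in seq_along(spec$conv_filters)) {
    cv <- conv1d_forward(a, params[[paste0("Wc", i)]],
                         params[[paste0("bc", i)]], spec$kernel_size)
    relu_mask <- cv$y > 0
    h <- cv$y * relu_mask
    pl <- maxpool1d_forward(h, spec$pool_size)
    caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl,
                        lin = dim(a)[2], cin = cin)
    a <- pl$y
    cin <- spec$conv_filters[i]
  }
  flat <- matrix(a, B, prod(dim(a)[2:3]))
  if (!is.null(dropout_mask)) flat <- flat * dropout_mask
  zd <- sweep(flat %*% params$Wd, 2, params$bd, "+")
  hd <- zd * (zd > 0)
  zo <- sweep(hd %*% params$Wo, 2, params$bo, "+")
  zo <- zo - matrixStats::rowMaxs(zo)
  ez <- exp(zo)
  probs <- ez / rowSums(ez)
  list(probs = probs, caches = caches, flat = flat, hd = hd, zd = zd,
       pooled_dim = dim(a))
}

cnn_backward <- function(fw, y_onehot, params, spec, dropout_mask = NULL) {
  B <- nrow(y_onehot)
  grads <- list()
  dzo <- (fw$probs - y_onehot) / B
  grads$Wo <- crossprod(fw$hd, dzo)
  grads$bo <- colSums(dzo)
  dhd <- tcrossprod(dzo, params$Wo)
  dzd <- dhd * (fw$zd > 0)
  grads$Wd <- crossprod(fw$flat, dzd)
  grads$bd <- colSums(dzd)
  dflat <- tcrossprod(dzd, params$Wd)
  if (!is.null(dropout_mask)) dflat <- dflat * dropout_mask
  da <- array(dflat, fw$pooled_dim)
  for (i in rev(seq_along(spec$conv_filters))) {
    cc <- fw$caches[[i]]
    dh <- maxpool1d_backward(da, cc$pool, spec$pool_size)
    dh <- dh * cc$relu
    bk <- conv1d_backward(dh, cc$conv, params[[paste0("Wc", i)]],
                          spec$kernel_size, B, cc$lin, cc$cin)
    grads[[paste0("Wc", i)]] <- bk$dw
    grads[[paste0("bc", i)]] <- bk$db
    da <- bk$dx
  }
  grads
}

adam_step <- function(state, params, grads, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

cnn_loss <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

# Core training loop. x: (n, F); y_onehot: (n, K). Returns params + history.
cnn_train <- function(x, y_onehot, x_val, y_val, spec) {
  params <- cnn_init(ncol(x), ncol(y_onehot), spec)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- nrow(x)
  flat_dim <- nrow(params$Wd)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L; t <- 0L
  set.seed((spec$seed + 7L) %% .Machine$integer.max)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    tl <- 0
    for (bidx in batches) {
      xb <- x[bidx, , drop = FALSE]
      yb <- y_onehot[bidx, , drop = FALSE]
      mask <- NULL
      if (spec$dropout > 0)
        mask <- matrix(stats::rbinom(length(bidx) * flat_dim, 1,
                                     1 - spec$dropout) / (1 - spec$dropout),
                       length(bidx), flat_dim)
      fw <- cnn_forward(xb, params, spec, dropout_mask = mask)
      tl <- tl + cnn_loss(fw$probs, yb) * length(bidx)
      grads <- cnn_backward(fw, yb, params, spec, dropout_mask = mask)
      t <- t + 1L
      st <- adam_step(state, params, grads, spec$learning_rate, t)
      state <- st$state; params <- st$params
    }
    vp <- cnn_predict_probs(x_val, params, spec)
    vl <- cnn_loss(vp, y_val)
    va <- mean(max.col(vp, ties.method = "first") ==
                 max.col(y_val, ties.method = "first"))
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl / n,
                                         val_loss = vl, val_acc = va))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch, val_acc = va)
      wait <- 0L
    } else if (epoch > spec$min_epochs) {
      # early stopping only arms after the warm-up: the first epochs sit on
      # a near-uniform plateau where validation loss is uninformative
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  list(params = best$params, history = history, epochs_run = nrow(history),
       best_epoch = best$epoch, val_acc = best$val_acc)
}

cnn_predict_probs <- function(x, params, spec, batch = 256L) {
  out <- matrix(0, nrow(x), ncol(params$Wo))
  i <- 1L
  while (i <= nrow(x)) {
    j <- min(i + batch - 1L, nrow(x))
    out[i:j, ] <- cnn_forward(x[i:j, , drop = FALSE], params, spec)$probs
    i <- j + 1L
  }
  out
}
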