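# Random-forest classifier: bagged CART trees with Gini splits and
# sqrt(F) feature subsampling, leaf class distributions averaged over trees
# (the usual defaults of the field's reference implementations). Trees are
# stored as flat vectors and predictions routed level-by-level, so the only
# per-sample R loop is over tree depth.

grow_tree <- function(x, y_int, n_classes, mtry, max_depth, min_node) {
  n_nodes_max <- 2L * length(y_int) + 1L
  feature <- integer(n_nodes_max); threshold <- numeric(n_nodes_max)
  left <- integer(n_nodes_max); right <- integer(n_nodes_max)
  dist <- matrix(0, n_nodes_max, n_classes)
  n_nodes <- 0L

  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    n_nodes
  }

  build <- function(idx, depth) {
    node <- new_node()
    yk <- tabulate(y_int[idx], n_classes)
    dist[node, ] <<- yk / length(idx)
    pure <- max(yk) == length(idx)
    if (pure || length(idx) < min_node || depth >= max_depth) {
      feature[node] <<- 0L
      return(node)
    }
    sp <- best_split(x, y_int, idx, n_classes, mtry)
    if (is.null(sp)) {
      feature[node] <<- 0L
      return(node)
    }
    go_left <- x[idx, sp$feature] <= sp$threshold
    feature[node] <<- sp$feature
    threshold[node] <<- sp$threshold
    l <- build(idx[go_left], depth + 1L)
    r <- build(idx[!go_left], depth + 1L)
    left[node] <<- l; right[node] <<- r
    node
  }
  build(seq_along(y_int), 0L)
  list(feature = feature[seq_len(n_nodes)],
       threshold = threshold[seq_len(n_nodes)],
       left = left[seq_len(n_nodes)], right = right[seq_len(n_nodes)],
       dist = dist[seq_len(n_nodes), , drop = FALSE])
}

best_split <- function(x, y_int, idx, n_classes, mtry) {
  n <- length(idx)
  feats <- sample.int(ncol(x), mtry)
  best <- NULL; best_imp <- Inf
  y_node <- y_int[idx]
  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), y_node)] <- 1
  for (f in feats) {
    v <- x[idx, f]
    o <- order(v)
    vs <- v[o]
    cut_ok <- which(vs[-n] < vs[-1])   # split between distinct values only
    if (!length(cut_ok)) next
    cs <- apply(onehot[o, , drop = FALSE], 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
    nl <- seq_len(n - 1)
    left_cs <- cs[nl, , drop = FALSE]
    tot <- cs[n, ]
    right_cs <- sweep(-left_cs, 2, tot, "+")
    gl <- 1 - rowSums(left_cs^2) / nl^2
    gr <- 1 - rowSums(right_cs^2) / (n - nl)^2
    imp <- (nl * gl + (n - nl) * gr) / n
    i <- cut_ok[which.min(imp[cut_ok])]
    if (imp[i] < best_imp - 1e-12) {
      best_imp <- imp[i]
      best <- list(feature = f, threshold = (vs[i] + vs[i + 1]) / 2)
    }
  }
  best
}

rf_fit <- function(x, y_int, n_classes, n_trees = 100L, mtry = NULL,
                   max_depth = 25L, min_node = 2L, seed = 1L) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(x)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[boot, , drop = FALSE], y_int[boot], n_classes,
                            mtry, max_depth, min_node)
  }
  list(trees = trees, n_classes = n_classes, mtry = mtry)
}

rf_predict_probs <- function(fit, x) {
  n <- nrow(x)
  acc <- matrix(0, n, fit$n_classes)
  for (tr in fit$trees) {
    node <- rep(1L, n)
    active <- which(tr$feature[node] != 0L)
    while (length(active)) {
      f <- tr$feature[node[active]]
      th <- tr$threshold[node[active]]
      goes_left <- x[cbind(active, f)] <= th
      node[active] <- ifelse(goes_left, tr$left[node[active]],
                             tr$right[node[active]])
      active <- active[tr$feature[node[active]] != 0L]
    }
    acc <- acc + tr$dist[node, , drop = FALSE]
  }
  acc / length(fit$trees)
}
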