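# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately written in a different style from the package
# code (explicit loops, no shared helpers) so that agreement is evidence.

toy_counts <- function(genes = 4, samples = 3, seed = 42, prefix = "G") {
  set.seed(seed)
  m <- matrix(rpois(genes * samples, lambda = 50), genes, samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  expr_matrix(m, unit = "counts", species = "synthetic-A")
}

toy_annotation <- function(ids, lengths = NULL, biotype = "protein_coding",
                           seed = 7) {
  set.seed(seed)
  if (is.null(lengths)) lengths <- sample(500:5000, length(ids))
  data.frame(gene_id = ids, length_bp = lengths,
             biotype = rep_len(biotype, length(ids)),
             stringsAsFactors = FALSE)
}

write_tmp_gmt <- function(lines) {
  p <- withr::local_tempfile(fileext = ".gmt",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

# small, fast simulation shared by several test files
small_sim_config <- function(seed = 5, ...) {
  args <- list(
    samples_per_class = list(A = c(BLCA = 20, LGG = 8, HGG = 8, normal = 6),
                             B = c(BLCA = 12, LGG = 6, HGG = 8, normal = 4)),
    n_genes_one_to_one = 250, n_genes_one_to_many = 30,
    n_genes_species_specific = c(A = 20, B = 20),
    fraction_protein_coding = 0.9, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# ---- independent metric oracle (straight loops over the formulas) ----
oracle_report <- function(cm) {
  k <- nrow(cm)
  n <- sum(cm)
  prec <- rec <- f1 <- sup <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- 0; fn <- 0
    for (i in seq_len(k)) if (i != c) fp <- fp + cm[i, c]
    for (j in seq_len(k)) if (j != c) fn <- fn + cm[c, j]
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    sup[c] <- tp + fn
  }
  wp <- 0; wr <- 0; wf <- 0
  for (c in seq_len(k)) {
    wp <- wp + sup[c] * prec[c]
    wr <- wr + sup[c] * rec[c]
    wf <- wf + sup[c] * f1[c]
  }
  acc <- 0
  for (c in seq_len(k)) acc <- acc + cm[c, c]
  list(precision = prec, recall = rec, f1 = f1, support = sup,
       weighted = c(precision = wp / n, recall = wr / n, f1 = wf / n,
                    accuracy = acc / n))
}

random_confusion <- function(k, seed) {
  set.seed(seed)
  matrix(rpois(k * k, lambda = sample(0:6, k * k, replace = TRUE)), k, k,
         dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
}

# ---- independent ssGSEA oracle: literal walk down the ranking ----
oracle_ssgsea <- function(values, ids, set_ids, alpha) {
  stopifnot(length(values) == length(ids))
  n <- length(values)
  # ranking: expression descending, gene id ascending on ties
  ord <- order(-values, ids)
  rk <- rank(values, ties.method = "average")
  in_set <- ids %in% set_ids
  sum_w <- 0
  for (i in seq_len(n)) if (in_set[i]) sum_w <- sum_w + abs(rk[i])^alpha
  n_out <- n - sum(in_set)
  run_in <- 0; run_out <- 0; es <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    if (in_set[g]) run_in <- run_in + abs(rk[g])^alpha / sum_w
    else run_out <- run_out + 1 / n_out
    es <- es + (run_in - run_out)
  }
  unname(es)
}
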