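#' ssGSEA configuration
#'
#' @param alpha rank weight exponent (>= 0); 0.25 is the canonical
#'   single-sample GSEA weighting, 0 reduces the member ECDF to the
#'   unweighted empirical CDF.
#' @param n_permutations size of the random-gene-set null per (sample,
#'   set size); at least 100 for significance calls.
#' @param seed RNG seed for the permutation null.
#' @param normalize_scores divide all scores by the score range across the
#'   matrix (a display convenience; significance is computed on raw scores).
#' @return list of class `ssgsea_config`.
#' @export
ssgsea_config <- function(alpha = 0.25, n_permutations = 1000L, seed = 1L,
                          normalize_scores = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 normalize_scores = isTRUE(normalize_scores)),
            class = "ssgsea_config")
}

# Per-sample rank machinery shared by scoring and the permutation null.
# Ranks use average ties (zero-TPM ties are common) and the walk order is
# expression-descending with a stable gene-id tie-break, so scores depend
# on the expression values only through ranks: any strictly monotone
# per-sample transform leaves them unchanged.
ssgsea_sample_prep <- function(v, ids, alpha) {
  ord <- order(-v, ids, method = "radix")
  r <- rank(v, ties.method = "average")
  list(ord = ord, w = abs(r[ord])^alpha)
}

ssgsea_es <- function(prep, member_idx_in_ord) {
  n <- length(prep$w)
  m <- logical(n)
  m[member_idx_in_ord] <- TRUE
  win <- prep$w * m
  sumw <- sum(win)
  if (sumw == 0) return(NA_real_)
  p_in <- cumsum(win) / sumw
  p_out <- cumsum(!m) / (n - sum(m))
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression (descending); walking
#' down the ranking, a running sum accumulates the weighted ECDF of the
#' set's members (weight `|rank|^alpha`) minus the uniform ECDF of the
#' non-members, and the score is the sum of the running-sum values — the
#' integrated deviation form of ssGSEA. Scores are deterministic and
#' rank-based, hence identical for `tpm` and `log10_tpm` input.
#'
#' @param x an [expr_matrix()] (`tpm` or `log10_tpm`) or a plain
#'   genes-by-samples matrix with gene rownames.
#' @param gene_sets a [read_gmt()] collection or named list of id vectors.
#'   Sets with fewer than 2 members present in the matrix are skipped with
#'   a warning; a set covering every gene is an error (the non-member ECDF
#'   is undefined).
#' @param config an [ssgsea_config()].
#' @return samples-by-sets numeric score matrix.
#' @export
ssgsea_score <- function(x, gene_sets, config = ssgsea_config()) {
  v <- if (inherits(x, "expr_matrix")) {
    if (!x$unit %in% c("tpm", "log10_tpm"))
      stop("ssgsea expects tpm or log10_tpm input, got ", x$unit)
    x$values
  } else as.matrix(x)
  ids <- rownames(v)
  keep <- vapply(gene_sets, function(s) sum(ids %in% s), integer(1))
  if (any(keep >= nrow(v)))
    stop("gene set covers all genes in the matrix: ",
         names(gene_sets)[keep >= nrow(v)][1])
  small <- keep < 2
  if (any(small)) {
    warning("skipping gene set(s) with < 2 present members: ",
            paste(names(gene_sets)[small], collapse = ", "))
    gene_sets <- gene_sets[!small]
  }
  if (!length(gene_sets)) stop("no scorable gene sets")
  member_idx <- lapply(gene_sets, function(s) which(ids %in% s))
  scores <- matrix(NA_real_, ncol(v), length(gene_sets),
                   dimnames = list(colnames(v), names(gene_sets)))
  for (j in seq_len(ncol(v))) {
    prep <- ssgsea_sample_prep(v[, j], ids, config$alpha)
    pos_of_gene <- integer(nrow(v))
    pos_of_gene[prep$ord] <- seq_len(nrow(v))
    for (k in seq_along(member_idx))
      scores[j, k] <- ssgsea_es(prep, pos_of_gene[member_idx[[k]]])
  }
  if (config$normalize_scores) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' ssGSEA scores with permutation significance
#'
#' The null for a (sample, set) pair is the score distribution of
#' size-matched gene sets drawn uniformly from the matrix's gene universe;
#' nulls are shared across sets of equal size within a sample. The p-value
#' uses the plus-one estimator `p = (1 + #{|null| >= |observed|}) /
#' (n_perm + 1)` (so it is never exactly 0) and Benjamini-Hochberg
#' adjustment runs across all (sample, set) pairs jointly.
#'
#' @inheritParams ssgsea_score
#' @return list of class `ssgsea_result`: `scores`, `p_value`, `fdr`
#'   (all samples-by-sets), and `config`.
#' @export
ssgsea_significance <- function(x, gene_sets, config = ssgsea_config()) {
  if (config$n_permutations < 100)
    stop("n_permutations must be >= 100 for significance calls")
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  ids <- rownames(v)
  scores <- ssgsea_score(x, gene_sets, config)
  gene_sets <- gene_sets[colnames(scores)]
  sizes <- vapply(gene_sets, function(s) sum(ids %in% s), integer(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n_genes <- nrow(v)
  B <- config$n_permutations
  pvals <- matrix(NA_real_, nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  for (j in seq_len(nrow(scores))) {          # scores rows = samples
    prep <- ssgsea_sample_prep(v[, j], ids, config$alpha)
    for (sz in unique(sizes)) {
      null_es <- vapply(seq_len(B), function(b)
        ssgsea_es(prep, sample.int(n_genes, sz)), numeric(1))
      for (k in which(sizes == sz))
        pvals[j, k] <- (1 + sum(abs(null_es) >= abs(scores[j, k]))) / (B + 1)
    }
  }
  fdr <- matrix(stats::p.adjust(as.vector(pvals), method = "BH"),
                nrow(pvals), ncol(pvals), dimnames = dimnames(pvals))
  structure(list(scores = scores, p_value = pvals, fdr = fdr,
                 config = config),
            class = "ssgsea_result")
}

#' Select gene sets enriched across a sample group
#'
#' A set is called enriched in a group when its FDR clears the threshold in
#' at least `ceiling(sample_fraction * |group|)` of the group's samples —
#' the "at least 2/3 of samples at FDR < 0.05" selection rule. Taking the
#' union of the selections over two tumor-type groups reproduces the
#' combined enriched-set list of a two-cancer comparison.
#'
#' @param result an [ssgsea_significance()] result.
#' @param fdr_threshold FDR cut-off (default 0.05, strict `<`).
#' @param sample_fraction required fraction of the group (default 2/3).
#' @param group character vector of sample ids (rows of the result).
#' @return character vector of selected gene-set names.
#' @export
select_enriched <- function(result, fdr_threshold = 0.05,
                            sample_fraction = 2 / 3, group) {
  stopifnot(inherits(result, "ssgsea_result"))
  if (missing(group) || length(group) == 0) stop("empty sample group")
  if (!all(group %in% rownames(result$fdr)))
    stop("group contains unknown sample id(s)")
  need <- ceiling(sample_fraction * length(group))
  hits <- colSums(result$fdr[group, , drop = FALSE] < fdr_threshold)
  names(hits)[hits >= need]
}

#' Subsample a fixed number of samples per group
#'
#' Balanced random subsetting before a cross-group comparison (e.g. a
#' fixed number of samples per tumor type ahead of ssGSEA heat-mapping).
#'
#' @param labels named character vector: group label per sample id.
#' @param per_group_n samples to keep from every group.
#' @param seed RNG seed.
#' @return character vector of kept sample ids, deterministic under seed.
#' @export
subsample_groups <- function(labels, per_group_n, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- character(0)
  for (g in unique(unname(labels))) {
    ids <- names(labels)[labels == g]
    if (length(ids) < per_group_n)
      stop(sprintf("group '%s' has %d samples, fewer than %d",
                   g, length(ids), per_group_n))
    out <- c(out, sample(ids, per_group_n))
  }
  out
}
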