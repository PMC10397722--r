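#' Top highly-variable genes
#'
#' Ranks genes by their sample variance (denominator n-1) across the
#' matrix, descending, ties broken lexicographically by gene id, and
#' returns the first `n`. Variance is intended to be computed on the log10
#' scale, matching the inputs of the usual embedding plots; a non-log
#' matrix is accepted with a warning. The selection pools whatever samples
#' are passed in.
#'
#' @param x an [expr_matrix()] (`log10_tpm` expected) or genes-by-samples
#'   matrix.
#' @param n number of genes to return (default 500).
#' @return character vector of `n` gene ids, most variable first; the
#'   result for `n` is always a prefix of the result for `n + 1`.
#' @export
top_variable_genes <- function(x, n = 500) {
  v <- if (inherits(x, "expr_matrix")) {
    if (x$unit != "log10_tpm")
      warning("variable-gene selection is intended for log10_tpm input (got ",
              x$unit, ")")
    x$values
  } else as.matrix(x)
  if (n > nrow(v))
    stop(sprintf("n (%d) exceeds gene count (%d)", n, nrow(v)))
  vars <- matrixStats::rowVars(v)
  ids <- rownames(v)
  ids[order(-vars, ids, method = "radix")][seq_len(n)]
}

#' Exclusive intersection table over named gene sets
#'
#' The tabular form of an upset plot: every element of the union is
#' assigned to exactly one membership pattern, so the pattern counts are
#' disjoint and sum to the union size. Pairwise (Venn-style, non-exclusive)
#' intersection sizes are attached as an attribute since both readings are
#' in routine use.
#'
#' @param named_sets named list (>= 2) of character vectors.
#' @return data.frame of class `intersection_table` with columns `pattern`
#'   (set names joined by `&`), one logical column per set, and `count`;
#'   attribute `pairwise` holds the matrix of pairwise intersection sizes,
#'   attribute `union_size` the size of the union.
#' @export
intersect_sets <- function(named_sets) {
  if (length(named_sets) < 2) stop("need at least 2 sets")
  nms <- names(named_sets)
  if (is.null(nms) || any(!nzchar(nms))) stop("sets must be named")
  if (anyDuplicated(nms)) stop("duplicate set name: ", nms[duplicated(nms)][1])
  named_sets <- lapply(named_sets, unique)
  universe <- unique(unlist(named_sets, use.names = FALSE))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(universe))
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(key)
  patterns <- names(tab)
  flags <- t(vapply(strsplit(patterns, ""),
                    function(ch) ch == "1", logical(length(nms))))
  if (length(nms) == 1) flags <- matrix(flags, ncol = 1)
  out <- data.frame(
    pattern = vapply(seq_along(patterns), function(i)
      paste(nms[flags[i, ]], collapse = "&"), character(1)),
    stringsAsFactors = FALSE)
  for (j in seq_along(nms)) out[[nms[j]]] <- flags[, j]
  out$count <- as.integer(tab)
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  pw <- outer(seq_along(nms), seq_along(nms), Vectorize(function(i, j)
    length(intersect(named_sets[[i]], named_sets[[j]]))))
  dimnames(pw) <- list(nms, nms)
  structure(out, pairwise = pw, union_size = length(universe),
            class = c("intersection_table", "data.frame"))
}

#' Fraction of a reference set covered by a target set
#'
#' `|target ∩ reference| / |reference|` — the "what fraction of the known
#' disease genes survive the feature filter" statistic.
#'
#' @param target_set,reference_set character vectors; the reference must be
#'   nonempty.
#' @return a fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(target_set, reference_set) {
  reference_set <- unique(reference_set)
  if (length(reference_set) == 0) stop("reference set is empty")
  length(intersect(unique(target_set), reference_set)) / length(reference_set)
}
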