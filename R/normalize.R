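#' Convert raw counts to TPM
#'
#' Transcripts per million. Per sample, each gene's count is first divided by
#' its length in kilobases to give a rate, and rates are rescaled so that the
#' sample sums to 1e6:
#' \deqn{TPM_g = 10^6 \, \frac{c_g / (L_g/1000)}{\sum_j c_j / (L_j/1000)}}
#' Gene lengths are union-exon lengths from the annotation table.
#'
#' @param x an [expr_matrix()] with unit `counts`.
#' @param annotation data.frame with `gene_id` and `length_bp` covering every
#'   gene in `x`.
#' @return an `expr_matrix` with unit `tpm`; gene and sample order unchanged.
#' @export
counts_to_tpm <- function(x, annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("input unit must be 'counts', got ", x$unit)
  len <- annotation_lengths(annotation, gene_ids(x))
  zero <- colSums(x$values) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(utils::head(sample_ids(x)[zero], 5), collapse = ", "))
  rate <- x$values / (len / 1000)
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expr_matrix(tpm, unit = "tpm", species = x$species)
}

annotation_lengths <- function(annotation, ids) {
  i <- match(ids, annotation$gene_id)
  if (anyNA(i))
    stop("gene(s) missing from annotation: ",
         paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  as.numeric(annotation$length_bp[i])
}

#' Convert FPKM-UQ to TPM
#'
#' FPKM-UQ is already a per-kilobase rate (scaled by the per-sample
#' upper-quartile count), so both the length and the upper-quartile factors
#' cancel under per-sample renormalisation:
#' \deqn{TPM_g = 10^6 \, FPKMUQ_g / \sum_j FPKMUQ_j}
#' The conversion is therefore invariant to any positive per-sample scaling
#' of its input and idempotent on its own output.
#'
#' @param x an [expr_matrix()] with unit `fpkm_uq` (or `tpm`, on which it
#'   is a no-op up to renormalisation).
#' @return an `expr_matrix` with unit `tpm`.
#' @export
fpkm_uq_to_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$unit %in% c("fpkm_uq", "tpm"))
    stop("input unit must be 'fpkm_uq' (or 'tpm'), got ", x$unit)
  cs <- colSums(x$values)
  if (any(cs <= 0))
    stop("sample(s) with zero column sum: ",
         paste(utils::head(sample_ids(x)[cs <= 0], 5), collapse = ", "))
  tpm <- sweep(x$values, 2, cs, "/") * 1e6
  expr_matrix(tpm, unit = "tpm", species = x$species)
}

#' Log10-transform a TPM matrix
#'
#' Elementwise `log10(tpm + pseudocount)`. TPM matrices contain exact zeros,
#' so a positive offset is required; the default pseudocount of 1 maps zero
#' to zero and is monotone, hence preserves within-sample ranking.
#'
#' @param x an [expr_matrix()] with unit `tpm`.
#' @param pseudocount positive offset added before the log (default 1).
#' @return an `expr_matrix` with unit `log10_tpm`.
#' @export
log10_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "tpm") stop("input unit must be 'tpm', got ", x$unit)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  expr_matrix(log10(x$values + pseudocount), unit = "log10_tpm",
              species = x$species, check_tpm = FALSE)
}

#' Convert raw counts to FPKM-UQ
#'
#' GDC-style upper-quartile normalisation: per sample,
#' \deqn{FPKMUQ_g = 10^6\, \frac{c_g/(L_g/1000)}{UQ_s}}
#' where \eqn{UQ_s} is the 75th percentile of the nonzero counts of
#' protein-coding genes in sample \eqn{s} (type-7 quantile). Any positive
#' per-sample scalar would do — it cancels exactly under TPM
#' renormalisation — and this definition mirrors the GDC's.
#'
#' @param x an [expr_matrix()] with unit `counts`.
#' @param annotation data.frame with `gene_id`, `length_bp`, `biotype`.
#' @return an `expr_matrix` with unit `fpkm_uq`.
#' @export
counts_to_fpkm_uq <- function(x, annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("input unit must be 'counts', got ", x$unit)
  len <- annotation_lengths(annotation, gene_ids(x))
  i <- match(gene_ids(x), annotation$gene_id)
  pc <- annotation$biotype[i] == "protein_coding"
  if (!any(pc)) pc <- rep(TRUE, nrow(x$values))  # fall back to all genes
  zero <- colSums(x$values) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(utils::head(sample_ids(x)[zero], 5), collapse = ", "))
  rate <- x$values / (len / 1000)
  uq <- vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[pc, j]
    v <- v[v > 0]
    if (!length(v)) v <- x$values[x$values[, j] > 0, j]
    stats::quantile(v, 0.75, names = FALSE, type = 7)
  }, numeric(1))
  out <- sweep(rate, 2, uq, "/") * 1e6
  expr_matrix(out, unit = "fpkm_uq", species = x$species)
}
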