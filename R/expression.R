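#' @title Expression matrix container
#'
#' @description
#' An `expr_matrix` is the single currency of the pipeline: a genes-by-samples
#' numeric matrix together with the unit its values are expressed in and the
#' species the genes belong to. Units form a closed vocabulary
#' (`counts`, `fpkm_uq`, `tpm`, `log10_tpm`); unit transitions are only ever
#' performed by the conversion functions ([counts_to_tpm()],
#' [fpkm_uq_to_tpm()], [log10_transform()]), never silently by readers.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names set to the gene and sample ids.
#' @param unit one of `"counts"`, `"fpkm_uq"`, `"tpm"`, `"log10_tpm"`.
#' @param species one of `"human"`, `"canine"`, `"synthetic-A"`,
#'   `"synthetic-B"`.
#' @param check_tpm when `TRUE` (the default) and `unit == "tpm"`, require
#'   each sample column to sum to 1e6 within relative tolerance 1e-6.
#'   Projection onto a gene subset legitimately breaks this invariant, so
#'   internal callers may disable the check; files read from disk are always
#'   checked.
#'
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `unit`, `species`.
#' @export
expr_matrix <- function(values, unit, species, check_tpm = TRUE) {
  unit <- match.arg(unit, expr_units())
  species <- match.arg(species, expr_species())
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("`values` must have gene ids as rownames")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("`values` must have sample ids as colnames")
  x <- structure(list(values = values, unit = unit, species = species),
                 class = "expr_matrix")
  validate_expr_matrix(x, check_tpm = check_tpm)
  x
}

expr_units <- function() c("counts", "fpkm_uq", "tpm", "log10_tpm")
expr_species <- function() c("human", "canine", "synthetic-A", "synthetic-B")

#' Validate an expression matrix
#'
#' Enforces the container invariants: unique gene and sample ids, no missing
#' values, non-negativity for linear units, and (optionally) the per-sample
#' TPM sum of 1e6.
#'
#' @param x an `expr_matrix`.
#' @inheritParams expr_matrix
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_expr_matrix <- function(x, check_tpm = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  g <- rownames(v); s <- colnames(v)
  if (anyDuplicated(g)) {
    bad <- g[duplicated(g)][1]
    stop("duplicate gene id: ", bad)
  }
  if (anyDuplicated(s)) stop("duplicate sample id: ", s[duplicated(s)][1])
  if (anyNA(v)) stop("missing values are not permitted in expression matrices")
  if (x$unit %in% c("counts", "fpkm_uq", "tpm") && length(v) && min(v) < 0) {
    ij <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value under unit '%s' at gene '%s', sample '%s'",
                 x$unit, g[ij[1]], s[ij[2]]))
  }
  if (check_tpm && x$unit == "tpm" && nrow(v) > 0 && ncol(v) > 0) {
    cs <- colSums(v)
    off <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(off))
      stop("tpm column sums deviate from 1e6 beyond tolerance for sample(s): ",
           paste(utils::head(s[off], 5), collapse = ", "))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [unit=%s, species=%s]\n",
              nrow(x$values), ncol(x$values), x$unit, x$species))
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of gene ids (row names).
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of sample ids (column names).
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV/CSV
#'
#' The file has a header row `gene_id<TAB>sample1<TAB>...` and one row per
#' gene. Optional comment lines `#unit=...` and `#species=...` before the
#' header carry metadata written by [write_expression_matrix()]; explicit
#' `unit`/`species` arguments override them. The unit is recorded as
#' declared, never inferred from the values.
#'
#' @param path file path. Tab- or comma-separated (inferred from the header).
#' @param unit,species declared unit and species; may be omitted when the
#'   file carries `#unit=`/`#species=` lines.
#' @return a validated [expr_matrix()].
#' @export
read_expression_matrix <- function(path, unit = NULL, species = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L)
  meta <- parse_header_meta(head_lines)
  if (is.null(unit)) unit <- meta[["unit"]]
  if (is.null(species)) species <- meta[["species"]]
  if (is.null(unit)) stop("unit not given and no #unit= header in ", path)
  if (is.null(species)) stop("species not given and no #species= header in ", path)
  hdr <- head_lines[!startsWith(head_lines, "#")][1]
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 1 || names(df)[1] != "gene_id")
    stop("first column must be 'gene_id' in ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expr_matrix(m, unit = unit, species = species)
}

parse_header_meta <- function(lines) {
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#(unit|species)=(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write an expression matrix to TSV
#'
#' Emits `#unit=` and `#species=` metadata lines followed by a
#' `gene_id`-headed tab-separated table; values are written with enough
#' digits that [read_expression_matrix()] round-trips them to better than
#' 1e-12 relative.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(paste0("#unit=", x$unit), paste0("#species=", x$species),
               paste(c("gene_id", colnames(x$values)), collapse = "\t")), con)
  if (nrow(x$values) > 0) {
    body <- apply(x$values, 1, function(r)
      paste(sprintf("%.15g", r), collapse = "\t"))
    writeLines(paste(rownames(x$values), body,
                     sep = if (ncol(x$values) > 0) "\t" else ""), con)
  }
  invisible(path)
}

#' Read a sample-label table
#'
#' Two-column TSV with header (`sample_id`, `label`); every sample id must
#' resolve to exactly one class label.
#'
#' @param path file path.
#' @return named character vector: labels named by sample id.
#' @export
read_sample_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("label table needs two columns (sample_id, label)")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("sample id labeled more than once: ", ids[duplicated(ids)][1])
  stats::setNames(as.character(df[[2]]), ids)
}

#' Write a sample-label table
#' @param labels named character vector (names are sample ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-annotation table
#'
#' TSV with header columns `gene_id`, `length_bp` (union-exon length used
#' for rate normalisation) and `biotype` (`protein_coding` is the
#' distinguished value).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `length_bp`, `biotype`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "length_bp", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation is missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$gene_id <- as.character(df$gene_id)
  df$length_bp <- as.integer(df$length_bp)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$length_bp < 1)) stop("length_bp must be >= 1")
  df
}

#' Write a gene-annotation table
#' @param ann data.frame with columns `gene_id`, `length_bp`, `biotype`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(ann[c("gene_id", "length_bp", "biotype")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
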