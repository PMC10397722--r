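#' Read a biomaRt-style ortholog export
#'
#' Parses a tab-separated human/canine homology export. Columns are matched
#' by header name (order-free); the default `col_map` accepts the package's
#' canonical names and can be overridden to match an arbitrary export, e.g.
#' `c(human_gene_id = "Gene stable ID")`. Required columns are the two gene
#' ids and the homology type; the rest (`human_gene_name`,
#' `canine_gene_name`, `pct_identity_h2c`, `pct_identity_c2h`,
#' `gene_order_conservation_score`, `human_biotype`) are optional and filled
#' with `NA` when absent. Ensembl version suffixes (`.NN`) are stripped from
#' gene ids on ingest: expression matrices and homology exports disagree on
#' versioning, so matching must be on stable ids.
#'
#' @param path TSV path.
#' @param col_map named character vector mapping canonical column names to
#'   the header names used in the file.
#' @return data.frame of class `ortholog_table` with the canonical columns;
#'   an empty data section yields an empty (zero-row) table, not an error.
#' @export
read_ortholog_table <- function(path, col_map = NULL) {
  canonical <- c("human_gene_id", "human_gene_name", "canine_gene_id",
                 "canine_gene_name", "homology_type", "pct_identity_h2c",
                 "pct_identity_c2h", "gene_order_conservation_score",
                 "human_biotype")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  required <- c("human_gene_id", "canine_gene_id", "homology_type")
  for (col in required)
    if (!map[[col]] %in% names(df))
      stop("ortholog table is missing required column: ", map[[col]])
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    lapply(stats::setNames(canonical, canonical), function(col) {
      if (map[[col]] %in% names(df)) df[[map[[col]]]]
      else rep(NA, nrow(df))
    }))
  out$human_gene_id <- strip_version(as.character(out$human_gene_id))
  out$canine_gene_id <- strip_version(as.character(out$canine_gene_id))
  out$homology_type <- as.character(out$homology_type)
  known <- c("ortholog_one2one", "ortholog_one2many", "ortholog_many2many")
  bad <- setdiff(unique(out$homology_type), known)
  if (length(bad))
    stop("unknown homology type(s): ", paste(bad, collapse = ", "))
  out <- unique(out)
  class(out) <- c("ortholog_table", "data.frame")
  out
}

strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Keep strict one-to-one ortholog pairs
#'
#' Retains rows labelled `ortholog_one2one` whose human id occurs exactly
#' once and whose canine id occurs exactly once among the retained rows.
#' The uniqueness re-check guards against label inconsistencies in real
#' exports (a gene can appear in several rows all marked one2one); it makes
#' the operation idempotent.
#'
#' @param table an `ortholog_table`.
#' @return the filtered `ortholog_table` (possibly zero rows).
#' @export
filter_one_to_one <- function(table) {
  tb <- table[table$homology_type == "ortholog_one2one", , drop = FALSE]
  keep <- !(tb$human_gene_id %in% tb$human_gene_id[duplicated(tb$human_gene_id)]) &
          !(tb$canine_gene_id %in% tb$canine_gene_id[duplicated(tb$canine_gene_id)])
  out <- tb[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Keep pairs whose human gene is protein-coding
#'
#' Second stage of the feature filter: restrict a one-to-one table to rows
#' whose human gene has biotype `protein_coding` in the human annotation.
#' The annotation is authoritative over the table's own `human_biotype`
#' column when both are present. Human genes absent from the annotation are
#' dropped with a warning rather than an error.
#'
#' @param table a one-to-one filtered `ortholog_table`.
#' @param human_annotation data.frame with `gene_id` and `biotype`.
#' @return the filtered `ortholog_table`.
#' @export
filter_protein_coding <- function(table, human_annotation = NULL) {
  if (!is.null(human_annotation)) {
    i <- match(table$human_gene_id, human_annotation$gene_id)
    if (anyNA(i))
      warning(sum(is.na(i)), " human gene(s) absent from annotation; dropped")
    bio <- human_annotation$biotype[i]
  } else {
    bio <- table$human_biotype
  }
  keep <- !is.na(bio) & bio == "protein_coding"
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Build the cross-species feature space
#'
#' The fixed feature axis shared by all models: the human gene ids of a
#' filtered ortholog table, sorted lexicographically, together with the
#' bijective canine-gene-to-feature-index map. The ordering carries no
#' biology; it merely has to be deterministic and recorded, because the
#' 1D convolution runs along it.
#'
#' @param table a one-to-one, protein-coding filtered `ortholog_table`.
#' @return an object of class `feature_space` with elements `human_ids`
#'   (sorted), `canine_ids` (aligned to `human_ids`) and `fingerprint`.
#' @export
build_feature_space <- function(table) {
  if (nrow(table) == 0) stop("cannot build a feature space from an empty table")
  if (anyDuplicated(table$human_gene_id))
    stop("duplicate human gene id after filtering/suffix stripping: ",
         table$human_gene_id[duplicated(table$human_gene_id)][1])
  if (anyDuplicated(table$canine_gene_id))
    stop("duplicate canine gene id after filtering/suffix stripping: ",
         table$canine_gene_id[duplicated(table$canine_gene_id)][1])
  o <- order(table$human_gene_id, method = "radix")
  fs <- structure(list(human_ids = table$human_gene_id[o],
                       canine_ids = table$canine_gene_id[o]),
                  class = "feature_space")
  fs$fingerprint <- feature_fingerprint(fs$human_ids)
  fs
}

#' @exportS3Method base::print
print.feature_space <- function(x, ...) {
  cat(sprintf("feature_space: %d features [%s]\n", length(x$human_ids),
              x$fingerprint))
  invisible(x)
}

#' Fingerprint of an ordered feature axis
#'
#' A cheap deterministic rolling hash of the ordered gene ids, prefixed with
#' the feature count. Models store it at training time and refuse to predict
#' on matrices whose axis hashes differently — a misaligned or unprojected
#' matrix fails loudly instead of silently mispredicting.
#'
#' @param ids ordered character vector of feature gene ids.
#' @return a string of the form `"<F>:<hash>"`.
#' @export
feature_fingerprint <- function(ids) {
  h <- 0
  mod <- 2147483647
  for (b in utf8ToInt(paste(ids, collapse = "\r")))
    h <- (h * 31 + b) %% mod
  sprintf("%d:%d", length(ids), as.integer(h))
}

#' Project an expression matrix onto a feature space
#'
#' Selects and orders the rows of a human or canine matrix so that row `i`
#' is the gene paired with feature `i`, renamed to the human gene id. Human
#' input selects by human id, canine input via the canine map. Projection is
#' strict: a feature whose source gene is absent from the input is an error
#' (no silent zero-fill — a spurious zero in log-TPM space is a strong fake
#' signal into the models). Unmapped extra genes are simply dropped; sample
#' order and selected values are preserved bit-exactly.
#'
#' @param x an [expr_matrix()] with unit `tpm` or `log10_tpm`.
#' @param feature_space a [build_feature_space()] result.
#' @return an `expr_matrix` with exactly `F` rows named by human gene ids.
#' @export
project_to_feature_space <- function(x, feature_space) {
  stopifnot(inherits(x, "expr_matrix"), inherits(feature_space, "feature_space"))
  if (!x$unit %in% c("tpm", "log10_tpm"))
    stop("projection expects unit 'tpm' or 'log10_tpm', got ", x$unit)
  src <- if (x$species %in% c("human", "synthetic-A"))
    feature_space$human_ids else feature_space$canine_ids
  i <- match(src, gene_ids(x))
  if (anyNA(i)) {
    miss <- src[is.na(i)]
    stop(sprintf("%d feature gene(s) missing from input matrix: %s",
                 length(miss),
                 paste(utils::head(miss, 20), collapse = ", ")))
  }
  v <- x$values[i, , drop = FALSE]
  rownames(v) <- feature_space$human_ids
  expr_matrix(v, unit = x$unit, species = x$species, check_tpm = FALSE)
}
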