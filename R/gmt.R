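#' Read a GMT gene-set collection
#'
#' Parses the MSigDB GMT dialect: one set per line,
#' `name<TAB>description<TAB>member1<TAB>member2...`. Set order is preserved.
#' Duplicate member ids within a line are removed with a warning; a line with
#' fewer than three fields or a duplicated set name is an error citing the
#' offending line number.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: named list of character vectors of member
#'   ids, with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    if (f[1] %in% nms[seq_len(i - 1)])
      stop(sprintf("duplicate gene-set name '%s' on line %d", f[1], i))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': %d duplicate member id(s) removed",
                      f[1], sum(duplicated(members))))
      members <- unique(members)
    }
    nms[i] <- f[1]; desc[i] <- f[2]; sets[[i]] <- members
  }
  names(sets) <- nms
  structure(sets, descriptions = stats::setNames(desc, nms),
            class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (a `gene_set_collection`
#'   or plain list).
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to the collection's `descriptions` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s); sizes %s\n", length(x),
              paste(utils::head(lengths(x), 8), collapse = ", ")))
  invisible(x)
}
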