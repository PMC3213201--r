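#' Read a phenotype/covariate table
#'
#' Whitespace- or tab-delimited text with a header row and `NA` as the
#' missing code. Columns named in `schema` are coerced to the given
#' type and required to exist; unknown columns are preserved as-is.
#'
#' @param path file path.
#' @param schema named character vector mapping mandatory column names
#'   to types (`"character"`, `"numeric"`, `"integer"`); must include
#'   `sample_id`.
#' @return A data frame keyed by `sample_id`.
#' @export
read_pheno_table <- function(path,
                             schema = c(sample_id = "character")) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = "NA")
  missing_cols <- setdiff(names(schema), names(tab))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in names(schema)) {
    tab[[col]] <- switch(schema[[col]],
                         character = as.character(tab[[col]]),
                         numeric = as.numeric(tab[[col]]),
                         integer = as.integer(tab[[col]]),
                         stop("unknown schema type: ", schema[[col]]))
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in ", path)
  tab
}

#' @rdname read_pheno_table
#' @param tab data frame to write.
#' @export
write_pheno_table <- function(tab, path) {
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     sep = "\t", na = "NA")
  invisible(path)
}
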