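# Shared tabular IO. All tabular outputs are TSV with a single commented
# header line carrying the column names and the package version; readers
# accept files with or without that comment line.

tapms_version <- function() {
  as.character(utils::packageVersion("tapms"))
}

write_tsv <- function(df, path, extra_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(extra_comment)) {
    writeLines(paste0("# ", extra_comment), con)
  }
  writeLines(
    paste0("# columns: ", paste(names(df), collapse = "\t"),
           "  tapms=", tapms_version()),
    con
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
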