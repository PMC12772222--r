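# Deterministic TSV output: tab-separated, UTF-8, '.' decimal, header row,
# no quoting, no row names -- bit-identical across platforms for identical
# inputs.

#' Write a data.frame as deterministic TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @param header_comments optional character vector written as leading
#'   `# `-prefixed lines (provenance: seeds, thresholds).
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path, header_comments = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con, sep = "\n")
  # fixed 15-significant-digit formatting keeps output platform-stable
  num <- vapply(x, is.numeric, TRUE) & !vapply(x, is.integer, TRUE)
  x[num] <- lapply(x[num], function(v) {
    out <- formatC(v, digits = 15, format = "g")
    out[is.na(v)] <- "NA"
    out
  })
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame (leading `#` comment lines skipped).
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
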