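#' Read and write FASTA
#'
#' Thin wrappers around Biostrings' FASTA reader that apply the package's
#' sequence normalization (uppercase, `U` to `T`, non-`ACGTN` to `N`).
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences (names are the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse failure in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(set), normalize_seq, "", USE.NAMES = FALSE)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' @rdname read_fasta
#' @param records named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(length(records) >= 1L, !is.null(names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
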