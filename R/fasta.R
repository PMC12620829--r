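#' Read a FASTA file
#'
#' Minimal strict FASTA reader returning named sequences: wrapped lines
#' are joined, surrounding whitespace is stripped, case is preserved.
#' A sequence line appearing before any header is a parse error
#' reporting the line number.
#'
#' @param path file path.
#' @return named character vector (names = record ids, first
#'   whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) seqs <- c(seqs, cur)
      ids <- c(ids, strsplit(sub("^>\\s*", "", ln), "\\s+")[[1]][1])
      cur <- ""
    } else {
      if (is.null(cur))
        stop("FASTA parse error at line ", i, ": sequence before any header")
      cur <- paste0(cur, gsub("\\s+", "", lines[i]))
    }
  }
  if (!is.null(cur)) seqs <- c(seqs, cur)
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Deterministic tabular writer: stable column order, numerics at 10
# significant digits.
write_table_stable <- function(df, path, sep = ",") {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 10, format = "g")
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
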