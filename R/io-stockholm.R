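# Stockholm 1.0 writer/reader for alignments with a consensus
# secondary-structure line (#=GC SS_cons, WUSS/dot-bracket).

#' Write an alignment with consensus structure to Stockholm format
#'
#' @param rows named character vector of aligned (gapped) sequences;
#'   the first row is the focal sequence.
#' @param ss_cons dot-bracket/WUSS consensus structure string, same
#'   length as the alignment (optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(rows, path, ss_cons = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    abort("alignment rows must be named")
  }
  width <- max(nchar(names(rows)), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", width, names(rows), unname(rows)))
  if (!is.null(ss_cons)) {
    stopifnot(nchar(ss_cons) == nchar(rows[[1]]))
    lines <- c(lines, sprintf("%-*s %s", width, "#=GC SS_cons", ss_cons))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read a single-block Stockholm alignment
#'
#' @param path path to a Stockholm file written by [write_stockholm()].
#' @return A list with `rows` (named character vector) and `ss_cons`
#'   (string or `NULL`).
#' @export
read_stockholm <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & lines != "//"]
  if (length(lines) == 0 || lines[1] != "# STOCKHOLM 1.0") {
    abort("not a Stockholm file")
  }
  lines <- lines[-1]
  ss <- NULL
  gc <- startsWith(lines, "#=GC SS_cons")
  if (any(gc)) {
    ss <- stringr::str_trim(sub("^#=GC SS_cons", "", lines[gc][1]))
  }
  seq_lines <- lines[!startsWith(lines, "#")]
  parts <- stringr::str_split_fixed(stringr::str_trim(seq_lines), "\\s+", 2)
  rows <- setNames(parts[, 2], parts[, 1])
  list(rows = rows, ss_cons = ss)
}

#' Write a pipeline TSV with "#"-prefixed metadata lines
#'
#' @param x data frame to write.
#' @param path output path.
#' @param meta named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a pipeline TSV, skipping "#"-prefixed metadata lines
#'
#' @param path input path.
#' @return A tibble.
#' @export
read_tsv_meta <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
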