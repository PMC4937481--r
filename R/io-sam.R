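# SAM text parsing. No installed R package reads SAM as text (the
# Bioconductor alignment readers require BGZF BAM), and the pipeline's
# contract is desk-scale SAM only, so records are parsed directly.
# Only the fields the pipeline uses are retained: chromosome, 0-based
# start, CIGAR-derived reference span, strand, mapped flag.

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' @noRd
cigar_ref_span <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    if (nrow(m) == 0) return(0L)
    len <- as.integer(m[, 2])
    consumes <- m[, 3] %in% c("M", "D", "N", "=", "X")
    sum(len[consumes])
  }, integer(1))
}

#' Read single-end alignments from a SAM file
#'
#' Unmapped records are dropped; multi-mapping records (secondary or
#' supplementary flags, or duplicated query names) are excluded
#' entirely, mirroring a unique-mapping filter. Records on chromosomes
#' absent from the header are skipped and counted.
#'
#' @param path path to a SAM file with a header containing `@SQ` lines.
#' @return An object of class `read_alignments`: a list with `reads`
#'   (tibble: `qname`, `chrom`, `start` 0-based, `span`, `strand`),
#'   `total_mapped`, `n_skipped_unknown_chrom`, and `chrom_lengths`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0) abort("SAM header has no @SQ sequence lines")
  sn <- stringr::str_match(sq, "SN:([^\\t]+)")[, 2]
  ln <- as.integer(stringr::str_match(sq, "LN:(\\d+)")[, 2])
  chrom_lengths <- setNames(ln, sn)

  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    return(structure(list(
      reads = tibble(qname = character(), chrom = character(),
                     start = integer(), span = integer(),
                     strand = character()),
      total_mapped = 0L, n_skipped_unknown_chrom = 0L,
      chrom_lengths = chrom_lengths), class = "read_alignments"))
  }
  fields <- stringr::str_split_fixed(body, "\t", 12)
  flag <- as.integer(fields[, 2])
  df <- tibble(
    qname = fields[, 1],
    flag = flag,
    chrom = fields[, 3],
    start = as.integer(fields[, 4]) - 1L,  # SAM POS is 1-based
    cigar = fields[, 6]
  )
  df <- df |> filter(bitwAnd(.data$flag, FLAG_UNMAPPED) == 0L)
  multi <- bitwAnd(df$flag, FLAG_SECONDARY) > 0 |
    bitwAnd(df$flag, FLAG_SUPPLEMENTARY) > 0
  multi_names <- unique(c(df$qname[multi],
                          df$qname[duplicated(df$qname)]))
  df <- df |> filter(!.data$qname %in% multi_names)
  known <- df$chrom %in% names(chrom_lengths)
  n_skipped <- sum(!known)
  df <- df[known, ]
  reads <- df |>
    mutate(span = cigar_ref_span(.data$cigar),
           strand = ifelse(bitwAnd(.data$flag, FLAG_REVERSE) > 0, "-", "+")) |>
    select("qname", "chrom", "start", "span", "strand")
  structure(list(reads = reads, total_mapped = nrow(reads),
                 n_skipped_unknown_chrom = n_skipped,
                 chrom_lengths = chrom_lengths),
            class = "read_alignments")
}

#' Write single-end alignments to SAM
#'
#' @param reads tibble with `qname`, `chrom`, `start` (0-based), `seq`
#'   and `strand` columns.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- ifelse(reads$strand == "-", FLAG_REVERSE, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  reads$qname, flag, reads$chrom, reads$start + 1L,
                  nchar(reads$seq), reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
print.read_alignments <- function(x, ...) {
  cat(sprintf("read_alignments: %d mapped reads on %d chromosomes (%d skipped)\n",
              x$total_mapped, length(x$chrom_lengths),
              x$n_skipped_unknown_chrom))
  invisible(x)
}
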