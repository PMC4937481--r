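# Shared low-level helpers: alphabet coding, reverse complement,
# coordinate conversions between GFF (1-based inclusive) and the
# internal 0-based half-open convention.

DNA_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L, N = 5L)

#' @noRd
encode_dna <- function(x) {
  codes <- DNA_CODES[strsplit(toupper(x), "", fixed = TRUE)[[1]]]
  if (anyNA(codes)) {
    abort(sprintf("illegal character in sequence near position %d",
                  which(is.na(codes))[1]))
  }
  unname(codes)
}

#' @noRd
decode_dna <- function(codes) {
  paste(c("A", "C", "G", "T", "N")[codes], collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Convert GFF3 coordinates (1-based, inclusive) to 0-based half-open
#'
#' @param start,end integer vectors of GFF3 start/end coordinates.
#' @return A tibble with columns `start` and `end` in the internal
#'   0-based half-open convention.
#' @export
gff_to_internal <- function(start, end) {
  tibble(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert internal 0-based half-open coordinates to GFF3 convention
#'
#' @param start,end integer vectors in 0-based half-open coordinates.
#' @return A tibble with 1-based inclusive `start` and `end`.
#' @export
internal_to_gff <- function(start, end) {
  tibble(start = as.integer(start) + 1L, end = as.integer(end))
}

# substring in 0-based half-open coordinates
#' @noRd
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# Watson-Crick + G.U complementarity on single characters (T treated as U)
#' @noRd
is_complementary <- function(x, y) {
  p <- paste0(x, y)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# random DNA string
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-site neutral substitution: each position substituted with
# probability `rate`, uniformly to one of the three other bases
#' @noRd
mutate_neutral <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' @noRd
check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  x
}

#' @noRd
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a positive integer", name))
  }
  as.integer(x)
}
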