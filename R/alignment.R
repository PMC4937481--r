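# Reference-anchored multiple alignment of an ortholog set: each
# ortholog is aligned globally to the focal sequence with affine gaps,
# and the pairwise alignments are merged column-wise on focal
# coordinates, with insertion columns allocated so that degapping any
# row reproduces its input sequence exactly.

#' Build a reference-anchored alignment of an ortholog set
#'
#' @param sequences named character vector of transcript-sense intron
#'   sequences, focal first; at least two sequences.
#' @param params a [search_params()] object (gap penalties and
#'   match/mismatch scores of the nucleotide aligner).
#' @return An object of class `intron_alignment`: a list with `rows`
#'   (named character vector of equal-length gapped rows, focal first),
#'   `gap_fraction`, and `mean_identity` (percent).
#' @export
build_alignment <- function(sequences, params = search_params()) {
  if (length(sequences) < 2) abort("need the focal sequence plus >= 1 ortholog")
  if (any(!nzchar(sequences))) abort("empty sequence in ortholog set")
  focal <- sequences[[1]]
  n <- nchar(focal)
  subst <- nt_subst_matrix(params)
  qc <- encode_dna(focal)

  # for each ortholog: aligned residue index per focal position (0 = gap)
  # plus insertions keyed by the focal position they follow (0 = before
  # the first focal residue)
  per_row <- purrr::map(sequences[-1], function(s) {
    tc <- encode_dna(s)
    al <- .align_affine_cpp(qc, tc, subst, params$gap_open_nt,
                            params$gap_extend_nt, FALSE)
    match_at <- integer(n)
    ins <- vector("list", n + 1)
    last_focal <- 0L
    for (k in seq_along(al$a_idx)) {
      ai <- al$a_idx[k]; bi <- al$b_idx[k]
      if (ai > 0 && bi > 0) {
        match_at[ai] <- bi
        last_focal <- ai
      } else if (ai == 0) {
        ins[[last_focal + 1L]] <- c(ins[[last_focal + 1L]], bi)
      } else {
        last_focal <- ai
      }
    }
    list(chars = strsplit(s, "", fixed = TRUE)[[1]],
         match_at = match_at, ins = ins)
  })

  ins_len <- vapply(seq_len(n + 1), function(p) {
    max(c(0L, vapply(per_row, function(r) length(r$ins[[p]]), integer(1))))
  }, integer(1))

  focal_chars <- strsplit(focal, "", fixed = TRUE)[[1]]
  build_row <- function(chars, match_at, ins) {
    out <- character(0)
    for (p in 0:n) {
      slot <- ins_len[p + 1]
      if (slot > 0) {
        mine <- if (is.null(ins[[p + 1]])) character(0) else chars[ins[[p + 1]]]
        out <- c(out, mine, rep("-", slot - length(mine)))
      }
      if (p < n) {
        out <- c(out, if (match_at[p + 1] > 0) chars[match_at[p + 1]] else "-")
      }
    }
    paste(out, collapse = "")
  }
  focal_row <- build_row(focal_chars, seq_len(n),
                         vector("list", n + 1))
  rows <- c(setNames(focal_row, names(sequences)[1]),
            purrr::imap_chr(per_row, function(r, nm) {
              build_row(r$chars, r$match_at, r$ins)
            }))

  structure(list(
    rows = rows,
    gap_fraction = alignment_gap_fraction(rows),
    mean_identity = alignment_identity(rows)
  ), class = "intron_alignment")
}

#' @noRd
alignment_chars <- function(rows) {
  do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
}

#' @noRd
alignment_gap_fraction <- function(rows) {
  m <- alignment_chars(rows)
  mean(m == "-")
}

# mean pairwise identity (percent) over columns where both rows are
# non-gap; NA when no comparable columns exist
#' @noRd
alignment_identity <- function(rows) {
  m <- alignment_chars(rows)
  k <- nrow(m)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(k, 2)
  ids <- apply(pairs, 2, function(p) {
    a <- m[p[1], ]; b <- m[p[2], ]
    both <- a != "-" & b != "-"
    if (!any(both)) return(NA_real_)
    100 * mean(a[both] == b[both])
  })
  mean(ids, na.rm = TRUE)
}

#' Degap one row of an alignment
#'
#' @param row gapped sequence string.
#' @return The ungapped sequence.
#' @export
degap <- function(row) gsub("-", "", row, fixed = TRUE)

#' @export
print.intron_alignment <- function(x, ...) {
  cat(sprintf("intron_alignment: %d rows x %d columns (gap %.2f, identity %.1f%%)\n",
              length(x$rows), nchar(x$rows[[1]]), x$gap_fraction,
              x$mean_identity))
  invisible(x)
}

#' Slice an alignment into filtered windows
#'
#' Sliding windows of `window_len` columns every `step` columns;
#' alignments shorter than `window_len` yield a single full-length
#' window. Windows with gap fraction above `max_gap` or mean pairwise
#' identity below `min_id` are dropped. When more than `max_seqs` rows
#' are present, a greedy subset of `max_seqs` rows spreading pairwise
#' identities is retained, the focal row always kept.
#'
#' @param alignment an `intron_alignment`.
#' @param window_len,step window length and step in columns.
#' @param max_gap maximum window gap fraction.
#' @param min_id minimum window mean pairwise identity (percent).
#' @param max_seqs maximum number of rows per window.
#' @return A list of `alignment_window` objects: lists with `rows`,
#'   `col_start`, `col_end` (1-based columns of the parent alignment),
#'   `gap_fraction`, `mean_identity`.
#' @export
window_alignment <- function(alignment, window_len = 120, step = 40,
                             max_gap = 0.25, min_id = 30, max_seqs = 6) {
  ncol_aln <- nchar(alignment$rows[[1]])
  starts <- if (ncol_aln <= window_len) 1L else
    unique(c(seq(1L, ncol_aln - window_len + 1L, by = step),
             ncol_aln - window_len + 1L))
  out <- list()
  for (s in starts) {
    e <- min(s + window_len - 1L, ncol_aln)
    rows <- vapply(alignment$rows, substr, "", s, e)
    if (length(rows) > max_seqs) rows <- spread_subset(rows, max_seqs)
    gf <- alignment_gap_fraction(rows)
    id <- alignment_identity(rows)
    if (gf > max_gap || is.na(id) || id < min_id) next
    out[[length(out) + 1]] <- structure(
      list(rows = rows, col_start = s, col_end = e,
           gap_fraction = gf, mean_identity = id),
      class = "alignment_window")
  }
  out
}

# Greedy row subset: keep the focal row, then repeatedly add the row
# with the lowest mean identity to the rows already kept, spreading the
# represented divergence.
#' @noRd
spread_subset <- function(rows, max_seqs) {
  kept <- 1L
  remaining <- setdiff(seq_along(rows), kept)
  while (length(kept) < max_seqs && length(remaining) > 0) {
    score <- vapply(remaining, function(r) {
      mean(vapply(kept, function(k2) {
        alignment_identity(rows[c(r, k2)])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    pick <- remaining[which.min(score)]
    kept <- c(kept, pick)
    remaining <- setdiff(remaining, pick)
  }
  rows[sort(kept)]
}
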