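# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

make_window <- function(rows) {
  structure(list(rows = rows, col_start = 1L,
                 col_end = nchar(rows[[1]]),
                 gap_fraction = mean(strsplit(paste(rows, collapse = ""),
                                              "")[[1]] == "-"),
                 mean_identity = NA_real_),
            class = "alignment_window")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent folding oracle ------------------------------------------
# Enumerates every nested pair set over positions 1..n allowed by
# `allowed` (logical matrix, min_sep already applied), then scores each
# set from scratch. Completely separate from the package's DP.

enumerate_pair_sets <- function(allowed, i, j) {
  if (i >= j) return(list(list()))
  out <- enumerate_pair_sets(allowed, i + 1, j)
  for (k in seq(i + 1, j)) {
    if (!allowed[i, k]) next
    left <- enumerate_pair_sets(allowed, i + 1, k - 1)
    right <- enumerate_pair_sets(allowed, k + 1, j)
    for (l in left) for (r in right) {
      out[[length(out) + 1]] <- c(list(c(i, k)), l, r)
    }
  }
  out
}

# score a pair set: per-pair scores from `pair_score`, + stack_bonus for
# each pair whose enclosing neighbour is also present, - helix_open per
# maximal helix
score_pair_set <- function(pairs, pair_score, stack_bonus, helix_open) {
  if (length(pairs) == 0) return(0)
  key <- vapply(pairs, function(p) paste(p, collapse = ","), "")
  total <- sum(vapply(pairs, function(p) pair_score[p[1], p[2]], 1))
  outer_of <- function(p) paste(p[1] - 1, p[2] + 1, sep = ",")
  stacked <- vapply(pairs, function(p) outer_of(p) %in% key, logical(1))
  total + stack_bonus * sum(stacked) - helix_open * sum(!stacked)
}

best_fold_by_enumeration <- function(pair_score, min_sep, stack_bonus,
                                     helix_open) {
  n <- nrow(pair_score)
  allowed <- is.finite(pair_score) & !is.na(pair_score)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i - 1 < min_sep) allowed[i, j] <- FALSE
  }
  sets <- enumerate_pair_sets(allowed, 1, n)
  max(vapply(sets, score_pair_set, numeric(1),
             pair_score = pair_score, stack_bonus = stack_bonus,
             helix_open = helix_open))
}

# pair-weight matrix for a single DNA sequence (codes 1..4)
seq_pair_matrix <- function(seq_str, w_gc = 1, w_au = 1, w_gu = 1) {
  codes <- intronscreen:::encode_dna(seq_str)
  n <- length(codes)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- min(codes[i], codes[j]); y <- max(codes[i], codes[j])
    m[i, j] <- if (x == 2 && y == 3) w_gc
    else if (x == 1 && y == 4) w_au
    else if (x == 3 && y == 4) w_gu
    else NA_real_
  }
  m
}

# --- brute-force read overlap oracle --------------------------------------
brute_force_counts <- function(reads, features) {
  vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    sum(reads$chrom == f$chrom &
          reads$start < f$end &
          (reads$start + reads$span) > f$start)
  }, integer(1))
}

# --- small cached simulation ----------------------------------------------
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome_set(sim_params(n_genes = 8, seed = 5))
    }
    cache
  }
})
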