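# The conserved-structure screen: three independent evidence channels
# (thermodynamic z-score against a dinucleotide-shuffled null,
# structure conservation index, compensatory-substitution count)
# combined by an intersection rule over alignment windows.

COMP_PAIRS <- matrix(FALSE, 5, 5)
COMP_PAIRS[cbind(c(1, 4, 2, 3, 3, 4), c(4, 1, 3, 2, 4, 3))] <- TRUE
WC_ONLY <- matrix(FALSE, 5, 5)
WC_ONLY[cbind(c(1, 4, 2, 3), c(4, 1, 3, 2))] <- TRUE

#' @noRd
window_codes <- function(window) {
  m <- alignment_chars(window$rows)
  codes <- matrix(0L, nrow(m), ncol(m))
  codes[] <- DNA_CODES[m]
  codes[m == "-"] <- 0L
  codes
}

#' Fold the consensus structure of an alignment window
#'
#' Nussinov-style dynamic programming over window columns maximising
#' the summed consensus pair score. A column pair (i, j) may pair only
#' when at least `pair_support` of the rows hold complementary
#' residues (Watson-Crick or G.U) at the two columns; its score is the
#' supporting fraction plus `kappa` times the number of distinct
#' complementary residue combinations beyond the most frequent one
#' (the covariation bonus). Hairpin loops span at least 3 columns;
#' traceback is deterministic.
#'
#' @param window an `alignment_window`.
#' @param pair_support minimum fraction of complementary rows.
#' @param kappa covariation bonus weight.
#' @param helix_open penalty for opening a new helix, in pair-score
#'   units; stops near-identical alignments from accumulating
#'   scattered spurious pairs.
#' @return An object of class `consensus_fold`: `structure`
#'   (dot-bracket over window columns), `pairs` (tibble `i`, `j`,
#'   `support`, `n_combos`), `score` (the DP objective, i.e. summed
#'   pair scores minus helix-opening penalties), `n_pairs`.
#' @export
fold_consensus <- function(window, pair_support = 0.75, kappa = 0.5,
                           helix_open = 2) {
  codes <- window_codes(window)
  nr <- nrow(codes); nc <- ncol(codes)
  empty <- structure(list(structure = strrep(".", nc),
                          pairs = tibble(i = integer(), j = integer(),
                                         support = numeric(),
                                         n_combos = integer()),
                          score = 0, n_pairs = 0L),
                     class = "consensus_fold")
  if (nc < 8) return(empty)

  # support matrix: fraction of rows complementary at (i, j)
  support <- matrix(0, nc, nc)
  for (r in seq_len(nr)) {
    v <- codes[r, ]
    ok <- v > 0 & v < 5
    comp <- matrix(FALSE, nc, nc)
    comp[ok, ok] <- COMP_PAIRS[v[ok], v[ok], drop = FALSE]
    support <- support + comp
  }
  support <- support / nr

  score_mat <- matrix(NA_real_, nc, nc)
  idx <- which(support >= pair_support & upper.tri(support), arr.ind = TRUE)
  combos <- matrix(0L, nc, nc)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    a <- codes[, i]; b <- codes[, j]
    ok <- a > 0 & a < 5 & b > 0 & b < 5
    comp <- ok & COMP_PAIRS[cbind(pmax(a, 1), pmax(b, 1))]
    types <- paste0(a[comp], b[comp])
    nco <- max(0L, length(unique(types)) - 1L)
    combos[i, j] <- nco
    score_mat[i, j] <- score_mat[j, i] <- support[i, j] + kappa * nco
  }

  fold <- .fold_pairs_cpp(score_mat, 3L, 0, helix_open)
  partner <- fold$partner
  db <- rep(".", nc)
  db[partner > seq_len(nc)] <- "("
  db[partner > 0 & partner < seq_len(nc)] <- ")"
  ii <- which(partner > seq_len(nc))
  pairs <- tibble(i = ii, j = partner[ii],
                  support = support[cbind(ii, partner[ii])],
                  n_combos = combos[cbind(ii, partner[ii])])
  structure(list(structure = paste(db, collapse = ""),
                 pairs = pairs, score = fold$score,
                 n_pairs = nrow(pairs)),
            class = "consensus_fold")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the shuffled sequence has
#' exactly the same dinucleotide (and mononucleotide) counts as the
#' input.
#'
#' @param seq DNA string.
#' @return A shuffled DNA string.
#' @export
dinucleotide_shuffle <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  first <- chars[1]; last <- chars[n]
  verts <- unique(chars)
  edges <- split(chars[-1], chars[-n])  # out-edges per vertex
  if (length(verts) == 1) return(seq)

  # pick random "last out-edges" until they form an arborescence to `last`
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last) return(NA_character_)
      sample(edges[[v]], 1)
    }, "")
    # check: following last edges from every vertex reaches `last`
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; steps <- 0
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1
      }
      if (!identical(cur, last)) { ok <- FALSE; break }
    }
    if (ok) break
  }

  shuffled_edges <- lapply(setNames(verts, verts), function(v) {
    ee <- edges[[v]]
    if (is.null(ee)) return(character(0))
    if (v != last) {
      # remove one instance of the chosen last edge, shuffle, append it
      ix <- match(last_edge[[v]], ee)
      rest <- ee[-ix]
      c(sample(rest), last_edge[[v]])
    } else {
      sample(ee)
    }
  })

  out <- character(n)
  out[1] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (k in 2:n) {
    nxt <- shuffled_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Thermodynamic z-score of the focal window sequence
#'
#' Folds the degapped focal row with a thermodynamically weighted
#' pairing score (pair weights by type, a stacking bonus per helically
#' stacked pair, and a helix-opening penalty standing in for loop
#' costs, so scattered lone pairs cannot saturate the score of random
#' sequence) and compares its pseudo-energy E = -score with the
#' energies of dinucleotide-preserving shuffles:
#' z = (E_focal - mean(E_shuffled)) / sd(E_shuffled). A degenerate null
#' (sd < 1e-9) returns z = 0 by convention.
#'
#' @param window an `alignment_window` (focal row first).
#' @param n_shuffles number of shuffles.
#' @param seed integer seed for the shuffle null.
#' @param stack_bonus stacking weight.
#' @param helix_open helix-opening penalty.
#' @param pair_weights named numeric: pair weights for `gc`, `au` and
#'   `gu` (wobble) pairs.
#' @return A list with `z`, `energy_focal` (E = -score), and
#'   `score_focal`.
#' @export
z_score <- function(window, n_shuffles = 100, seed = 1, stack_bonus = 1,
                    helix_open = 9,
                    pair_weights = c(gc = 3, au = 2, gu = 0.5)) {
  focal <- degap(window$rows[[1]])
  codes <- encode_dna(focal)
  codes[codes == 5L] <- 0L
  fe <- function(cc) {
    .fold_energy_cpp(cc, 3L, stack_bonus, helix_open,
                     pair_weights[["gc"]], pair_weights[["au"]],
                     pair_weights[["gu"]])
  }
  score_focal <- fe(codes)
  e_focal <- -score_focal
  if (!is.null(seed)) set.seed(seed)
  e_null <- vapply(seq_len(n_shuffles), function(i) {
    s <- dinucleotide_shuffle(focal)
    sc <- encode_dna(s)
    sc[sc == 5L] <- 0L
    -fe(sc)
  }, numeric(1))
  s <- sd(e_null)
  z <- if (is.na(s) || s < 1e-9) 0 else (e_focal - mean(e_null)) / s
  list(z = z, energy_focal = e_focal, score_focal = score_focal)
}

#' Structure conservation index of a window
#'
#' Consensus folding score divided by the mean single-sequence folding
#' score of the rows (maximum-pairing score, no stacking, same minimum
#' loop length). An alignment of identical rows has SCI exactly 1;
#' values near 1 indicate the rows fold as well together as alone.
#'
#' @param window an `alignment_window`.
#' @param fold the window's `consensus_fold` (computed if missing).
#' @param pair_support,kappa consensus fold parameters, used only when
#'   `fold` is missing.
#' @param helix_open helix-opening penalty; must match the consensus
#'   fold's so that identical rows give SCI exactly 1.
#' @return SCI (0 when the denominator is 0).
#' @export
sci <- function(window, fold = NULL, pair_support = 0.75, kappa = 0.5,
                helix_open = 2) {
  if (is.null(fold)) {
    fold <- fold_consensus(window, pair_support, kappa, helix_open)
  }
  single <- vapply(window$rows, function(r) {
    codes <- encode_dna(degap(r))
    codes[codes == 5L] <- 0L
    .fold_energy_cpp(codes, 3L, 0, helix_open, 1, 1, 1)
  }, numeric(1))
  denom <- mean(single)
  if (denom <= 0) return(0)
  fold$score / denom
}

#' Count compensatory and consistent substitutions supporting a fold
#'
#' For each predicted consensus pair and each non-focal row:
#' compensatory when both positions differ from the focal row and the
#' row's residues form a Watson-Crick pair (the double substitution
#' restored canonical pairing); consistent when exactly one position
#' differs and complementarity (including G.U wobble) holds.
#'
#' @param window an `alignment_window`.
#' @param fold the window's `consensus_fold`.
#' @return A list with `n_compensatory` and `n_consistent`.
#' @export
count_compensatory <- function(window, fold) {
  codes <- window_codes(window)
  if (nrow(fold$pairs) == 0 || nrow(codes) < 2) {
    return(list(n_compensatory = 0L, n_consistent = 0L))
  }
  n_comp <- 0L; n_cons <- 0L
  for (k in seq_len(nrow(fold$pairs))) {
    i <- fold$pairs$i[k]; j <- fold$pairs$j[k]
    fi <- codes[1, i]; fj <- codes[1, j]
    for (r in 2:nrow(codes)) {
      a <- codes[r, i]; b <- codes[r, j]
      if (a == 0 || b == 0 || a == 5 || b == 5) next
      if (!COMP_PAIRS[a, b]) next
      ndiff <- (a != fi) + (b != fj)
      if (ndiff == 2 && WC_ONLY[a, b]) n_comp <- n_comp + 1L
      else if (ndiff == 1) n_cons <- n_cons + 1L
    }
  }
  list(n_compensatory = n_comp, n_consistent = n_cons)
}

#' Score every window of an ortholog set
#'
#' Builds the reference-anchored alignment, slices it into filtered
#' windows, and computes the three scorer channels per window.
#'
#' @param sequences named character vector (focal first).
#' @param thresholds a [screen_thresholds()] object.
#' @param search a [search_params()] object (alignment scoring).
#' @param window_len,step,max_gap,min_id,max_seqs window filters.
#' @param n_shuffles,seed z-score null parameters.
#' @return A tibble with one row per retained window: column interval,
#'   scores, flags, and the consensus fold as a list-column; zero rows
#'   when the set is a singleton or no window survives the filters.
#' @export
score_windows <- function(sequences, thresholds = screen_thresholds(),
                          search = search_params(),
                          window_len = 120, step = 40, max_gap = 0.25,
                          min_id = 30, max_seqs = 6,
                          n_shuffles = 100, seed = 1) {
  if (length(sequences) < 2) return(tibble())
  aln <- build_alignment(sequences, search)
  windows <- window_alignment(aln, window_len, step, max_gap, min_id,
                              max_seqs)
  if (length(windows) == 0) return(tibble())
  # focal-position map: alignment column -> focal coordinate (1-based)
  focal_chars <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  focal_pos <- cumsum(focal_chars != "-")

  rows <- purrr::imap(windows, function(w, wi) {
    fold <- fold_consensus(w, thresholds$pair_support, thresholds$kappa,
                           thresholds$helix_open)
    zz <- z_score(w, n_shuffles, seed + wi)
    sci_v <- sci(w, fold, helix_open = thresholds$helix_open)
    cc <- count_compensatory(w, fold)
    tibble(
      col_start = w$col_start, col_end = w$col_end,
      focal_start = focal_pos[w$col_start], focal_end = focal_pos[w$col_end],
      mean_identity = w$mean_identity, gap_fraction = w$gap_fraction,
      z = zz$z, score_focal = zz$score_focal, sci = sci_v,
      n_compensatory = cc$n_compensatory, n_consistent = cc$n_consistent,
      pass_z = zz$z <= thresholds$z_max &
        zz$score_focal >= thresholds$energy_min,
      pass_sci = sci_v >= thresholds$sci_min,
      pass_cov = cc$n_compensatory >= thresholds$cov_min,
      fold = list(fold), window = list(w))
  })
  bind_rows(rows)
}

#' Call candidate conserved structures from scored windows
#'
#' A window is a candidate when at least `thresholds$min_scorers` of
#' the z, SCI and covariation flags pass. Overlapping candidate
#' windows of one intron are merged: the union of their focal
#' coordinates with the best score of each channel.
#'
#' @param scored tibble from [score_windows()].
#' @param thresholds a [screen_thresholds()] object.
#' @return A tibble of candidates: `focal_start`, `focal_end`, best
#'   channel scores, flags, `structure` (consensus dot-bracket of the
#'   best-supported merged window).
#' @export
call_candidates <- function(scored, thresholds = screen_thresholds()) {
  if (nrow(scored) == 0) return(tibble())
  hits <- scored |>
    mutate(n_pass = .data$pass_z + .data$pass_sci + .data$pass_cov) |>
    filter(.data$n_pass >= thresholds$min_scorers)
  if (nrow(hits) == 0) return(tibble())
  hits <- hits |> arrange(.data$focal_start)
  grp <- integer(nrow(hits))
  grp[1] <- 1L
  if (nrow(hits) > 1) {
    cur_end <- hits$focal_end[1]
    for (i in 2:nrow(hits)) {
      if (hits$focal_start[i] <= cur_end) {
        grp[i] <- grp[i - 1]
      } else {
        grp[i] <- grp[i - 1] + 1L
      }
      cur_end <- max(cur_end, hits$focal_end[i])
    }
  }
  hits$merge_group <- grp
  hits |>
    group_by(.data$merge_group) |>
    summarise(
      focal_start = min(.data$focal_start),
      focal_end = max(.data$focal_end),
      z = min(.data$z), sci = max(.data$sci),
      n_compensatory = max(.data$n_compensatory),
      n_consistent = max(.data$n_consistent),
      pass_z = any(.data$pass_z), pass_sci = any(.data$pass_sci),
      pass_cov = any(.data$pass_cov),
      structure = .data$fold[[which.max(.data$sci)]]$structure,
      window = list(.data$window[[which.max(.data$sci)]]),
      fold = list(.data$fold[[which.max(.data$sci)]]),
      .groups = "drop") |>
    select(-"merge_group")
}

#' Screen a table of ortholog sets for conserved structures
#'
#' @param sets tibble with `intron_id` and list-column `sequences`
#'   (from [build_ortholog_sets()] or [truth_ortholog_sets()]).
#' @param thresholds a [screen_thresholds()] object.
#' @param seed seed for the z-score null.
#' @param ... passed to [score_windows()].
#' @return A list with `candidates` (tibble, one row per merged
#'   candidate with `intron_id`) and `windows` (all scored windows).
#' @export
screen_ortholog_sets <- function(sets, thresholds = screen_thresholds(),
                                 seed = 1, ...) {
  all_scored <- list()
  all_cand <- list()
  for (i in seq_len(nrow(sets))) {
    seqs <- sets$sequences[[i]]
    if (length(seqs) < 2) next  # singleton set: skipped
    scored <- score_windows(seqs, thresholds, seed = seed + i, ...)
    if (nrow(scored) == 0) next
    scored$intron_id <- sets$intron_id[i]
    all_scored[[length(all_scored) + 1]] <- scored
    cand <- call_candidates(scored, thresholds)
    if (nrow(cand) > 0) {
      cand$intron_id <- sets$intron_id[i]
      all_cand[[length(all_cand) + 1]] <- cand
    }
  }
  list(candidates = bind_rows(all_cand), windows = bind_rows(all_scored))
}

#' Species tree of the simulated comparison panel
#'
#' A ladder topology grouping the focal species with successively more
#' divergent clades; internal nodes are labelled with the clade names
#' so conservation extent can be reported as a clade label.
#'
#' @param params a [sim_params()] object.
#' @return An `ape` phylo object with node labels.
#' @export
species_tree <- function(params = sim_params()) {
  clade_names <- names(params$clades)
  tips <- purrr::imap(params$clades, function(d, nm) {
    sprintf("%s_%d", nm, seq_along(d))
  })
  inner <- "focal"
  for (i in seq_along(clade_names)) {
    members <- paste(c(inner, tips[[i]]), collapse = ",")
    inner <- sprintf("(%s)%s", members, clade_names[i])
  }
  ape::read.tree(text = paste0(inner, ";"))
}

#' Conservation extent of a candidate structure
#'
#' A species supports the candidate when at least `pair_support` of
#' the predicted consensus pairs remain complementary in its row. The
#' extent is the smallest named clade of the species tree covering the
#' focal species and all supporting species.
#'
#' @param candidate one row of the candidates tibble (needs `window`
#'   and `fold` list-columns).
#' @param tree an `ape` phylo with labelled internal nodes.
#' @param focal name of the focal tip.
#' @param pair_support support threshold.
#' @return The clade label (character).
#' @export
conservation_extent <- function(candidate, tree, focal = "focal",
                                pair_support = 0.75) {
  w <- candidate$window[[1]]
  fold <- candidate$fold[[1]]
  codes <- window_codes(w)
  rows <- names(w$rows)
  supported <- focal
  if (nrow(fold$pairs) > 0 && nrow(codes) >= 2) {
    for (r in 2:nrow(codes)) {
      okpair <- vapply(seq_len(nrow(fold$pairs)), function(k) {
        a <- codes[r, fold$pairs$i[k]]; b <- codes[r, fold$pairs$j[k]]
        a > 0 && a < 5 && b > 0 && b < 5 && COMP_PAIRS[a, b]
      }, logical(1))
      if (mean(okpair) >= pair_support) supported <- c(supported, rows[r])
    }
  }
  supported <- intersect(supported, tree$tip.label)
  missing <- setdiff(setdiff(supported, focal), tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("species not in tree: %s", missing[1]))
  }
  clade_label(tree, supported)
}

# smallest named clade containing the given tips
#' @noRd
clade_label <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label)) {
    abort("species missing from tree")
  }
  ntip <- length(tree$tip.label)
  node <- if (length(tips) == 1) {
    tree$edge[tree$edge[, 2] == match(tips, tree$tip.label), 1]
  } else {
    ape::getMRCA(tree, tips)
  }
  # walk rootward until a named node is found
  repeat {
    lbl <- tree$node.label[node - ntip]
    if (!is.null(lbl) && !is.na(lbl) && nzchar(lbl)) return(lbl)
    up <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(up) == 0) return("root")
    node <- up
  }
}
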