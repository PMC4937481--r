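# Structure screen: consensus folding, z-score, SCI, covariation
# counting, candidate calling, conservation extent.

test_that("consensus DP equals exhaustive enumeration on small windows", {
  set.seed(20)
  checked <- 0
  for (rep in 1:100) {
    n <- sample(10:15, 1)
    nrow_w <- sample(2:4, 1)
    focal <- random_dna_str(n)
    rows <- c(focal = focal,
              setNames(vapply(seq_len(nrow_w - 1), function(i) {
                intronscreen:::mutate_neutral(focal, runif(1, 0, 0.3))
              }, ""), paste0("sp", seq_len(nrow_w - 1))))
    w <- make_window(rows)
    fold <- fold_consensus(w, pair_support = 0.5, kappa = 0.5,
                           helix_open = 2)
    # rebuild the score matrix independently and enumerate
    codes <- do.call(rbind, lapply(rows, intronscreen:::encode_dna))
    support <- matrix(0, n, n); combos <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      comp <- intronscreen:::COMP_PAIRS[cbind(codes[, i], codes[, j])]
      support[i, j] <- mean(comp)
      types <- paste0(codes[comp, i], codes[comp, j])
      combos[i, j] <- max(0L, length(unique(types)) - 1L)
    }
    score_mat <- ifelse(support >= 0.5, support + 0.5 * combos, NA_real_)
    n_allowed <- sum(is.finite(score_mat[upper.tri(score_mat)]) &
                       (col(score_mat) - row(score_mat) - 1 >=
                          3)[upper.tri(score_mat)])
    if (n_allowed > 18) next  # keep the enumeration tractable
    oracle <- best_fold_by_enumeration(score_mat, 3, 0, 2)
    expect_equal(fold$score, max(oracle, 0), tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 50)
})

test_that("an unpairable window yields an empty structure", {
  w <- make_window(c(focal = strrep("A", 20), sp = strrep("A", 20)))
  fold <- fold_consensus(w)
  expect_equal(fold$n_pairs, 0)
  expect_equal(fold$structure, strrep(".", 20))
})

test_that("a conserved perfect hairpin folds into its full stem", {
  # stem 8, loop 4, non-pairing tails: conserved in 4 rows
  hp <- paste0("AA", strrep("G", 8), "AAAA", strrep("C", 8), "AA")
  w <- make_window(setNames(rep(hp, 4), c("focal", "sp1", "sp2", "sp3")))
  fold <- fold_consensus(w)
  expect_equal(fold$n_pairs, 8)
  expect_true(all(fold$pairs$support == 1))
  # enumeration oracle on a stem-4 variant (enumeration stays tractable)
  hp4 <- paste0("AA", strrep("G", 4), "AAAA", strrep("C", 4), "AA")
  w4 <- make_window(setNames(rep(hp4, 4), c("focal", "sp1", "sp2", "sp3")))
  fold4 <- fold_consensus(w4)
  oracle <- best_fold_by_enumeration(seq_pair_matrix(hp4), 3, 0, 2)
  expect_equal(fold4$score, oracle)
})

test_that("the covariation bonus adds exactly kappa per extra pair combination", {
  # a single admissible pair (1,10): G:C in every row (invariant) vs
  # G:C in two rows and A:T in two rows (one covarying combination)
  rows_inv <- setNames(rep("GAAAAAAAAC", 4), c("focal", "a", "b", "c"))
  rows_cov <- rows_inv
  rows_cov[3:4] <- "TAAAAAAAAA"
  f_inv <- fold_consensus(make_window(rows_inv), pair_support = 0.6,
                          helix_open = 0)
  f_cov <- fold_consensus(make_window(rows_cov), pair_support = 0.6,
                          helix_open = 0)
  p_inv <- f_inv$pairs[f_inv$pairs$i == 1 & f_inv$pairs$j == 10, ]
  p_cov <- f_cov$pairs[f_cov$pairs$i == 1 & f_cov$pairs$j == 10, ]
  expect_equal(p_inv$support, 1)
  expect_equal(p_cov$support, 1)
  expect_equal(p_inv$n_combos, 0L)
  expect_equal(p_cov$n_combos, 1L)
  # pair score difference is exactly kappa
  expect_equal(f_cov$score - f_inv$score, 0.5)
})

test_that("dinucleotide shuffling preserves doublet counts exactly", {
  set.seed(21)
  doublets <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(head(ch, -1), tail(ch, -1)))
  }
  changed <- 0
  for (rep in 1:50) {
    s <- random_dna_str(sample(30:150, 1))
    sh <- dinucleotide_shuffle(s)
    expect_identical(doublets(sh), doublets(s))
    if (sh != s) changed <- changed + 1
  }
  expect_gt(changed, 40)  # shuffles genuinely permute
})

test_that("the z-score flags a planted stem and is null-calibrated", {
  # degenerate null: homopolymer
  w0 <- make_window(c(focal = strrep("A", 60)))
  expect_equal(z_score(w0, 50, seed = 1)$z, 0)
  # planted 12-bp stem hairpin
  set.seed(22)
  stem <- random_dna_str(12)
  hp <- paste0(stem, "AAAA",
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(stem))))
  s <- paste0(random_dna_str(40), hp, random_dna_str(80 - nchar(hp)))
  z <- z_score(make_window(c(focal = s)), 100, seed = 7)
  expect_lte(z$z, -2)
  # null calibration: mean z of random sequences is near 0
  set.seed(23)
  zs <- vapply(1:50, function(i) {
    z_score(make_window(c(focal = random_dna_str(120))), 100,
            seed = 100 + i)$z
  }, numeric(1))
  expect_gt(mean(zs), -1)
  expect_lt(mean(zs), 1)
})

test_that("SCI is exactly 1 for identical rows and counts are zero", {
  s <- random_dna_str(60)
  w <- make_window(setNames(rep(s, 4), c("focal", "a", "b", "c")))
  fold <- fold_consensus(w)
  expect_equal(sci(w, fold), 1)
  cc <- count_compensatory(w, fold)
  expect_equal(cc$n_compensatory, 0L)
  expect_equal(cc$n_consistent, 0L)
})

test_that("compensatory and consistent substitutions are counted by construction", {
  # hairpin fixture whose stem pairs are known; one row carries
  # G:C -> A:T at one pair (compensatory), another G:C -> G:T (consistent)
  stem_l <- "GGGG"; loop <- "AAAA"; stem_r <- "CCCC"
  focal <- paste0(stem_l, loop, stem_r)
  comp_row <- paste0("AGGG", loop, "CCCT")   # pair (1,12): A:T
  cons_row <- paste0("GGGG", loop, "CCCT")   # pair (1,12): G:T wobble
  w <- make_window(c(focal = focal, a = comp_row, b = cons_row))
  fold <- fold_consensus(w, pair_support = 0.6)
  expect_true(any(fold$pairs$i == 1 & fold$pairs$j == 12))
  cc <- count_compensatory(w, fold)
  expect_equal(cc$n_compensatory, 1L)
  expect_gte(cc$n_consistent, 1L)
})

test_that("a fixture with four planted compensatory pairs passes the covariation channel", {
  # four G:C pairs of the focal stem become A:T pairs in the ortholog
  focal <- paste0("GGGGGGGG", "AAAA", "CCCCCCCC")
  orth <- paste0("AAAAGGGG", "AAAA", "CCCCTTTT")
  w <- make_window(c(focal = focal, sp1 = orth))
  fold <- fold_consensus(w, pair_support = 0.6)
  cc <- count_compensatory(w, fold)
  expect_equal(cc$n_compensatory, 4L)
  thresholds <- screen_thresholds()
  expect_gte(cc$n_compensatory, thresholds$cov_min)
})

test_that("candidate calling is the set algebra of the pass flags", {
  set.seed(24)
  scored <- tibble::tibble(
    col_start = 1L, col_end = 120L,
    focal_start = seq(1, by = 200, length.out = 50),
    focal_end = seq(120, by = 200, length.out = 50),
    z = runif(50, -4, 1), sci = runif(50, 0, 1.2),
    n_compensatory = rpois(50, 1), n_consistent = 0L,
    score_focal = 20,
    pass_z = NA, pass_sci = NA, pass_cov = NA,
    fold = replicate(50, list(structure = ".", pairs = NULL), simplify = FALSE),
    window = replicate(50, list(), simplify = FALSE))
  th <- screen_thresholds()
  scored$pass_z <- scored$z <= th$z_max
  scored$pass_sci <- scored$sci >= th$sci_min
  scored$pass_cov <- scored$n_compensatory >= th$cov_min
  # windows here never overlap, so candidates = flag algebra
  cand3 <- call_candidates(scored, screen_thresholds(min_scorers = 3))
  expect_equal(nrow(cand3),
               sum(scored$pass_z & scored$pass_sci & scored$pass_cov))
  cand2 <- call_candidates(scored, screen_thresholds(min_scorers = 2))
  expect_equal(nrow(cand2),
               sum(scored$pass_z + scored$pass_sci + scored$pass_cov >= 2))
  expect_gte(nrow(cand2), nrow(cand3))
  # all flags false -> no candidates
  none <- scored
  none$pass_z <- none$pass_sci <- none$pass_cov <- FALSE
  expect_equal(nrow(call_candidates(none)), 0)
})

test_that("a two-of-three window is admitted when min_scorers is 2", {
  scored <- tibble::tibble(
    col_start = 1L, col_end = 120L, focal_start = 1L, focal_end = 120L,
    z = -3, sci = 0.9, n_compensatory = 0L, n_consistent = 0L,
    score_focal = 20, pass_z = TRUE, pass_sci = TRUE, pass_cov = FALSE,
    fold = list(list(structure = ".", pairs = NULL)),
    window = list(list()))
  expect_equal(nrow(call_candidates(scored, screen_thresholds(min_scorers = 3))), 0)
  expect_equal(nrow(call_candidates(scored, screen_thresholds(min_scorers = 2))), 1)
})

test_that("overlapping candidate windows merge into one region", {
  base <- tibble::tibble(
    col_start = 1L, col_end = 120L,
    z = -3, sci = 0.9, n_compensatory = 2L, n_consistent = 0L,
    score_focal = 20, pass_z = TRUE, pass_sci = TRUE, pass_cov = TRUE,
    fold = list(list(structure = ".", pairs = NULL)),
    window = list(list()))
  scored <- dplyr::bind_rows(
    base |> dplyr::mutate(focal_start = 1L, focal_end = 120L),
    base |> dplyr::mutate(focal_start = 41L, focal_end = 160L, sci = 1.1),
    base |> dplyr::mutate(focal_start = 400L, focal_end = 520L))
  cand <- call_candidates(scored)
  expect_equal(nrow(cand), 2)
  merged <- cand[cand$focal_start == 1, ]
  expect_equal(merged$focal_end, 160L)
  expect_equal(merged$sci, 1.1)  # best score kept
})

test_that("tightening any threshold never enlarges the candidate set", {
  sim <- small_sim()
  sets <- truth_ortholog_sets(sim)
  res <- screen_ortholog_sets(sets, seed = 9)
  loose <- nrow(call_candidates(res$windows, screen_thresholds(min_scorers = 2)))
  for (th in list(screen_thresholds(min_scorers = 2, z_max = -3),
                  screen_thresholds(min_scorers = 2, sci_min = 0.9),
                  screen_thresholds(min_scorers = 2, cov_min = 5),
                  screen_thresholds(min_scorers = 3))) {
    tight <- res$windows
    tight$pass_z <- tight$z <= th$z_max & tight$score_focal >= th$energy_min
    tight$pass_sci <- tight$sci >= th$sci_min
    tight$pass_cov <- tight$n_compensatory >= th$cov_min
    expect_lte(nrow(call_candidates(tight, th)), loose)
  }
})

test_that("conservation extent is the LCA clade of the supporting species", {
  tree <- ape::read.tree(
    text = "(((focal,s1,s2)inner,(m1,m2)mid)core,(o1,o2)outer)root;")
  # hand-made candidate: stem supported in s1 (inner) and m1 (mid)
  focal <- paste0("GGGGGGGG", "AAAA", "CCCCCCCC")
  broken <- paste0("GGGGGGGG", "AAAA", "CCCAAAAA")  # stem lost
  rows <- c(focal = focal, s1 = focal, m1 = focal, o1 = broken)
  w <- make_window(rows)
  fold <- fold_consensus(w, pair_support = 0.6)
  cand <- tibble::tibble(window = list(w), fold = list(fold))
  # supported: focal, s1, m1 -> LCA named 'core'
  expect_equal(conservation_extent(cand, tree), "core")
  # supported everywhere -> root label
  rows_all <- setNames(rep(focal, 4), c("focal", "s1", "m1", "o1"))
  w2 <- make_window(rows_all)
  cand2 <- tibble::tibble(window = list(w2),
                          fold = list(fold_consensus(w2, pair_support = 0.6)))
  expect_equal(conservation_extent(cand2, tree), "root")
  # sister-group-only support -> narrowest clade (lower the fold's
  # support threshold so the half-supported stem is still predicted)
  lost <- paste0("GGGGGGGG", "AAAA", "GGGGGGGG")  # right arm cannot pair
  rows_sister <- c(focal = focal, s1 = focal, m1 = lost, o1 = lost)
  w3 <- make_window(rows_sister)
  cand3 <- tibble::tibble(window = list(w3),
                          fold = list(fold_consensus(w3, pair_support = 0.4)))
  expect_equal(conservation_extent(cand3, tree), "inner")
})

test_that("species absent from the tree raise an error", {
  tree <- ape::read.tree(text = "((focal,s1)a,(s2,s3)b)r;")
  expect_error(intronscreen:::clade_label(tree, c("focal", "nope")),
               "missing")
})
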