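# Expression quantification: counting, RPKM, evidence rule,
# host-normalisation, Mann-Whitney, group comparison.

fake_alignments <- function(reads, chrom_lengths = c(chr1 = 100000L)) {
  structure(list(reads = reads, total_mapped = nrow(reads),
                 n_skipped_unknown_chrom = 0L,
                 chrom_lengths = chrom_lengths),
            class = "read_alignments")
}

test_that("any-overlap counting assigns boundary reads to both classes", {
  features <- tibble::tibble(
    feature_id = c("g1", "g1.i1"), class = c("CDS", "intron"),
    gene_id = "g1", chrom = "chr1",
    start = c(0L, 1000L), end = c(1000L, 1500L))
  reads <- tibble::tibble(
    qname = c("inside", "boundary", "far"),
    chrom = "chr1",
    start = c(1100L, 951L, 90000L),   # boundary read: [951, 1001) -> 1 nt in intron
    span = c(50L, 50L, 50L),
    strand = "+")
  counted <- count_reads(fake_alignments(reads), features)
  expect_equal(counted$count[counted$feature_id == "g1.i1"], 2L)
  expect_equal(counted$count[counted$feature_id == "g1"], 1L)
  # zero reads
  zero <- count_reads(fake_alignments(reads[0, ]), features)
  expect_true(all(zero$count == 0))
  # unknown chromosome errors
  bad <- features |> dplyr::mutate(chrom = "chrX")
  expect_error(count_reads(fake_alignments(reads), bad), "chromosome")
})

test_that("interval counting matches a brute-force oracle on random reads", {
  set.seed(30)
  features <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:20), class = "intron",
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
    start = sort(sample.int(90000, 20)) )
  features$end <- features$start + sample(100:400, 20, replace = TRUE)
  reads <- tibble::tibble(
    qname = sprintf("r%04d", 1:1000), chrom = "chr1",
    start = sample.int(95000, 1000, replace = TRUE),
    span = 50L, strand = "+")
  counted <- count_reads(fake_alignments(reads), features)
  expect_equal(counted$count, brute_force_counts(reads, features))
})

test_that("count conservation holds on simulated reads", {
  sim <- small_sim()
  reads <- simulate_reads(sim)
  aln <- fake_alignments(reads$reads, reads$chrom_lengths)
  features <- annotation_features(sim$annotations)
  counted <- count_reads(aln, features)
  intron_sum <- sum(counted$count[counted$class == "intron"])
  expect_lte(intron_sum, aln$total_mapped)
  # per-feature counts match the generator ledger (reads never span
  # feature boundaries in the generator)
  by_feat <- counted |>
    dplyr::group_by(feature_id) |>
    dplyr::summarise(count = sum(count))
  merged <- dplyr::left_join(reads$ledger, by_feat, by = "feature_id")
  expect_equal(merged$count, merged$true_count)
})

test_that("RPKM follows its closed form and is scale invariant", {
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  r1 <- rpkm(c(10, 250), c(800, 1200), 5e5)
  r2 <- rpkm(2 * c(10, 250), c(800, 1200), 1e6)
  expect_equal(r1, r2)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "positive")
})

test_that("the evidence rule is a strict disjunction with the stated boundaries", {
  expect_true(evidence(151, 5))
  expect_false(evidence(150, 19.9))
  expect_true(evidence(0, 25))
  expect_true(evidence(0, 20))   # 20 RPKM is enough
  expect_false(evidence(150, 0))
})

test_that("host normalisation flags undefined ratios", {
  expect_equal(normalize_by_host(20, 200), 0.1)
  expect_equal(normalize_by_host(0, 50), 0)
  expect_true(is.na(normalize_by_host(10, 0)))
})

test_that("Mann-Whitney exact p matches full enumeration for small groups", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2/20 arrangements
  expect_equal(mw$method, "exact")
  # identical groups: p near 1 (approximate path, ties present)
  same <- mann_whitney(rep(1:4, 3), rep(1:4, 3))
  expect_gt(same$p, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with the independent implementation", {
  set.seed(31)
  for (i in 1:40) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:10, 1))
    m <- mann_whitney(a, b)
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(m$U, unname(w$statistic))
    expect_equal(m$p, w$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation is close to the exact law at n = m = 15", {
  set.seed(32)
  devs <- vapply(1:100, function(i) {
    a <- rnorm(15); b <- rnorm(15)
    m <- mann_whitney(a, b)  # N = 30 forces the approximate path
    expect_equal(m$method, "normal")
    abs(m$p - stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }, numeric(1))
  expect_lt(max(devs), 0.02)
})

test_that("the expression table wires counts into flags and ratios", {
  study <- simulate_expression_study(sim_params(n_genes = 50, seed = 61))
  preds <- paste0(study$genes$gene_id[study$genes$structured], ".i1")
  expr <- expression_table(study$features, study$total_mapped, preds)
  introns <- expr |> dplyr::filter(class == "intron")
  expect_true(all(introns$normalized[introns$host_rpkm > 0] ==
                    introns$rpkm[introns$host_rpkm > 0] /
                      introns$host_rpkm[introns$host_rpkm > 0]))
  expect_equal(sum(expr$has_prediction), length(preds))
  expect_true(all(expr$is_rp == grepl("^RP[LS]", expr$gene_id)))
})

test_that("group comparison reports single-value medians verbatim", {
  expr <- tibble::tibble(
    feature_id = c("RPL1.i1", "RPL2.i1"), class = "intron",
    gene_id = c("RPL1", "RPL2"), count = c(10, 20), length = 100,
    rpkm = c(5, 9), host_rpkm = c(10, 10), normalized = c(0.5, 0.9),
    evidence = FALSE, is_rp = TRUE, has_prediction = c(TRUE, FALSE))
  gs <- group_compare(expr)
  expect_equal(gs$median_pred[gs$measure == "rpkm"], 5)
  expect_equal(gs$median_all[gs$measure == "rpkm"], 7)
})

test_that("estimated RPKM tracks the generating rate on simulated counts", {
  p <- sim_params(n_genes = 60, seed = 62, depth = 20)
  study <- simulate_expression_study(p)
  expr <- expression_table(study$features, study$total_mapped)
  merged <- expr |>
    dplyr::filter(class == "CDS") |>
    dplyr::left_join(study$genes, by = "gene_id")
  # expected count = expr * len/1000 * depth; Poisson CI per feature
  lam <- merged$expression * merged$length / 1000 * p$depth
  ok <- abs(merged$count - lam) <= 3 * sqrt(pmax(lam, 1))
  expect_gte(mean(ok), 0.95)
})
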