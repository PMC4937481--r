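# Ortholog mapper: translated seed-and-extend search, flank extension,
# nucleotide intron search, best-hit selection and the histogram.

test_that("a focal gene finds itself with full coverage", {
  sim <- small_sim()
  gene <- sim$annotations[1, ]
  hits <- find_gene_orthologs(gene, sim$genomes, "focal")
  expect_gte(nrow(hits), 1)
  top <- hits[which.min(hits$evalue), ]
  expect_equal(top$query_coverage, 1)
  expect_equal(top$strand, gene$strand)
  # the hit interval covers the gene's exons
  ex <- gene$exons[[1]]
  expect_lte(top$start, min(ex$start))
  expect_gte(top$end, max(ex$end))
})

test_that("hits below 65% query coverage are discarded", {
  set.seed(40)
  # target genome contains only 60% of the CDS
  cds <- random_dna_str(600)
  chrom_f <- paste0(random_dna_str(200), cds, random_dna_str(200))
  chrom_t <- paste0(random_dna_str(300), substr(cds, 1, 360),
                    random_dna_str(300))
  genomes <- tibble::tibble(
    species_id = c("focal", "tgt"), chrom_id = "c",
    residues = c(chrom_f, chrom_t))
  gene <- tibble::tibble(
    gene_id = "g", species_id = "focal", chrom_id = "c", strand = "+",
    exons = list(tibble::tibble(start = 200L, end = 800L)),
    introns = list(tibble::tibble(start = integer(), end = integer())))
  hits <- find_gene_orthologs(gene, genomes, "tgt")
  expect_equal(nrow(hits), 0)
  # lowering the coverage threshold recovers the partial hit
  relaxed <- find_gene_orthologs(gene, genomes, "tgt",
                                 search_params(min_coverage = 0.4))
  expect_gte(nrow(relaxed), 1)
})

test_that("raising the coverage threshold never increases the hit count", {
  sim <- small_sim()
  gene <- sim$annotations[2, ]
  targets <- setdiff(unique(sim$genomes$species_id), "focal")[1:3]
  n_prev <- Inf
  for (cov in c(0.4, 0.65, 0.9)) {
    h <- find_gene_orthologs(gene, sim$genomes, targets,
                             search_params(min_coverage = cov))
    expect_lte(nrow(h), n_prev)
    n_prev <- nrow(h)
  }
})

test_that("a planted diverged ortholog is located where the alignment oracle puts it", {
  set.seed(41)
  # 150-codon gene planted in a 10-kb synthetic chromosome with ~10%
  # amino-acid divergence (implemented as codon-level substitutions)
  cds <- random_dna_str(450)
  ortho <- intronscreen:::mutate_neutral(cds, 0.06)
  pos <- 4000L
  chrom_t <- paste0(random_dna_str(pos), ortho,
                    random_dna_str(10000 - pos - nchar(ortho)))
  chrom_f <- paste0(random_dna_str(100), cds, random_dna_str(100))
  genomes <- tibble::tibble(species_id = c("focal", "tgt"), chrom_id = "c",
                            residues = c(chrom_f, chrom_t))
  gene <- tibble::tibble(
    gene_id = "g", species_id = "focal", chrom_id = "c", strand = "+",
    exons = list(tibble::tibble(start = 100L, end = 550L)),
    introns = list(tibble::tibble(start = integer(), end = integer())))
  hits <- find_gene_orthologs(gene, genomes, "tgt")
  expect_equal(nrow(hits), 1)
  # X-drop extension may overrun the planted boundary by a residue or
  # two; allow three codons of slack
  expect_lt(abs(hits$start - pos), 10)
  expect_lt(abs(hits$end - (pos + 450)), 10)
  # oracle: exhaustive local alignment of the translated query against
  # the six frame translations finds the same locus
  qprot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  best <- NULL
  for (fr in intronscreen:::translate_frames(chrom_t)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(qprot), Biostrings::AAString(fr$prot),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    if (is.null(best) || Biostrings::score(al) > best$score) {
      best <- list(score = Biostrings::score(al), frame = fr,
                   t_start = al@subject@range@start)
    }
  }
  oracle_nt_start <- best$frame$frame + 3 * (best$t_start - 1)
  expect_lt(abs(hits$start - oracle_nt_start), 10)
})

test_that("flank extension follows transcript orientation and clips", {
  genomes <- tibble::tibble(species_id = "t", chrom_id = "c",
                            residues = random_dna_str(8000))
  hit <- tibble::tibble(query_gene = "g", species_id = "t", chrom_id = "c",
                        start = 5000, end = 6000, strand = "+",
                        score = 100, evalue = 1e-10, query_coverage = 1)
  loc <- extend_flanks(hit, genomes, 1000, 300)
  expect_equal(c(loc$ext_start, loc$ext_end), c(4000, 6300))
  # at the contig start the 5' extension clips to 0 without error
  hit2 <- hit |> dplyr::mutate(start = 500, end = 1500)
  loc2 <- extend_flanks(hit2, genomes, 1000, 300)
  expect_equal(loc2$ext_start, 0)
  # minus strand: amounts mirror and the sequence is the reverse
  # complement of the extended interval (manual 60-nt oracle)
  toy <- tibble::tibble(species_id = "t", chrom_id = "c",
                        residues = random_dna_str(60))
  hit3 <- hit |> dplyr::mutate(start = 20, end = 30, strand = "-")
  loc3 <- extend_flanks(hit3, toy, 10, 5)
  expect_equal(c(loc3$ext_start, loc3$ext_end), c(15, 40))
  manual <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(toy$residues, 16, 40))))
  expect_identical(loc3$sequence, manual)
})

test_that("intron search recovers exact copies and ranks diverged copies by the oracle", {
  set.seed(42)
  intron <- random_dna_str(200)
  near <- intronscreen:::mutate_neutral(intron, 0.05)
  far <- intronscreen:::mutate_neutral(intron, 0.20)
  locus_seq <- paste0(random_dna_str(300), intron, random_dna_str(200),
                      far, random_dna_str(150), near,
                      random_dna_str(300))
  locus <- tibble::tibble(species_id = "t", sequence = locus_seq)
  hits <- find_intron_ortholog(intron, locus)
  expect_gte(nrow(hits), 2)
  best <- hits[hits$is_best_hit, ]
  expect_equal(nrow(best), 1)
  # exact copy wins, at its planted location
  expect_lt(abs(best$locus_start - 300), 10)
  expect_equal(best$identity, 1)
  # oracle on the two diverged candidates: 5% copy outscores 20% copy
  score_of <- function(cand) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(intron), Biostrings::DNAString(cand),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 5, gapExtension = 2))
  }
  expect_gt(score_of(near), score_of(far))
  non_exact <- hits[!hits$is_best_hit, ]
  near_hit <- non_exact[which.min(abs(non_exact$locus_start -
                                        (300 + 200 + 200 + 200 + 150))), ]
  far_hit <- non_exact[which.min(abs(non_exact$locus_start - 700)), ]
  expect_gt(near_hit$score, far_hit$score)
  expect_error(find_intron_ortholog("", locus), "empty")
})

test_that("the e-value filter drops weak intron hits", {
  set.seed(43)
  intron <- random_dna_str(150)
  locus <- tibble::tibble(species_id = "t",
                          sequence = random_dna_str(2000))
  hits <- find_intron_ortholog(intron, locus)
  if (nrow(hits) > 0) expect_true(all(hits$evalue <= 0.1))
  strict <- find_intron_ortholog(intron, locus,
                                 search_params(e_max_nt = 1e-20))
  expect_equal(nrow(strict), 0)
})

test_that("the ortholog histogram equals the planted presence row sums", {
  sim <- small_sim()
  sets <- truth_ortholog_sets(sim) |>
    dplyr::mutate(n_orthologs = lengths(sequences) - 1L)
  hist_tab <- count_orthologs(sets)
  # oracle: direct row sums of the presence matrix
  planted <- sim$truth$presence |>
    dplyr::filter(intron_present) |>
    dplyr::count(gene_id)
  all_introns <- sim$truth$introns$gene_id
  counts <- setNames(rep(0L, length(all_introns)), all_introns)
  counts[planted$gene_id] <- planted$n
  oracle <- table(counts)
  got <- setNames(hist_tab$n_introns, hist_tab$k)
  expect_equal(got[names(oracle)], setNames(as.integer(oracle), names(oracle)))
  expect_equal(sum(hist_tab$n_introns), length(all_introns))
})

test_that("the seeded search recovers planted orthologs at moderate divergence", {
  # sensitivity of the full mapper on a small panel
  p <- sim_params(n_genes = 10, seed = 55)
  sim <- simulate_genome_set(p)
  hits <- map_orthologs(sim)
  truth_n <- sim$truth$presence |>
    dplyr::filter(intron_present) |>
    nrow()
  expect_gte(nrow(hits) / truth_n, 0.9)
})
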