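# Synthetic-data generator: hairpin evolution, genome panel, reads,
# CRAC tables, growth and competition models.

test_that("evolve_hairpin honours degenerate parameters", {
  hp <- intronscreen:::make_hairpin(c(8, 15), c(4, 8))
  expect_identical(evolve_hairpin(hp$seq, hp$pairing, 0, 0.9), hp$seq)
  expect_error(evolve_hairpin("ATAT", c(3L, 4L, 1L, 2L), 0.1, 1),
               "nested")
})

test_that("full compensation keeps every pair complementary", {
  set.seed(1)
  for (rep in 1:30) {
    hp <- intronscreen:::make_hairpin(c(8, 15), c(4, 8))
    ev <- evolve_hairpin(hp$seq, hp$pairing, 0.3, 1.0)
    ch <- strsplit(ev, "", fixed = TRUE)[[1]]
    left <- which(hp$pairing > seq_along(hp$pairing))
    expect_true(all(vapply(left, function(i) {
      intronscreen:::is_complementary(ch[i], ch[hp$pairing[i]])
    }, logical(1))))
  }
})

test_that("without compensation the disrupted-pair fraction matches the closed form", {
  # all-G:C stem so the per-pair disruption probability is exact:
  # event at G disrupts always (3/3); event at C disrupts 2/3 (C->T
  # keeps G.U); both events re-pair 4/9 of the time
  d <- 0.3
  p_disrupt <- d * (1 - d) * (1 + 2 / 3) + d^2 * (1 - 4 / 9)
  stem <- 12; loop <- 4
  seqs <- paste0(strrep("G", stem), strrep("A", loop), strrep("C", stem))
  n <- 2 * stem + loop
  pairing <- integer(n)
  pairing[1:stem] <- n:(n - stem + 1)
  pairing[n:(n - stem + 1)] <- 1:stem
  set.seed(99)
  disrupted <- 0; total <- 0
  for (rep in 1:80) {
    ev <- evolve_hairpin(seqs, pairing, d, 0)
    ch <- strsplit(ev, "", fixed = TRUE)[[1]]
    for (i in 1:stem) {
      total <- total + 1
      if (!intronscreen:::is_complementary(ch[i], ch[pairing[i]])) {
        disrupted <- disrupted + 1
      }
    }
  }
  se <- sqrt(p_disrupt * (1 - p_disrupt) / total)
  expect_lt(abs(disrupted / total - p_disrupt), 3.5 * se)
})

test_that("zero divergence reproduces the focal sequences in every species", {
  p <- sim_params(n_genes = 6, seed = 3,
                  clades = list(one = c(0, 0)),
                  retention = c(one = 1), gene_retention = c(one = 1))
  sim <- simulate_genome_set(p)
  sets <- truth_ortholog_sets(sim)
  for (i in seq_len(nrow(sets))) {
    seqs <- sets$sequences[[i]]
    expect_true(all(seqs == seqs[["focal"]]))
  }
})

test_that("structured_fraction 0 plants no hairpins", {
  p <- sim_params(n_genes = 10, seed = 4, structured_fraction = 0)
  sim <- simulate_genome_set(p)
  expect_false(any(sim$truth$introns$structured))
})

test_that("neutral substitution fraction matches the divergence rate", {
  set.seed(8)
  d <- 0.1; n <- 1000
  s <- random_dna_str(n)
  m <- intronscreen:::mutate_neutral(s, d)
  diff_frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(diff_frac - d), 3 * sqrt(d * (1 - d) / n))
})

test_that("planted introns are recoverable by coordinates from the emitted GFF3", {
  sim <- small_sim()
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotations, tmp)
  genomes <- sim$genomes[sim$genomes$species_id == "focal", ]
  back <- read_gff3(tmp, genomes, species_id = "focal")
  for (iid in sim$truth$introns$intron_id) {
    gid <- sub("\\.i1$", "", iid)
    orig <- sim$annotations[sim$annotations$gene_id == gid, ]
    reread <- back[back$gene_id == gid, ]
    expect_equal(reread$introns[[1]], orig$introns[[1]],
                 ignore_attr = TRUE)
    expect_identical(intron_seq(reread[1, ], sim$genomes, 1),
                     intron_seq(orig[1, ], sim$genomes, 1))
  }
})

test_that("read simulation conserves counts and respects zero expression", {
  sim <- small_sim()
  sim2 <- sim
  gid0 <- sim$truth$genes$gene_id[1]
  sim2$truth$genes$expression[1] <- 0
  reads <- simulate_reads(sim2)
  expect_equal(reads$total_mapped, sum(reads$ledger$true_count))
  expect_equal(sum(reads$ledger$true_count[reads$ledger$gene_id == gid0]), 0)
})

test_that("maintenance factor 1 gives intron RPKM near host RPKM", {
  p <- sim_params(n_genes = 20, seed = 21, maintenance_base = 1,
                  maintenance_multiplier = 1, structured_fraction = 0,
                  depth = 10)
  sim <- simulate_genome_set(p)
  reads <- simulate_reads(sim, p)
  led <- reads$ledger
  for (gid in unique(led$gene_id[led$class == "intron"])) {
    cds <- led[led$gene_id == gid & led$class == "CDS", ]
    intr <- led[led$gene_id == gid & led$class == "intron", ]
    if (cds$true_count < 50) next  # too noisy to compare
    r_cds <- cds$true_count / cds$length
    r_int <- intr$true_count / intr$length
    se <- r_cds * sqrt(1 / max(cds$true_count, 1) +
                         1 / max(intr$true_count, 1))
    expect_lt(abs(r_int - r_cds), 4 * se)
  }
})

test_that("CRAC simulation emits one table per experiment", {
  sim <- small_sim()
  crac <- simulate_crac(sim)
  expect_length(crac, 16)
  expect_true(all(vapply(crac, function(x) all(x$count >= 0), logical(1))))
  expect_true(all(vapply(crac, function(x) {
    setequal(x$gene_id,
             sim$truth$genes$gene_id[sim$truth$genes$has_intron])
  }, logical(1))))
})

test_that("noise-free growth curves are recovered exactly by the fit", {
  p <- sim_params(growth_noise_sd = 0, seed = 12)
  g <- simulate_growth(p, n_wells = 1)
  fit <- fit_growth(g$time_min, g$od)
  expect_equal(fit$a_max, p$growth_a, tolerance = 1e-6)
  expect_equal(fit$mu, p$growth_mu, tolerance = 1e-6)
  expect_equal(fit$lambda, p$growth_lambda, tolerance = 1e-6)
})

test_that("neutral competition keeps the mutant fraction near one half", {
  p <- sim_params(selection_s = 0, seed = 31, n_replicates = 8)
  comp <- simulate_competition(p)
  pooled <- sum(comp$assays$colonies_mutant) /
    sum(comp$assays$colonies_total)
  n <- sum(comp$assays$colonies_total)
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / n))
})

test_that("selection drives the mutant fraction to the closed-form expectation", {
  expected <- 1 / (1 + 0.95^(-37))  # ~0.13
  p <- sim_params(selection_s = -0.05, target_generations = 37,
                  seed = 32, n_replicates = 10, plating_cells = 500)
  comp <- simulate_competition(p)
  pooled <- sum(comp$assays$colonies_mutant) /
    sum(comp$assays$colonies_total)
  # generations are realised per replicate, so allow both binomial and
  # schedule spread around the closed form
  expect_lt(abs(pooled - expected), 0.05)
  # realised generation counts honour the target
  expect_true(all(abs(comp$assays$generations - 37) < 1.5))
})

test_that("the generator is deterministic in the seed", {
  a <- simulate_genome_set(sim_params(n_genes = 6, seed = 77))
  b <- simulate_genome_set(sim_params(n_genes = 6, seed = 77))
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth$introns$hairpin_start, b$truth$introns$hairpin_start)
  ra <- simulate_reads(a); rb <- simulate_reads(b)
  expect_identical(ra$reads, rb$reads)
})
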