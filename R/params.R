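#' Simulation parameters for the synthetic-data generator
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe the study conditions the pipeline is exercised
#' under: a focal yeast-like genome plus a panel of comparison species
#' in three clades of increasing divergence, a subset of introns
#' carrying planted hairpins evolved with compensatory substitutions,
#' RNA-seq read counts in which structured introns are maintained at
#' about twice the level of unstructured ones, sixteen CRAC
#' pseudo-experiments with configurable enrichment for structured-intron
#' genes, logistic growth curves sampled every 5 minutes, and a
#' serial-dilution competition assay with a selection coefficient.
#'
#' @param n_genes number of genes on the focal chromosome.
#' @param intron_fraction probability a gene carries an intron.
#' @param rp_fraction probability an intron-containing gene is named as a
#'   ribosomal-protein (RPL/RPS) gene.
#' @param clades named list; each element is a numeric vector of
#'   per-site substitution probabilities at neutral (intronic) sites,
#'   one per species in that clade. Clade order is interpreted as
#'   increasing distance from the focal species. Coding sites evolve
#'   slower, at `coding_rate_ratio` times these rates.
#' @param coding_rate_ratio ratio of the coding-site substitution rate
#'   to the intronic rate (purifying selection on exons).
#' @param retention named numeric; per-clade probability that an
#'   orthologous gene retains its intron.
#' @param gene_retention named numeric; per-clade probability that a gene
#'   has a detectable ortholog at all.
#' @param structured_fraction probability an intron carries a planted
#'   hairpin.
#' @param compensatory_rate probability that a substitution in a stem is
#'   accompanied by the partner substitution restoring complementarity.
#' @param stem_range,loop_range inclusive ranges (bp / nt) from which the
#'   planted stem length and loop length are drawn uniformly.
#' @param expr_meanlog,expr_sdlog log-normal parameters of per-gene
#'   expression.
#' @param maintenance_base post-splicing maintenance factor of an
#'   unstructured intron (intron coverage relative to its host CDS).
#' @param maintenance_multiplier multiplicative boost of the maintenance
#'   factor for structured introns (default 2, matching the roughly
#'   two-fold median expression difference the screen is expected to
#'   recover).
#' @param read_length read length in nt (fixed-length, error-free reads).
#' @param depth expected number of reads per expression unit per kb.
#' @param n_crac_experiments number of CRAC pseudo-experiments.
#' @param crac_enrichment multiplier on expected CRAC counts for
#'   structured-intron genes.
#' @param growth_a,growth_mu,growth_lambda,growth_noise_sd logistic
#'   growth parameters: maximum growth A (normalised OD), maximum growth
#'   rate mu (1/h), lag lambda (h), Gaussian noise sd.
#' @param growth_hours duration of the growth experiment in hours,
#'   sampled every 5 minutes.
#' @param selection_s per-generation selection coefficient of the mutant
#'   in the competition assay.
#' @param initial_fraction initial mutant fraction.
#' @param bottleneck cells/ml each culture is diluted back to at every
#'   transfer.
#' @param target_generations generations of competitive growth before
#'   plating.
#' @param plating_cells number of colonies counted per replicate.
#' @param n_replicates competition replicates.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 40,
                       intron_fraction = 0.8,
                       rp_fraction = 0.45,
                       clades = list(
                         sensu_stricto = c(0.10, 0.15, 0.20),
                         saccharomycetaceae = c(0.22, 0.25, 0.25),
                         outgroup = c(0.25, 0.25)
                       ),
                       coding_rate_ratio = 0.4,
                       retention = c(sensu_stricto = 0.9,
                                     saccharomycetaceae = 0.5,
                                     outgroup = 0.25),
                       gene_retention = c(sensu_stricto = 0.95,
                                          saccharomycetaceae = 0.8,
                                          outgroup = 0.6),
                       structured_fraction = 0.3,
                       compensatory_rate = 0.9,
                       stem_range = c(8L, 15L),
                       loop_range = c(4L, 8L),
                       expr_meanlog = 3,
                       expr_sdlog = 1,
                       maintenance_base = 0.3,
                       maintenance_multiplier = 2,
                       read_length = 50,
                       depth = 2,
                       n_crac_experiments = 16,
                       crac_enrichment = 10,
                       growth_a = 1.0,
                       growth_mu = 0.4,
                       growth_lambda = 2,
                       growth_noise_sd = 0.02,
                       growth_hours = 24,
                       selection_s = -0.05,
                       initial_fraction = 0.5,
                       bottleneck = 2e5,
                       target_generations = 37,
                       plating_cells = 200,
                       n_replicates = 6,
                       seed = 1) {
  check_probability(intron_fraction, "intron_fraction")
  check_probability(rp_fraction, "rp_fraction")
  check_probability(structured_fraction, "structured_fraction")
  check_probability(compensatory_rate, "compensatory_rate")
  check_probability(unlist(clades), "clades")
  check_probability(retention, "retention")
  check_probability(gene_retention, "gene_retention")
  check_probability(initial_fraction, "initial_fraction")
  check_count(n_genes, "n_genes")
  check_count(n_crac_experiments, "n_crac_experiments")
  check_count(read_length, "read_length")
  if (!setequal(names(clades), names(retention)) ||
      !setequal(names(clades), names(gene_retention))) {
    abort("`retention` and `gene_retention` must name the same clades as `clades`")
  }
  if (crac_enrichment <= 0) abort("`crac_enrichment` must be > 0")
  if (maintenance_base <= 0 || maintenance_multiplier <= 0) {
    abort("maintenance factors must be > 0")
  }
  p <- list(
    n_genes = as.integer(n_genes), intron_fraction = intron_fraction,
    rp_fraction = rp_fraction, clades = clades,
    coding_rate_ratio = coding_rate_ratio, retention = retention,
    gene_retention = gene_retention,
    structured_fraction = structured_fraction,
    compensatory_rate = compensatory_rate,
    stem_range = as.integer(stem_range), loop_range = as.integer(loop_range),
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    maintenance_base = maintenance_base,
    maintenance_multiplier = maintenance_multiplier,
    read_length = as.integer(read_length), depth = depth,
    n_crac_experiments = as.integer(n_crac_experiments),
    crac_enrichment = crac_enrichment,
    growth_a = growth_a, growth_mu = growth_mu,
    growth_lambda = growth_lambda, growth_noise_sd = growth_noise_sd,
    growth_hours = growth_hours,
    selection_s = selection_s, initial_fraction = initial_fraction,
    bottleneck = bottleneck, target_generations = target_generations,
    plating_cells = as.integer(plating_cells),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  structure(p, class = "sim_params")
}

# Per-stage seeds derive from the global seed by fixed offsets so stages
# are reproducible independently of each other.
STAGE_OFFSETS <- c(genome = 101L, reads = 211L, crac = 307L,
                   growth = 401L, competition = 503L, screen = 601L)

#' @noRd
stage_seed <- function(params, stage) {
  (params$seed + STAGE_OFFSETS[[stage]]) %% .Machine$integer.max
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic-data parameters\n")
  cat(sprintf("  genes: %d (intron fraction %.2f, structured fraction %.2f)\n",
              x$n_genes, x$intron_fraction, x$structured_fraction))
  cat(sprintf("  species: %d in %d clades\n",
              length(unlist(x$clades)), length(x$clades)))
  cat(sprintf("  maintenance: base %.2f, structured multiplier %.1f\n",
              x$maintenance_base, x$maintenance_multiplier))
  cat(sprintf("  CRAC: %d experiments, enrichment %.1f\n",
              x$n_crac_experiments, x$crac_enrichment))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Thresholds of the conserved-structure screen
#'
#' The three scorers mirror the decision logic of a three-tool consensus
#' screen: a window is called when at least `min_scorers` of the z-score,
#' structure-conservation-index and covariation channels pass.
#'
#' @param z_max maximum (most positive) thermodynamic z-score that still
#'   passes; default -2.
#' @param sci_min minimum structure conservation index; default 0.5.
#' @param cov_min minimum number of compensatory substitutions; default 1.
#' @param min_scorers how many of the three channels must pass for a
#'   window to be called (3 = strict intersection; 2 admits the
#'   two-of-three loci).
#' @param energy_min minimum folding score of the focal sequence (analog
#'   of a minimum free-energy cut-off); windows folding worse than this
#'   never pass the z channel.
#' @param pair_support minimum fraction of rows that must form the pair
#'   for a consensus pair to be predicted.
#' @param kappa covariation bonus weight in the consensus pair score.
#' @param helix_open helix-opening penalty of the consensus fold (also
#'   applied to the single-sequence folds inside the SCI denominator).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(z_max = -2, sci_min = 0.5, cov_min = 1,
                              min_scorers = 3, energy_min = 5,
                              pair_support = 0.75, kappa = 0.5,
                              helix_open = 2) {
  if (!min_scorers %in% 1:3) abort("`min_scorers` must be 1, 2 or 3")
  structure(list(z_max = z_max, sci_min = sci_min, cov_min = cov_min,
                 min_scorers = as.integer(min_scorers),
                 energy_min = energy_min,
                 pair_support = pair_support, kappa = kappa,
                 helix_open = helix_open),
            class = "screen_thresholds")
}

#' Parameters of the ortholog search
#'
#' Defaults follow the screen's search settings: translated search with
#' e-value cut-off 1e-6 and a 65% query-coverage rule; nucleotide intron
#' search with word size 3 and e-value cut-off 0.1; 1000 nt of 5' and
#' 300 nt of 3' flank added around gene hits (transcript orientation).
#'
#' @param e_max_protein,e_max_nt e-value cut-offs for the translated and
#'   nucleotide searches.
#' @param min_coverage minimum query coverage of a gene-level hit.
#' @param flank_5p,flank_3p flank lengths (nt) added around gene hits.
#' @param word_protein,word_nt seed word sizes.
#' @param seed_threshold minimum BLOSUM62 score of a 3-mer seed match.
#' @param min_segment_score minimum score of an ungapped extended
#'   segment to enter chaining.
#' @param xdrop_protein,xdrop_nt X-drop extension cut-offs.
#' @param max_chain_gap maximum diagonal/coordinate gap (nt) when
#'   chaining seed hits into a gene-level hit.
#' @param gap_open_protein,gap_extend_protein,gap_open_nt,gap_extend_nt
#'   affine gap penalties.
#' @param match_nt,mismatch_nt nucleotide match/mismatch scores.
#' @param lambda_protein,k_protein,lambda_nt,k_nt Karlin-Altschul style
#'   constants for the e-value approximation.
#' @return A list of class `search_params`.
#' @export
search_params <- function(e_max_protein = 1e-6, e_max_nt = 0.1,
                          min_coverage = 0.65,
                          flank_5p = 1000L, flank_3p = 300L,
                          word_protein = 3L, word_nt = 3L,
                          seed_threshold = 11,
                          min_segment_score = 40,
                          xdrop_protein = 20, xdrop_nt = 10,
                          max_chain_gap = 1000L,
                          gap_open_protein = 11, gap_extend_protein = 1,
                          gap_open_nt = 5, gap_extend_nt = 2,
                          match_nt = 2, mismatch_nt = -3,
                          lambda_protein = 0.267, k_protein = 0.041,
                          lambda_nt = 0.625, k_nt = 0.41) {
  structure(list(
    e_max_protein = e_max_protein, e_max_nt = e_max_nt,
    min_coverage = min_coverage,
    flank_5p = as.integer(flank_5p), flank_3p = as.integer(flank_3p),
    word_protein = as.integer(word_protein), word_nt = as.integer(word_nt),
    seed_threshold = seed_threshold,
    min_segment_score = min_segment_score,
    xdrop_protein = xdrop_protein, xdrop_nt = xdrop_nt,
    max_chain_gap = as.integer(max_chain_gap),
    gap_open_protein = gap_open_protein,
    gap_extend_protein = gap_extend_protein,
    gap_open_nt = gap_open_nt, gap_extend_nt = gap_extend_nt,
    match_nt = match_nt, mismatch_nt = mismatch_nt,
    lambda_protein = lambda_protein, k_protein = k_protein,
    lambda_nt = lambda_nt, k_nt = k_nt
  ), class = "search_params")
}
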