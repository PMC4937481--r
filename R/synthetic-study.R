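# Counts-level study simulator: draws per-gene expression and
# per-feature read counts directly, without materialising genomes or
# reads. Used for calibration studies (null p-value uniformity,
# top-decile flagging, group-comparison recapitulation) where only the
# count tables matter and hundreds of replicate simulations are run.

#' Simulate an expression study at the counts level
#'
#' Draws the same gene-level quantities as [simulate_genome_set()]
#' (ribosomal-protein flags, planted-structure flags, log-normal
#' expression, maintenance factors) and Poisson feature counts as
#' [simulate_reads()], but skips sequence and read generation.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (defaults to the reads-stage seed derived
#'   from `params$seed`).
#' @return A list with `features` (tibble: `feature_id`, `class`,
#'   `gene_id`, `count`, `length`), `genes` (tibble with `gene_id`,
#'   `is_rp`, `has_intron`, `structured`, `expression`,
#'   `maintenance_factor`), and `total_mapped`.
#' @export
simulate_expression_study <- function(params = sim_params(), seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(params, "reads")
  set.seed(seed)
  n <- params$n_genes
  has_intron <- runif(n) < params$intron_fraction
  is_rp <- has_intron & runif(n) < params$rp_fraction
  structured <- has_intron & runif(n) < params$structured_fraction
  gene_id <- sprintf("%s%03d", ifelse(is_rp, sample(c("RPL", "RPS"), n,
                                                    replace = TRUE), "YGEN"),
                     seq_len(n))
  expression <- rlnorm(n, params$expr_meanlog, params$expr_sdlog)
  maintenance <- ifelse(structured,
                        params$maintenance_base * params$maintenance_multiplier,
                        params$maintenance_base)
  cds_len <- sample(300:900, n, replace = TRUE)
  intron_len <- sample(150:350, n, replace = TRUE)

  feats <- list(tibble(feature_id = gene_id, class = "CDS",
                       gene_id = gene_id,
                       count = rpois(n, expression * cds_len / 1000 *
                                       params$depth),
                       length = cds_len))
  sel <- which(has_intron)
  feats[[2]] <- tibble(feature_id = paste0(gene_id[sel], ".i1"),
                       class = "intron", gene_id = gene_id[sel],
                       count = rpois(length(sel),
                                     expression[sel] * maintenance[sel] *
                                       intron_len[sel] / 1000 * params$depth),
                       length = intron_len[sel])
  features <- bind_rows(feats)
  genes <- tibble(gene_id = gene_id, is_rp = is_rp,
                  has_intron = has_intron, structured = structured,
                  expression = expression,
                  maintenance_factor = ifelse(has_intron, maintenance, NA))
  list(features = features, genes = genes,
       total_mapped = sum(features$count))
}
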