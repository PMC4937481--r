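# End-to-end driver: generate (or load) inputs, run every analysis
# stage, and write the stage artifacts (TSV / FASTA / GFF3 / SAM /
# Stockholm) plus a run log echoing all parameters.

#' Run the full pipeline on synthetic data
#'
#' Generates a synthetic genome panel, maps orthologous introns,
#' screens for conserved structures, quantifies intron/CDS expression
#' from simulated reads, scores exosome association from simulated
#' CRAC tables, and computes growth/competition/qPCR analytics.
#' All stage outputs are written under `outdir`; the same parameters
#' and seed reproduce byte-identical outputs.
#'
#' @param params a [sim_params()] object (includes the seed).
#' @param outdir output directory (created if missing).
#' @param search a [search_params()] object.
#' @param thresholds a [screen_thresholds()] object.
#' @param use_mapper map orthologs with the search stage (default);
#'   when FALSE, ortholog sets are assembled from the generator's
#'   coordinates instead (faster, search stage skipped).
#' @return A list with the main result tables: `ortholog_sets`,
#'   `histogram`, `candidates`, `expression`, `group_stats`,
#'   `exosome`, `growth`, `competition`, and `truth`.
#' @export
run_pipeline <- function(params = sim_params(), outdir = tempfile("run"),
                         search = search_params(),
                         thresholds = screen_thresholds(),
                         use_mapper = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- c(sprintf("intronscreen %s",
                         as.character(utils::packageVersion("intronscreen"))),
                 sprintf("seed: %d", params$seed),
                 sprintf("param %s: %s", names(unclass(params)),
                         vapply(unclass(params), function(v) {
                           paste(format(unlist(v)), collapse = ",")
                         }, "")))
  writeLines(log_lines, log_path)

  # --- simulate
  sim <- simulate_genome_set(params)
  for (sp in unique(sim$genomes$species_id)) {
    write_fasta(sim$genomes |> filter(.data$species_id == sp),
                file.path(outdir, paste0("genome_", sp, ".fasta")))
  }
  write_gff3(sim$annotations, file.path(outdir, "annotations.gff3"))
  reads <- simulate_reads(sim, params, path = file.path(outdir, "reads.sam"))
  crac <- simulate_crac(sim, params, dir = outdir)
  growth <- simulate_growth(params, path = file.path(outdir, "growth.tsv"))
  comp <- simulate_competition(params,
                               path = file.path(outdir, "competition.tsv"))

  # --- orthologs
  sets <- if (use_mapper) {
    hits <- map_orthologs(sim, search)
    build_ortholog_sets(sim, hits)
  } else {
    truth_ortholog_sets(sim) |>
      mutate(n_orthologs = lengths(.data$sequences) - 1L)
  }
  hist_tab <- count_orthologs(sets)
  write_tsv_meta(hist_tab, file.path(outdir, "histogram.tsv"),
                 meta = c(stage = "orthologs"))

  # --- structure screen
  screen <- screen_ortholog_sets(sets, thresholds,
                                 seed = stage_seed(params, "screen"))
  tree <- species_tree(params)
  cand <- screen$candidates
  if (nrow(cand) > 0) {
    cand$clade <- vapply(seq_len(nrow(cand)), function(i) {
      conservation_extent(cand[i, ], tree,
                          pair_support = thresholds$pair_support)
    }, "")
    for (i in seq_len(nrow(cand))) {
      w <- cand$window[[i]]
      write_stockholm(w$rows,
                      file.path(outdir, sprintf("candidate_%s_%d.stk",
                                                cand$intron_id[i], i)),
                      ss_cons = cand$structure[i])
    }
    write_tsv_meta(cand |> select("intron_id", "focal_start", "focal_end",
                                  "z", "sci", "n_compensatory",
                                  "pass_z", "pass_sci", "pass_cov", "clade"),
                   file.path(outdir, "candidates.tsv"),
                   meta = c(stage = "screen"))
  } else {
    write_tsv_meta(tibble(intron_id = character()),
                   file.path(outdir, "candidates.tsv"),
                   meta = c(stage = "screen"))
  }
  predicted_ids <- unique(cand$intron_id)

  # --- expression quantification
  aln <- read_sam(file.path(outdir, "reads.sam"))
  features <- annotation_features(sim$annotations)
  counted <- count_reads(aln, features)
  expr <- expression_table(counted, aln$total_mapped, predicted_ids)
  write_tsv_meta(expr, file.path(outdir, "expression.tsv"),
                 meta = c(stage = "expression",
                          total_mapped = aln$total_mapped))
  group_stats <- group_compare(expr)
  write_tsv_meta(group_stats, file.path(outdir, "group_stats.tsv"))

  # --- exosome association
  orf <- expr |> filter(.data$class == "CDS")
  exo <- average_and_flag(crac, orf)
  write_tsv_meta(exo, file.path(outdir, "exosome_scores.tsv"))

  # --- phenotype
  gp <- growth |>
    group_by(.data$well) |>
    summarise(fit = list(fit_growth(.data$time_min, .data$od)),
              .groups = "drop") |>
    mutate(tidy = purrr::map(.data$fit, generics::tidy)) |>
    tidyr::unnest("tidy") |> select(-"fit")
  write_tsv_meta(gp, file.path(outdir, "growth_params.tsv"))
  ct <- competition_test(comp$assays$colonies_mutant,
                         comp$assays$colonies_total)
  comp_stats <- tibble(n = nrow(comp$assays),
                       mean_generations = mean(comp$assays$generations),
                       mean_fraction = ct$mean_fraction,
                       t = ct$t, p = ct$p)
  write_tsv_meta(comp_stats, file.path(outdir, "competition_stats.tsv"))

  list(ortholog_sets = sets, histogram = hist_tab, candidates = cand,
       expression = expr, group_stats = group_stats, exosome = exo,
       growth = gp, competition = comp_stats, truth = sim$truth,
       outdir = outdir)
}

#' Compare screen calls against the planted truth
#'
#' @param candidates candidate tibble (with `intron_id`).
#' @param sets ortholog-set tibble carrying `intron_id`.
#' @param truth truth ledger of the `genome_sim`.
#' @return A list with `sensitivity` (fraction of screened structured
#'   introns called), `fpr` (fraction of screened unstructured introns
#'   called), and the per-intron call table.
#' @export
screen_performance <- function(candidates, sets, truth) {
  screened <- sets |>
    filter(lengths(.data$sequences) >= 2) |>
    select("intron_id") |>
    left_join(truth$introns |> select("intron_id", "structured"),
              by = "intron_id") |>
    mutate(called = .data$intron_id %in% unique(candidates$intron_id))
  pos <- screened |> filter(.data$structured)
  neg <- screened |> filter(!.data$structured)
  list(sensitivity = if (nrow(pos)) mean(pos$called) else NA_real_,
       fpr = if (nrow(neg)) mean(neg$called) else NA_real_,
       calls = screened)
}
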