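# Exosome-association scoring from CRAC cross-linking count tables:
# per-experiment normalisation by ORF expression, percentile ranks,
# averaging across experiments, and the top-decile flag.

#' Normalise CRAC counts by ORF expression
#'
#' @param crac tibble with `gene_id` and `count` (one CRAC experiment).
#' @param orf_rpkm tibble with `gene_id` and `rpkm` (ORF expression of
#'   the same gene universe, from [expression_table()] rows of class
#'   "CDS").
#' @return A tibble with `gene_id`, `normalized` (count / ORF RPKM) and
#'   `scorable` (FALSE when the ORF RPKM is 0 or the gene is absent
#'   from the ORF table).
#' @export
normalize_crac <- function(crac, orf_rpkm) {
  crac |>
    left_join(orf_rpkm |> select("gene_id", "rpkm"), by = "gene_id") |>
    mutate(scorable = !is.na(.data$rpkm) & .data$rpkm > 0,
           normalized = ifelse(.data$scorable, .data$count / .data$rpkm,
                               NA_real_)) |>
    select("gene_id", "normalized", "scorable")
}

#' Percentile ranks (mean-rank convention)
#'
#' rank(x) = 100 * (r_mean - 0.5) / N, where r_mean is the mean rank of
#' x among the N values (ties share the mean rank). With no ties the
#' ranks of N values have mean exactly 50.
#'
#' @param values numeric vector (>= 2 values).
#' @return Percentile ranks between 0 and 100.
#' @export
percentile_rank <- function(values) {
  if (length(values) < 2) abort("need at least 2 values to rank")
  r <- rank(values, ties.method = "average")
  100 * (r - 0.5) / length(values)
}

#' Average percentile ranks across experiments and flag the top decile
#'
#' Per gene, the average percentile rank over the experiments in which
#' it was scorable; genes whose average falls at or above the (1 - q)
#' quantile over all genes are flagged as preferentially bound.
#'
#' @param crac_list named list of CRAC experiment tibbles (`gene_id`,
#'   `count`).
#' @param orf_rpkm ORF expression tibble (`gene_id`, `rpkm`).
#' @param q top fraction to flag (default 0.10).
#' @return A tibble with `gene_id`, `n_experiments`,
#'   `average_percentile`, `top_decile`.
#' @export
average_and_flag <- function(crac_list, orf_rpkm, q = 0.10) {
  ranks <- purrr::imap(crac_list, function(crac, nm) {
    norm <- normalize_crac(crac, orf_rpkm) |> filter(.data$scorable)
    if (nrow(norm) < 2) return(NULL)
    tibble(gene_id = norm$gene_id,
           experiment = nm,
           percentile = percentile_rank(norm$normalized))
  })
  ranks <- bind_rows(purrr::compact(ranks))
  if (nrow(ranks) == 0) abort("no scorable experiment")
  scores <- ranks |>
    group_by(.data$gene_id) |>
    summarise(n_experiments = n(),
              average_percentile = mean(.data$percentile),
              .groups = "drop")
  cutoff <- quantile(scores$average_percentile, 1 - q, type = 7)
  scores |> mutate(top_decile = .data$average_percentile >= cutoff)
}
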