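# Growth-curve and competition-assay simulators. The logistic model is
# parameterised directly in (A, mu, lambda) so that a perfect fit
# recovers the generating values:
#   od(t) = A / (1 + exp(4 * mu * (lambda - t) / A + 2))
# (mu is the slope at the inflection point and lambda the x-intercept
# of the tangent there - the standard sigmoid growth parameterisation).

#' @noRd
logistic_growth <- function(t, a, mu, lambda) {
  a / (1 + exp(4 * mu * (lambda - t) / a + 2))
}

#' @noRd
gompertz_growth <- function(t, a, mu, lambda) {
  a * exp(-exp(mu * exp(1) * (lambda - t) / a + 1))
}

#' Simulate plate-reader growth curves
#'
#' Logistic curves sampled every 5 minutes with additive Gaussian
#' noise.
#'
#' @param params [sim_params()]; uses `growth_a`, `growth_mu`,
#'   `growth_lambda`, `growth_noise_sd`, `growth_hours`.
#' @param n_wells number of replicate wells.
#' @param path optional TSV output path (`time_min`, `well`, `od`).
#' @return A tibble with `time_min`, `well`, `od`.
#' @export
simulate_growth <- function(params = sim_params(), n_wells = 3,
                            path = NULL) {
  set.seed(stage_seed(params, "growth"))
  t_min <- seq(0, params$growth_hours * 60, by = 5)
  t_h <- t_min / 60
  out <- purrr::map(seq_len(n_wells), function(w) {
    od <- logistic_growth(t_h, params$growth_a, params$growth_mu,
                          params$growth_lambda) +
      rnorm(length(t_h), 0, params$growth_noise_sd)
    tibble(time_min = t_min, well = sprintf("A%d", w), od = od)
  })
  out <- bind_rows(out)
  if (!is.null(path)) write_tsv_meta(out, path)
  out
}

#' Simulate a serial-dilution competition assay
#'
#' Mutant and reference strains start at equal density; the mutant's
#' per-generation fitness is `1 + s`. Cultures are diluted back to the
#' bottleneck density each transfer; the realised generation count is
#' the sum of log2 fold-expansions. At the end, `plating_cells`
#' colonies are sampled binomially from the final mutant fraction.
#'
#' @param params [sim_params()]; uses `selection_s`, `initial_fraction`,
#'   `bottleneck`, `target_generations`, `plating_cells`,
#'   `n_replicates`.
#' @param path optional TSV output path.
#' @return A list with `assays` (tibble: `replicate`, `generations`,
#'   `true_fraction`, `colonies_total`, `colonies_mutant`) and
#'   `transfers` (tibble: `replicate`, `transfer`, `pre_density`).
#' @export
simulate_competition <- function(params = sim_params(), path = NULL) {
  set.seed(stage_seed(params, "competition"))
  per_transfer <- 3  # nominal doublings per growth cycle
  assays <- list()
  transfers <- list()
  for (r in seq_len(params$n_replicates)) {
    g <- 0
    tr <- 0
    while (g < params$target_generations) {
      gen <- min(per_transfer + rnorm(1, 0, 0.15),
                 params$target_generations - g + 0.0)
      gen <- max(gen, 0.5)
      tr <- tr + 1
      g <- g + gen
      transfers[[length(transfers) + 1]] <- tibble(
        replicate = r, transfer = tr,
        pre_density = params$bottleneck * 2^gen)
    }
    f <- 1 / (1 + (1 / params$initial_fraction - 1) *
                (1 + params$selection_s)^(-g))
    mut <- rbinom(1, params$plating_cells, f)
    assays[[length(assays) + 1]] <- tibble(
      replicate = r, generations = g, true_fraction = f,
      colonies_total = params$plating_cells, colonies_mutant = mut)
  }
  out <- list(assays = bind_rows(assays), transfers = bind_rows(transfers))
  if (!is.null(path)) write_tsv_meta(out$assays, path)
  out
}

#' Simulate a qPCR Ct table for the delta-delta-Ct analysis
#'
#' @param fold true fold change of the target in the sample vs control.
#' @param n_replicates technical replicates.
#' @param ct_ref baseline reference-gene Ct.
#' @param ct_target baseline target-gene Ct in the control.
#' @param noise_sd Gaussian Ct noise.
#' @param seed integer seed.
#' @return A tibble with `replicate`, `ct_target_sample`,
#'   `ct_ref_sample`, `ct_target_control`, `ct_ref_control`.
#' @export
simulate_qpcr <- function(fold = 0.57, n_replicates = 3, ct_ref = 15,
                          ct_target = 20, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  tibble(
    replicate = seq_len(n_replicates),
    ct_target_sample = ct_target - log2(fold) + rnorm(n_replicates, 0, noise_sd),
    ct_ref_sample = ct_ref + rnorm(n_replicates, 0, noise_sd),
    ct_target_control = ct_target + rnorm(n_replicates, 0, noise_sd),
    ct_ref_control = ct_ref + rnorm(n_replicates, 0, noise_sd)
  )
}
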