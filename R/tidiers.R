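# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted growth curve
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return One-row tibble with `a_max`, `mu`, `lambda`, `auc`, `model`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(a_max = x$a_max, mu = x$mu, lambda = x$lambda, auc = x$auc,
         model = x$model)
}

#' One-line summary of a fitted growth curve
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return One-row tibble with fit diagnostics.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(model = x$model, residual = x$residual, fallback = x$fallback,
         n = length(x$time_min))
}

#' Tidy a consensus fold
#'
#' @param x a `consensus_fold`.
#' @param ... unused.
#' @return The pair table with support and covariation counts.
#' @export
tidy.consensus_fold <- function(x, ...) {
  x$pairs
}

#' One-line summary of a consensus fold
#'
#' @param x a `consensus_fold`.
#' @param ... unused.
#' @return One-row tibble with `score` and `n_pairs`.
#' @export
glance.consensus_fold <- function(x, ...) {
  tibble(score = x$score, n_pairs = x$n_pairs)
}
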