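#' Tidy a mixture fit
#'
#' @param x A `psmix_fit`.
#' @param ... Unused.
#' @return A tibble with one row per charge and parameter: `charge`, `term`
#'   (e.g. `pi0`, `negative.alpha`, `positive.mu`), `estimate`.
#' @export
tidy.psmix_fit <- function(x, ...) {
  tb <- fit_params_tibble(x)
  dplyr::rename(tb, estimate = "value")
}

#' Summarize a mixture fit in one row
#'
#' @param x A `psmix_fit`.
#' @param ... Unused.
#' @return A one-row tibble: fitting method, negative family, number of
#'   charges fit and skipped, total records, whether all charges converged,
#'   total iterations, summed log-likelihood.
#' @export
glance.psmix_fit <- function(x, ...) {
  tibble::tibble(
    method = x$options$method,
    negative = x$options$negative %||% "kernel",
    n_charges = length(x$models),
    n_skipped = length(x$skipped),
    n_records = sum(x$n_records),
    converged = all(x$converged),
    total_iterations = sum(x$n_iterations),
    loglik = sum(x$loglik)
  )
}

#' Tidy a bootstrap result
#'
#' @param x A `psmix_bootstrap`.
#' @param ... Unused.
#' @return The per-parameter summary tibble: `charge`, `term`, `original`,
#'   `bias`, `variance`, `mse`.
#' @export
tidy.psmix_bootstrap <- function(x, ...) {
  x$summaries
}

#' Summarize a bootstrap result in one row
#'
#' @param x A `psmix_bootstrap`.
#' @param ... Unused.
#' @return A one-row tibble: `B`, `n_failed`, `seed`, and the largest
#'   per-parameter MSE observed.
#' @export
glance.psmix_bootstrap <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, seed = x$seed,
                 max_mse = max(x$summaries$mse))
}
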