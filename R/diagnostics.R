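#' Bootstrap stability assessment of a mixture fit
#'
#' Deviations from the model assumptions or a small number of identified
#' spectra make the EM fit unstable. `bootstrap_fit()` quantifies this by
#' resampling records with replacement `B` times (within each charge
#' stratum, preserving per-charge counts, since models are fit per charge),
#' refitting with identical options, and summarizing every parameter's
#' resampled estimates by
#'
#' * `bias = mean(resampled) - original`,
#' * `variance` = sample variance of the resampled estimates,
#' * `mse = variance + bias^2`.
#'
#' At least 100-500 bootstrap samples are recommended for stable summaries.
#' Resamples whose refit fails (EM can degenerate on unlucky resamples of
#' small data — itself a diagnostic signal) are excluded with a warning;
#' more than 20% failures is an error.
#'
#' @param table A PSM table with `discriminant_score`.
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param fit_fn Fitting function applied to each resample (default
#'   [fit_em()]).
#' @param ... Options passed on to `fit_fn`.
#' @return A `psmix_bootstrap` object with elements `estimates` (tibble:
#'   `replicate`, `charge`, `term`, `value`), `original`, `summaries`
#'   (tibble: `charge`, `term`, `original`, `bias`, `variance`, `mse`),
#'   `B`, `seed`, `n_failed`.
#' @export
bootstrap_fit <- function(table, B = 200, seed = 1, fit_fn = fit_em, ...) {
  stopifnot(B >= 2)
  table <- validate_psm_table(table)
  base_fit <- fit_fn(table, ...)
  original <- fit_params_tibble(base_fit)

  set.seed(seed)
  idx_by_charge <- split(seq_len(nrow(table)), table$charge)
  est <- vector("list", B)
  n_failed <- 0
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_charge, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    boot_tab <- table[take, , drop = FALSE]
    # resampled rows are pseudo-records; relabel so duplicated draws do not
    # trip the (spectrum_id, rank) uniqueness invariant
    boot_tab$spectrum_id <- sprintf("boot%d_%06d", b, seq_len(nrow(boot_tab)))
    res <- tryCatch(
      suppressWarnings(fit_fn(boot_tab, ...)),
      error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1
    } else {
      tb <- fit_params_tibble(res)
      tb$replicate <- b
      est[[b]] <- tb
    }
  }
  if (n_failed > 0.2 * B)
    stop(n_failed, " of ", B, " bootstrap refits failed", call. = FALSE)
  if (n_failed > 0)
    warning(n_failed, " of ", B, " bootstrap refits failed and were excluded",
            call. = FALSE)
  estimates <- dplyr::bind_rows(est)

  summaries <- estimates |>
    dplyr::group_by(.data$charge, .data$term) |>
    dplyr::summarise(boot_mean = mean(.data$value),
                     variance = stats::var(.data$value), .groups = "drop") |>
    dplyr::inner_join(dplyr::rename(original, original = "value"),
                      by = c("charge", "term")) |>
    dplyr::mutate(bias = .data$boot_mean - .data$original,
                  mse = .data$variance + .data$bias^2) |>
    dplyr::select("charge", "term", "original", "bias", "variance", "mse")

  structure(list(estimates = estimates[, c("replicate", "charge", "term", "value")],
                 original = original, summaries = summaries,
                 B = B, seed = seed, n_failed = n_failed),
            class = "psmix_bootstrap")
}

fit_params_tibble <- function(fit) {
  purrr::imap(fit$models, function(m, ch) {
    p <- model_params(m)
    tibble::tibble(charge = as.integer(ch), term = names(p),
                   value = unname(p))
  }) |> dplyr::bind_rows()
}

#' @export
print.psmix_bootstrap <- function(x, ...) {
  cat("<psmix bootstrap: B = ", x$B, ", seed = ", x$seed,
      if (x$n_failed > 0) paste0(", ", x$n_failed, " failed refits"),
      ">\n", sep = "")
  print(x$summaries, n = Inf)
  invisible(x)
}

#' Matched quantile pairs for a quantile-quantile plot
#'
#' Computes `(Q_a(p), Q_b(p))` at `p = k / n_quantiles`, `k = 1..n_quantiles`,
#' with `Q` the empirical quantile (linear interpolation between order
#' statistics, `stats::quantile()` type 7). Two samples from the same
#' distribution give pairs close to the diagonal; deviations localize where
#' the distributions differ — for mixture fits, the center and right of the
#' plot matter most, as confidence estimates lean on a good fit there.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param n_quantiles Number of quantile pairs (>= 2), default 100.
#' @return A tibble with columns `p`, `q_a`, `q_b`.
#' @export
qq_pairs <- function(sample_a, sample_b, n_quantiles = 100) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1, n_quantiles >= 2)
  p <- seq_len(n_quantiles) / n_quantiles
  tibble::tibble(
    p = p,
    q_a = unname(stats::quantile(sample_a, p, type = 7)),
    q_b = unname(stats::quantile(sample_b, p, type = 7))
  )
}
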