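#' Plot a fitted score mixture
#'
#' Draws, per charge, the fitted component curves — `pi0 f0(s)` for
#' incorrect matches, `(1 - pi0) f1(s)` for correct ones, and their sum —
#' optionally over a histogram of the observed scores. Visual inspection of
#' this plot (do the curves track the histogram, especially in the right
#' tail of the incorrect component and the left tail of the correct one?) is
#' the recommended quality-of-fit check.
#'
#' @param object A `psmix_fit`.
#' @param table Optional PSM table to draw the score histogram from.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object, faceted by charge.
#' @export
autoplot.psmix_fit <- function(object, table = NULL, bins = 60, ...) {
  grids <- purrr::imap(object$models, function(m, ch) {
    if (!is.null(table)) {
      s <- table$discriminant_score[table$charge == as.integer(ch)]
      rng <- range(s)
    } else if (m$negative$kind == "kernel") {
      rng <- range(m$negative$kde$points, m$positive$kde$points)
    } else {
      mom <- rbind(component_moments(m$negative), component_moments(m$positive))
      rng <- c(min(mom[, "mean"] - 4 * mom[, "sd"]),
               max(mom[, "mean"] + 4 * mom[, "sd"]))
    }
    s_grid <- seq(rng[1], rng[2], length.out = 400)
    tibble::tibble(
      charge = as.integer(ch), score = rep(s_grid, 3),
      density = c(m$pi0 * component_density(m$negative, s_grid),
                  (1 - m$pi0) * component_density(m$positive, s_grid),
                  mixture_density(m, s_grid)),
      component = rep(c("incorrect", "correct", "mixture"), each = 400)
    )
  })
  curves <- dplyr::bind_rows(grids)
  p <- ggplot2::ggplot()
  if (!is.null(table)) {
    dat <- tibble::tibble(charge = table$charge,
                          score = table$discriminant_score)
    dat <- dat[dat$charge %in% as.integer(names(object$models)), ]
    p <- p + ggplot2::geom_histogram(
      data = dat,
      ggplot2::aes(x = .data$score, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", color = "grey70")
  }
  p +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$score, y = .data$density,
                                    color = .data$component),
                       linewidth = 0.7) +
    ggplot2::scale_color_manual(values = c(incorrect = "#d73027",
                                           correct = "#4575b4",
                                           mixture = "grey30")) +
    ggplot2::facet_wrap(~charge, scales = "free", labeller = "label_both") +
    ggplot2::labs(x = "discriminant score", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap parameter distributions
#'
#' Histograms of the resampled estimates for each parameter and charge, with
#' the original estimate marked by a vertical line. Skewed or wide
#' distributions flag unstable fits (typically too few identified spectra).
#'
#' @param object A `psmix_bootstrap`.
#' @param terms Optional character vector restricting the parameters shown.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object faceted by charge and parameter.
#' @export
autoplot.psmix_bootstrap <- function(object, terms = NULL, bins = 30, ...) {
  est <- object$estimates
  orig <- object$original
  if (!is.null(terms)) {
    est <- est[est$term %in% terms, ]
    orig <- orig[orig$term %in% terms, ]
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey80", color = "grey60") +
    ggplot2::geom_vline(data = orig,
                        ggplot2::aes(xintercept = .data$value),
                        color = "#d73027", linewidth = 0.7) +
    ggplot2::facet_wrap(charge ~ term, scales = "free",
                        labeller = "label_both") +
    ggplot2::labs(x = "bootstrap estimate", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot confidence measures against the score
#'
#' Shows PEP, p-value, FDR and q-value as functions of the discriminant
#' score for each charge (targets only).
#'
#' @param object A `psmix_confidence` table from [build_confidence_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psmix_confidence <- function(object, ...) {
  dat <- object[!object$is_decoy, ] |>
    tidyr::pivot_longer(c("pep", "p_value", "fdr", "q_value"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$value,
                                    color = .data$measure)) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::facet_wrap(~charge, labeller = "label_both") +
    ggplot2::labs(x = "discriminant score", y = "estimated probability") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of two samples
#'
#' Plots the matched quantile pairs from [qq_pairs()] with the identity
#' line; deviations localize where two distributions differ.
#'
#' @param pairs A tibble from [qq_pairs()].
#' @return A ggplot object.
#' @export
plot_qq <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$q_a, y = .data$q_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "sample A quantiles", y = "sample B quantiles") +
    ggplot2::theme_minimal()
}
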