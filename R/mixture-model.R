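#' Discrete feature tables
#'
#' Per-component categorical distributions for the auxiliary discrete
#' features: number of tryptic termini (`ntt`), number of missed cleavages
#' (`nmc`), and the binned precursor mass difference (`delta_mass_bin`).
#' Conditional on a match being correct or incorrect, these features are
#' modeled as independent of the score and of each other, each with its own
#' probability vector per component.
#'
#' @param feature Feature name (`"ntt"`, `"nmc"`, `"delta_mass_bin"` or any
#'   label).
#' @param levels Ordered vector of observed levels.
#' @param p_incorrect,p_correct Probability vectors over `levels` for the
#'   incorrect and correct components; each must sum to 1 within 1e-9.
#' @return A `psmix_discrete` object.
#' @export
discrete_feature_table <- function(feature, levels, p_incorrect, p_correct) {
  stopifnot(length(levels) == length(p_incorrect),
            length(levels) == length(p_correct))
  if (any(p_incorrect < 0) || any(p_correct < 0))
    stop("discrete probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p_incorrect) - 1) > 1e-9 || abs(sum(p_correct) - 1) > 1e-9)
    stop("discrete probability vectors must sum to 1", call. = FALSE)
  structure(list(feature = feature, levels = levels,
                 p_incorrect = unname(p_incorrect),
                 p_correct = unname(p_correct)),
            class = "psmix_discrete")
}

# Per-record component factor for one discrete feature; unseen or NA levels
# contribute a factor of 1 (the feature is skipped for that record).
discrete_factor <- function(tab, values, component = c("incorrect", "correct")) {
  component <- match.arg(component)
  p <- if (component == "incorrect") tab$p_incorrect else tab$p_correct
  idx <- match(values, tab$levels)
  out <- p[idx]
  out[is.na(idx)] <- 1
  out
}

#' Two-component mixture model for PSM scores
#'
#' Bundles the mixing weight `pi0` (the overall proportion of incorrect
#' identifications), the negative (incorrect) and positive (correct) score
#' components, and any fitted discrete feature tables for one precursor
#' charge. The observed score density is
#' `pi0 * f0(s) + (1 - pi0) * f1(s)`, with each component further multiplied
#' by its discrete-feature probabilities when those are modeled.
#'
#' @param charge Integer charge the model applies to.
#' @param pi0 Proportion of incorrect identifications, in `[0, 1]`.
#' @param negative,positive `psmix_dist` components for incorrect and correct
#'   matches.
#' @param discrete Named list of [discrete_feature_table()] objects, keyed by
#'   the PSM-table column holding the feature's level.
#' @return A `psmix_model` object.
#' @export
mixture_model <- function(charge, pi0, negative, positive, discrete = list()) {
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1)
    stop("`pi0` must be in [0, 1]", call. = FALSE)
  stopifnot(inherits(negative, "psmix_dist"), inherits(positive, "psmix_dist"))
  structure(list(charge = as.integer(charge), pi0 = pi0,
                 negative = negative, positive = positive,
                 discrete = discrete),
            class = "psmix_model")
}

#' @export
print.psmix_model <- function(x, ...) {
  cat("<psmix mixture model, charge ", x$charge, ">\n", sep = "")
  cat("  pi0 (incorrect proportion):", signif(x$pi0, 5), "\n")
  cat("  negative: "); print(x$negative)
  cat("  positive: "); print(x$positive)
  if (length(x$discrete) > 0)
    cat("  discrete features:", paste(names(x$discrete), collapse = ", "), "\n")
  invisible(x)
}

model_params <- function(model) {
  c(pi0 = model$pi0,
    stats::setNames(component_params(model$negative),
                    paste0("negative.", names(component_params(model$negative)))),
    stats::setNames(component_params(model$positive),
                    paste0("positive.", names(component_params(model$positive)))))
}

# pi0*f0*fac0 and (1-pi0)*f1*fac1 for a score vector and optional levels
# (a data frame/list with one entry per discrete feature in the model).
mixture_terms <- function(model, scores, levels = NULL) {
  t0 <- model$pi0 * component_density(model$negative, scores)
  t1 <- (1 - model$pi0) * component_density(model$positive, scores)
  for (feat in names(model$discrete)) {
    if (!is.null(levels) && feat %in% names(levels)) {
      tab <- model$discrete[[feat]]
      t0 <- t0 * discrete_factor(tab, levels[[feat]], "incorrect")
      t1 <- t1 * discrete_factor(tab, levels[[feat]], "correct")
    }
  }
  list(t0 = t0, t1 = t1)
}

#' Observed-data mixture density
#'
#' Evaluates `pi0 * f0(s) * prod(f0,feat) + (1 - pi0) * f1(s) * prod(f1,feat)`
#' at the given scores (and optional discrete levels).
#'
#' @inheritParams e_step
#' @return Numeric vector of mixture densities.
#' @export
mixture_density <- function(model, scores, levels = NULL) {
  tm <- mixture_terms(model, scores, levels)
  tm$t0 + tm$t1
}

#' E-step: posterior error probability of a score
#'
#' Applies Bayes' theorem to the fitted two-component mixture:
#' `PEP(s) = pi0 f0(s) prod(f0,feat) / (pi0 f0(s) prod(f0,feat) +
#' (1 - pi0) f1(s) prod(f1,feat))`, the posterior probability that the match
#' is incorrect given its score (the local false discovery rate). Discrete
#' factors are included only for features present in both the model and
#' `levels`.
#'
#' @param model A [mixture_model()].
#' @param scores Numeric vector of discriminant scores.
#' @param levels Optional data frame (or named list) with one column per
#'   modeled discrete feature giving each record's level; `NA` or unseen
#'   levels contribute a factor of 1.
#' @return Numeric vector of PEPs in `[0, 1]`.
#' @export
e_step <- function(model, scores, levels = NULL) {
  tm <- mixture_terms(model, scores, levels)
  both_zero <- tm$t0 == 0 & tm$t1 == 0
  if (any(both_zero))
    stop("degenerate density: both mixture terms are 0 at score ",
         signif(scores[which(both_zero)[1]], 6), call. = FALSE)
  pep <- tm$t0 / (tm$t0 + tm$t1)
  # an infinite density (e.g. Gamma with shape < 1 evaluated at the shift)
  # dominates the finite term
  pep[is.infinite(tm$t0) & is.finite(tm$t1)] <- 1
  pep[is.infinite(tm$t1) & is.finite(tm$t0)] <- 0
  pep[is.infinite(tm$t0) & is.infinite(tm$t1)] <- model$pi0
  pep
}

# In-loop variant: falls back to pi0 where both terms vanish instead of
# erroring, so a transient parameter estimate cannot abort the fit.
e_step_safe <- function(model, scores, levels = NULL) {
  tm <- mixture_terms(model, scores, levels)
  pep <- tm$t0 / (tm$t0 + tm$t1)
  pep[is.infinite(tm$t0) & is.finite(tm$t1)] <- 1
  pep[is.infinite(tm$t1) & is.finite(tm$t0)] <- 0
  pep[!is.finite(pep)] <- model$pi0
  pep
}

#' M-step estimators
#'
#' The maximization-step updates of the EM algorithm, given current
#' membership probabilities `pep` (`p_i = P(T_i = 0 | s_i)`):
#'
#' * `m_step_pi0()`: `sum(p_i) / N`.
#' * `m_step_normal()`: weighted MLE for the correct component,
#'   `mu = sum((1-p_i) s_i) / sum(1-p_i)` and
#'   `sigma = sqrt(sum((1-p_i)(s_i - mu)^2) / sum(1-p_i))` (the biased form
#'   with the same denominator as the mean).
#' * `m_step_gamma()`: the shift `gamma` is the minimum of all scores; with
#'   `m1 = sum(p_i (s_i - shift)) / sum(p_i)` and
#'   `m2 = sum(p_i (s_i - shift - m1)^2) / sum(p_i)`, the method-of-moments
#'   estimates are `alpha = m1^2 / m2` (shape) and `beta = m1 / m2` (rate),
#'   so the component mean is `shift + alpha / beta`.
#' * `m_step_gumbel()`: weighted moment matching,
#'   `scale = sqrt(6 * var_w) / pi` and
#'   `location = mean_w - 0.57722 * scale` (Euler-Mascheroni constant).
#' * `m_step_discrete()`: weighted multinomial frequencies,
#'   `p_incorrect(l) = sum(p_i [level_i = l]) / sum(p_i)` and `p_correct`
#'   analogously with weights `1 - p_i`.
#'
#' @param pep Numeric vector of membership probabilities in `[0, 1]`.
#' @param scores Numeric score vector, same length as `pep`.
#' @param levels Vector of discrete level values, same length as `pep`.
#' @param feature Feature name stored in the returned table.
#' @param level_set Optional full ordered level set (defaults to the sorted
#'   unique observed levels).
#' @return `m_step_pi0`: a probability. `m_step_normal`: named vector
#'   `(mu, sigma)`. `m_step_gamma`: named vector `(alpha, beta, shift)`.
#'   `m_step_gumbel`: named vector `(location, scale)`. `m_step_discrete`:
#'   a [discrete_feature_table()].
#' @name m-step
NULL

#' @rdname m-step
#' @export
m_step_pi0 <- function(pep) {
  if (length(pep) == 0) stop("empty membership vector", call. = FALSE)
  mean(pep)
}

#' @rdname m-step
#' @export
m_step_normal <- function(scores, pep) {
  w <- 1 - pep
  W <- sum(w)
  if (W <= 0) stop("all positive-component weights are 0", call. = FALSE)
  mu <- sum(w * scores) / W
  sigma <- sqrt(sum(w * (scores - mu)^2) / W)
  if (sigma <= 0)
    stop("degenerate positive component: zero variance", call. = FALSE)
  c(mu = mu, sigma = sigma)
}

#' @rdname m-step
#' @export
m_step_gamma <- function(scores, pep) {
  W <- sum(pep)
  if (W <= 0) stop("all negative-component weights are 0", call. = FALSE)
  shift <- min(scores)
  m1 <- sum(pep * (scores - shift)) / W
  m2 <- sum(pep * (scores - shift - m1)^2) / W
  if (m2 <= 0)
    stop("degenerate negative component: zero second moment", call. = FALSE)
  c(alpha = m1^2 / m2, beta = m1 / m2, shift = shift)
}

#' @rdname m-step
#' @export
m_step_gumbel <- function(scores, pep) {
  W <- sum(pep)
  if (W <= 0) stop("all negative-component weights are 0", call. = FALSE)
  mw <- sum(pep * scores) / W
  vw <- sum(pep * (scores - mw)^2) / W
  if (vw <= 0)
    stop("degenerate negative component: zero variance", call. = FALSE)
  scale <- sqrt(6 * vw) / pi
  c(location = mw - 0.5772156649015329 * scale, scale = scale)
}

# Weighted level probabilities over a fixed level set.
weighted_level_probs <- function(levels, w, level_set) {
  W <- sum(w)
  p <- vapply(level_set, function(l) sum(w[levels == l]), numeric(1)) / W
  unname(p)
}

#' @rdname m-step
#' @export
m_step_discrete <- function(levels, pep, feature = "feature", level_set = NULL) {
  if (sum(pep) <= 0 || sum(1 - pep) <= 0)
    stop("a component has zero total weight for the discrete update",
         call. = FALSE)
  if (is.null(level_set)) level_set <- sort(unique(levels))
  discrete_feature_table(
    feature, level_set,
    p_incorrect = weighted_level_probs(levels, pep, level_set),
    p_correct = weighted_level_probs(levels, 1 - pep, level_set)
  )
}
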