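#' Fit the two-component mixture by expectation-maximization
#'
#' Fits, independently for each precursor charge, a two-component mixture to
#' the discriminant scores of a PSM table: a Normal component for correct
#' matches and a shifted-Gamma (default) or Gumbel component for incorrect
#' ones, with the mixing weight `pi0` giving the overall proportion of
#' incorrect identifications. The EM algorithm alternates the E-step
#' ([e_step()], Bayes posterior of being incorrect) with the M-step
#' estimators ([m_step_pi0()], [m_step_normal()], [m_step_gamma()] /
#' [m_step_gumbel()], [m_step_discrete()]) until no parameter changes by more
#' than `epsilon` or `max_iter` is reached.
#'
#' With `use_decoys = TRUE` the fit is semisupervised: decoy records are
#' pinned to the incorrect component (their membership probability is exactly
#' 1 at every iteration), contribute only to the negative-component and
#' incorrect-side discrete updates, and are excluded from the `pi0` and
#' Normal updates. The Gamma shift is the minimum score over all records
#' including decoys. With `use_decoys = FALSE` decoy rows are dropped before
#' fitting (the basic model is decoy-blind); their PEPs are still evaluated
#' under the final model.
#'
#' Optional discrete features (`"ntt"`, `"nmc"`, `"delta_mass"`) are modeled
#' as per-component categorical distributions; `delta_mass` is first
#' discretized into `dm_bin_width`-Da bins centered on integers.
#'
#' @param table A PSM table with `discriminant_score` populated.
#' @param use_decoys Logical; fit the semisupervised variant.
#' @param negative Negative-component family, `"gamma"` (shifted Gamma) or
#'   `"gumbel"`.
#' @param discrete Character vector of discrete features to model, a subset
#'   of `c("ntt", "nmc", "delta_mass")`; `NULL` for none.
#' @param epsilon Convergence tolerance on the maximum absolute parameter
#'   change (default 1e-4).
#' @param max_iter Maximum EM iterations per charge.
#' @param min_records Minimum number of target records per charge; sparser
#'   charges are skipped with a warning.
#' @param dm_bin_width Width (Da) of the mass-difference bins.
#' @return A `psmix_fit` object: per-charge `models`, a `pep` vector aligned
#'   to the input rows (`NA` for skipped charges), per-charge iteration
#'   counts, convergence flags, log-likelihood trace, and the options used.
#' @examples
#' tab <- simulate_psms(list(sim_charge(2, pi0 = 0.6, n_targets = 500)), seed = 1)
#' fit <- fit_em(tab, min_records = 100)
#' tidy(fit)
#' @export
fit_em <- function(table, use_decoys = FALSE,
                   negative = c("gamma", "gumbel"),
                   discrete = NULL, epsilon = 1e-4, max_iter = 1000,
                   min_records = 100, dm_bin_width = 1) {
  negative <- match.arg(negative)
  table <- validate_psm_table(table)
  if (!"discriminant_score" %in% names(table) ||
      anyNA(table$discriminant_score))
    stop("`discriminant_score` must be present for every record; ",
         "run apply_discriminant() first", call. = FALSE)
  if (!is.null(discrete)) {
    bad <- setdiff(discrete, c("ntt", "nmc", "delta_mass"))
    if (length(bad) > 0)
      stop("unknown discrete feature(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!"is_decoy" %in% names(table)) table$is_decoy <- FALSE

  levels_df <- discrete_levels_frame(table, discrete, dm_bin_width)

  charges <- sort(unique(table$charge))
  models <- list(); n_iter <- integer(0); converged <- logical(0)
  loglik <- numeric(0); skipped <- integer(0)
  n_records <- integer(0)
  pep_out <- rep(NA_real_, nrow(table))
  trace_list <- list()

  for (ch in charges) {
    idx <- which(table$charge == ch)
    decoy <- table$is_decoy[idx]
    n_targets <- sum(!decoy)
    if (n_targets < min_records) {
      warning("charge ", ch, ": only ", n_targets, " target records (< ",
              min_records, "); charge skipped", call. = FALSE)
      skipped <- c(skipped, ch)
      next
    }
    fit_idx <- if (use_decoys) idx else idx[!decoy]
    res <- fit_em_one_charge(
      scores = table$discriminant_score[fit_idx],
      decoy = if (use_decoys) decoy else rep(FALSE, length(fit_idx)),
      levels = if (is.null(levels_df)) NULL else levels_df[fit_idx, , drop = FALSE],
      charge = ch, negative = negative, epsilon = epsilon,
      max_iter = max_iter
    )
    models[[as.character(ch)]] <- res$model
    n_iter[as.character(ch)] <- res$n_iter
    converged[as.character(ch)] <- res$converged
    loglik[as.character(ch)] <- res$loglik
    n_records[as.character(ch)] <- length(fit_idx)
    trace_list[[as.character(ch)]] <- res$trace
    # PEPs for every record of this charge under the final model
    pep_out[idx] <- e_step(
      res$model, table$discriminant_score[idx],
      if (is.null(levels_df)) NULL else levels_df[idx, , drop = FALSE]
    )
    if (use_decoys) pep_out[idx[decoy]] <- 1
  }
  if (length(models) == 0)
    stop("no charge had at least `min_records` target records", call. = FALSE)

  structure(
    list(models = models, pep = pep_out,
         n_iterations = n_iter, converged = converged,
         loglik = loglik, n_records = n_records, skipped = skipped,
         trace = dplyr::bind_rows(trace_list),
         options = list(method = if (use_decoys) "semisupervised" else "parametric",
                        use_decoys = use_decoys, negative = negative,
                        discrete = discrete, epsilon = epsilon,
                        max_iter = max_iter, min_records = min_records,
                        dm_bin_width = dm_bin_width)),
    class = "psmix_fit"
  )
}

# Assemble the per-record discrete level columns used by the E/M-steps.
discrete_levels_frame <- function(table, discrete, dm_bin_width) {
  if (is.null(discrete) || length(discrete) == 0) return(NULL)
  out <- list()
  if ("ntt" %in% discrete) {
    if (!"ntt" %in% names(table))
      stop("discrete feature `ntt` requested but column is absent", call. = FALSE)
    out$ntt <- table$ntt
  }
  if ("nmc" %in% discrete) {
    if (!"nmc" %in% names(table))
      stop("discrete feature `nmc` requested but column is absent", call. = FALSE)
    out$nmc <- table$nmc
  }
  if ("delta_mass" %in% discrete) {
    if (!"delta_mass" %in% names(table))
      stop("discrete feature `delta_mass` requested but column is absent",
           call. = FALSE)
    out$delta_mass_bin <- bin_delta_mass(table$delta_mass, dm_bin_width)
  }
  tibble::as_tibble(out)
}

#' Discretize mass differences into bins
#'
#' Maps each precursor mass difference to the center of its bin
#' (`dm_bin_width`-Da-wide bins centered on multiples of the width), turning
#' the continuous mass error into a discrete mixture feature.
#'
#' @param delta_mass Numeric vector of mass differences (Da).
#' @param width Bin width in Da (default 1).
#' @return Numeric vector of bin centers.
#' @export
bin_delta_mass <- function(delta_mass, width = 1) {
  round(delta_mass / width) * width
}

fit_em_one_charge <- function(scores, decoy, levels, charge, negative,
                              epsilon, max_iter) {
  n <- length(scores)
  target <- !decoy
  if (stats::sd(scores) == 0)
    stop("degenerate component: all scores identical for charge ", charge,
         call. = FALSE)

  # --- initialization: incorrect matches dominate typical searches ---
  pi0 <- 0.9
  top <- scores[target][scores[target] >= stats::quantile(scores[target], 0.9)]
  mu <- mean(top)
  sigma <- max(stats::sd(top), 0.05 * stats::sd(scores), 1e-3)
  positive <- dist_normal(mu, sigma)
  bottom <- scores[scores <= stats::median(scores)]
  neg <- init_negative(bottom, min(scores), negative)

  level_sets <- NULL
  dtabs <- list()
  if (!is.null(levels)) {
    level_sets <- lapply(levels, function(v) sort(unique(v[!is.na(v)])))
    # neutral start: both components share the marginal frequencies
    dtabs <- purrr::imap(levels, function(v, nm) {
      ok <- !is.na(v)
      p <- weighted_level_probs(v[ok], rep(1, sum(ok)), level_sets[[nm]])
      discrete_feature_table(nm, level_sets[[nm]], p, p)
    })
  }

  model <- mixture_model(charge, pi0, neg, positive, dtabs)
  params <- model_params(model)
  trace <- list()
  converged <- FALSE
  iter <- 0
  ll <- NA_real_

  while (iter < max_iter) {
    iter <- iter + 1
    pep <- e_step_safe(model, scores, levels)
    pep[decoy] <- 1
    pep <- pmin(pmax(pep, 1e-12), 1 - 1e-12)
    pep[decoy] <- 1

    pi0_new <- m_step_pi0(pep[target])
    norm_par <- m_step_normal(scores[target], pep[target])
    neg_par <- if (negative == "gamma") m_step_gamma(scores, pep)
               else m_step_gumbel(scores, pep)
    neg_new <- if (negative == "gamma")
      dist_shifted_gamma(neg_par[["alpha"]], neg_par[["beta"]], neg_par[["shift"]])
    else dist_gumbel(neg_par[["location"]], neg_par[["scale"]])

    dtabs_new <- dtabs
    if (!is.null(levels)) {
      dtabs_new <- purrr::imap(levels, function(v, nm) {
        ok <- !is.na(v)
        # incorrect side: all records (decoys pinned at 1 contribute here);
        # correct side: targets only
        discrete_feature_table(
          nm, level_sets[[nm]],
          p_incorrect = weighted_level_probs(v[ok], pep[ok], level_sets[[nm]]),
          p_correct = weighted_level_probs(v[ok & target],
                                           1 - pep[ok & target],
                                           level_sets[[nm]])
        )
      })
    }

    model <- mixture_model(charge, pi0_new, neg_new,
                           dist_normal(norm_par[["mu"]], norm_par[["sigma"]]),
                           dtabs_new)
    dtabs <- dtabs_new
    params_new <- model_params(model)
    delta <- max(abs(params_new - params))
    params <- params_new
    ll <- sum(log(mixture_density(
      model, scores[target],
      if (is.null(levels)) NULL else levels[target, , drop = FALSE])))
    trace[[iter]] <- c(iteration = iter, params_new, loglik = ll, delta = delta)
    if (delta < epsilon) { converged <- TRUE; break }
  }

  trace_tb <- tibble::as_tibble(do.call(rbind, trace))
  trace_tb <- tidyr::pivot_longer(trace_tb, -"iteration",
                                  names_to = "term", values_to = "value")
  trace_tb$charge <- charge
  trace_tb <- trace_tb[, c("charge", "iteration", "term", "value")]

  list(model = model, n_iter = iter, converged = converged, loglik = ll,
       trace = trace_tb)
}

init_negative <- function(bottom, global_min, negative) {
  m1 <- mean(bottom - global_min)
  m2 <- stats::var(bottom) * (length(bottom) - 1) / length(bottom)
  if (negative == "gamma") {
    if (m1 <= 0 || m2 <= 0)
      stop("degenerate component: cannot initialize the Gamma", call. = FALSE)
    dist_shifted_gamma(m1^2 / m2, m1 / m2, global_min)
  } else {
    if (m2 <= 0)
      stop("degenerate component: cannot initialize the Gumbel", call. = FALSE)
    scale <- sqrt(6 * m2) / pi
    dist_gumbel(mean(bottom) - 0.5772156649015329 * scale, scale)
  }
}

#' @export
print.psmix_fit <- function(x, ...) {
  cat("<psmix ", x$options$method, " fit: ", length(x$models), " charge(s), ",
      "negative = ", x$options$negative, ">\n", sep = "")
  for (ch in names(x$models)) {
    cat(sprintf("  charge %s: pi0 = %.4f, %d records, %d iterations%s\n",
                ch, x$models[[ch]]$pi0, x$n_records[[ch]],
                x$n_iterations[[ch]],
                if (x$converged[[ch]]) "" else " (NOT converged)"))
  }
  if (length(x$skipped) > 0)
    cat("  skipped charges:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
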