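#' Train a two-class Fisher linear discriminant
#'
#' Computes the Fisher direction `w = Sp^{-1} (mean_pos - mean_neg)` with
#' `Sp` the pooled within-class covariance, sets the intercept so the score
#' is 0 at the midpoint of the projected class means, and rescales to unit
#' weight norm (the direction, not the scale, carries the information).
#' A small ridge is added to `Sp` if it is numerically singular.
#'
#' @param positives,negatives Numeric matrices (or data frames) of features,
#'   one row per record, same columns; each class needs >= 2 rows.
#' @param ridge Ridge added to the covariance diagonal when solving fails
#'   (relative to the mean diagonal entry).
#' @return A [discriminant_coefficients()] object (engine `"custom"`).
#' @export
train_linear_discriminant <- function(positives, negatives, ridge = 1e-8) {
  positives <- as.matrix(positives); negatives <- as.matrix(negatives)
  if (nrow(positives) < 2 || nrow(negatives) < 2)
    stop("each class needs at least 2 rows", call. = FALSE)
  if (is.null(colnames(positives)))
    colnames(positives) <- colnames(negatives) <- paste0("F", seq_len(ncol(positives)))
  mu_p <- colMeans(positives); mu_n <- colMeans(negatives)
  n_p <- nrow(positives); n_n <- nrow(negatives)
  Sp <- ((n_p - 1) * stats::cov(positives) + (n_n - 1) * stats::cov(negatives)) /
    (n_p + n_n - 2)
  w <- tryCatch(solve(Sp, mu_p - mu_n), error = function(e) {
    Sr <- Sp + diag(ridge * mean(diag(Sp)) + 1e-12, ncol(Sp))
    tryCatch(solve(Sr, mu_p - mu_n), error = function(e2)
      stop("pooled covariance is singular even after ridge regularization",
           call. = FALSE))
  })
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  intercept <- -sum(w * (mu_p + mu_n) / 2)
  discriminant_coefficients(intercept, stats::setNames(as.numeric(w),
                                                       colnames(positives)))
}

#' Options for the adaptive discriminant fit
#'
#' @param pep_low PEP at or below which a target joins the positive training
#'   set (default 0.05).
#' @param pep_high PEP at or above which a record joins the negative training
#'   set (default 0.9). Must exceed `pep_low`.
#' @param n_resample Number `I` of positive-set subsamples whose trained
#'   discriminants are averaged each round (default 10).
#' @param subsample_fraction Fraction of the positive set drawn per
#'   subsample (default 0.7).
#' @param epsilon Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-4).
#' @param max_rounds Maximum outer rounds (default 20).
#' @param top_k Number of ranked candidate matches per spectrum to rescore
#'   (default 5).
#' @param min_positives Floor on the positive training set: when fewer
#'   targets clear `pep_low` (typical in early rounds under a weak initial
#'   discriminant), the `min_positives` lowest-PEP above-median targets are
#'   used instead (default 25).
#' @return A list of class `psmix_adaptive_options`.
#' @export
adaptive_options <- function(pep_low = 0.05, pep_high = 0.9, n_resample = 10,
                             subsample_fraction = 0.7, epsilon = 1e-4,
                             max_rounds = 20, top_k = 5, min_positives = 25) {
  if (!(pep_low < pep_high))
    stop("`pep_low` must be smaller than `pep_high`", call. = FALSE)
  structure(list(pep_low = pep_low, pep_high = pep_high,
                 n_resample = n_resample,
                 subsample_fraction = subsample_fraction,
                 epsilon = epsilon, max_rounds = max_rounds, top_k = top_k,
                 min_positives = min_positives),
            class = "psmix_adaptive_options")
}

#' Adaptive re-estimation of discriminant coefficients
#'
#' Constrained searches often leave fixed, externally trained discriminant
#' coefficients suboptimal, blurring the separation between correct and
#' incorrect matches. This fit adapts the coefficients to the experiment:
#' each round it (1) scores the current best candidate per spectrum with the
#' current coefficients, (2) fits the score mixture with [fit_em()],
#' (3) takes records with PEP `<= pep_low` as positives and PEP `>= pep_high`
#' as negatives, (4) draws `n_resample` subsamples of the positive set,
#' trains a Fisher discriminant for each against the full negative set and
#' averages the coefficient vectors, then (5) rescores the `top_k` ranked
#' candidates of every spectrum with the averaged coefficients and promotes
#' the highest-scoring candidate (ties go to the lowest original rank). It
#' stops when the coefficient vector revisits a state from the last few
#' rounds within `epsilon` — usually the previous round (a plain fixed
#' point), but also a short limit cycle induced by a boundary record
#' flipping between the training sets — or after `max_rounds`.
#'
#' @param candidates A PSM table that may contain several ranked candidates
#'   per spectrum (`rank` column, best = 1) with raw feature columns.
#' @param init_coeffs Initial [discriminant_coefficients()]; its weight names
#'   define the features used.
#' @param options An [adaptive_options()] list.
#' @param seed Integer seed driving the subsampling (one RNG stream for the
#'   whole fit, so results are reproducible).
#' @param ... Passed to [fit_em()] (e.g. `use_decoys`, `min_records`).
#' @return A list with elements `coefficients` (the final averaged
#'   [discriminant_coefficients()]), `fit` (the final `psmix_fit` on the
#'   promoted best candidates), `best` (the final best-candidate table with
#'   scores), `n_rounds`, `converged`, and `trace` (per-round coefficient
#'   vectors as a tibble).
#' @export
fit_adaptive <- function(candidates, init_coeffs, options = adaptive_options(),
                         seed = 1, ...) {
  stopifnot(inherits(init_coeffs, "psmix_coefficients"),
            inherits(options, "psmix_adaptive_options"))
  candidates <- validate_psm_table(candidates)
  if (!"rank" %in% names(candidates)) candidates$rank <- 1L
  candidates <- candidates[candidates$rank <= options$top_k, , drop = FALSE]
  feats <- names(init_coeffs$weights)
  missing_feat <- setdiff(feats, names(candidates))
  if (length(missing_feat) > 0)
    stop("candidate table is missing feature `", missing_feat[1], "`",
         call. = FALSE)

  coeffs <- init_coeffs
  best_idx <- best_by_rank(candidates)
  trace <- list()
  coeff_history <- list()
  converged <- FALSE
  n_rounds <- 0
  fit <- NULL

  repeat {
    n_rounds <- n_rounds + 1
    best <- apply_discriminant(candidates[best_idx, , drop = FALSE], coeffs)
    fit <- fit_em(best, ...)
    pep <- fit$pep
    # A shifted-Gamma negative component has density 0 at its left support
    # edge, so the very lowest scores get a spuriously tiny PEP; requiring
    # positives to also score above the target median keeps that artifact
    # out of the positive training set without altering reported posteriors.
    is_target <- !best$is_decoy
    med <- stats::median(best$discriminant_score[is_target])
    pos_rows <- which(is_target & !is.na(pep) & pep <= options$pep_low &
                        best$discriminant_score >= med)
    # Early rounds under a weak discriminant can leave the mixture so
    # overlapped that no target clears pep_low; bootstrap the loop from the
    # lowest-PEP above-median targets until thresholding takes over.
    if (length(pos_rows) < options$min_positives) {
      eligible <- which(is_target & !is.na(pep) &
                          best$discriminant_score >= med)
      pos_rows <- eligible[order(pep[eligible])][
        seq_len(min(options$min_positives, length(eligible)))]
    }
    neg_rows <- which(!is.na(pep) & pep >= options$pep_high)
    if (length(pos_rows) < 2 || length(neg_rows) < 2)
      stop("adaptive round ", n_rounds, ": positive (", length(pos_rows),
           ") or negative (", length(neg_rows), ") training set too small; ",
           "relax pep_low/pep_high", call. = FALSE)

    # The subsample pattern is re-seeded identically every round, so each
    # round is a deterministic function of the current assignment state and
    # the loop is a fixed-point iteration: once the training sets stop
    # changing, the averaged coefficients repeat exactly and the epsilon
    # stopping rule can fire. The resampling acts as a bagging stabilizer,
    # not a stochastic search.
    set.seed(seed)
    neg_mat <- as.matrix(best[neg_rows, feats])
    coef_mat <- vapply(seq_len(options$n_resample), function(i) {
      take <- sample(pos_rows,
                     size = max(2, round(options$subsample_fraction *
                                           length(pos_rows))))
      coeff_vector(train_linear_discriminant(as.matrix(best[take, feats]),
                                             neg_mat))
    }, numeric(length(feats) + 1))
    avg <- rowMeans(coef_mat)
    new_coeffs <- discriminant_coefficients(avg[["intercept"]],
                                            avg[setdiff(names(avg), "intercept")])
    delta <- max(abs(coeff_vector(new_coeffs) - coeff_vector(coeffs)))
    # With discrete training-set membership the round map can settle on a
    # short limit cycle around its fixed point (a boundary record flipping
    # in and out). Stop when the coefficient vector revisits any state from
    # the last few rounds within epsilon: the iteration has reached its
    # invariant set and further rounds only retrace it.
    delta_cycle <- delta
    for (j in seq_len(min(4, n_rounds - 1))) {
      delta_cycle <- min(delta_cycle,
                         max(abs(coeff_vector(new_coeffs) -
                                   coeff_history[[n_rounds - j]])))
    }
    coeff_history[[n_rounds]] <- coeff_vector(new_coeffs)
    trace[[n_rounds]] <- c(round = n_rounds, coeff_vector(new_coeffs),
                           delta = delta, delta_cycle = delta_cycle,
                           n_pos = length(pos_rows), n_neg = length(neg_rows))
    coeffs <- new_coeffs

    # rescore every retained candidate and promote the best per spectrum
    rescored <- apply_discriminant(candidates, coeffs)
    best_idx <- promote_best(rescored)

    if (delta_cycle < options$epsilon) { converged <- TRUE; break }
    if (n_rounds >= options$max_rounds) {
      warning("adaptive fit did not converge in ", options$max_rounds,
              " rounds (last max |delta beta| = ", signif(delta, 3), ")",
              call. = FALSE)
      break
    }
  }

  best <- apply_discriminant(candidates[best_idx, , drop = FALSE], coeffs)
  fit <- fit_em(best, ...)
  list(coefficients = coeffs, fit = fit, best = best,
       n_rounds = n_rounds, converged = converged,
       trace = tibble::as_tibble(do.call(rbind, trace)))
}

# Row indices of the rank-1 candidate per spectrum.
best_by_rank <- function(candidates) {
  ord <- order(candidates$spectrum_id, candidates$rank)
  ord[!duplicated(candidates$spectrum_id[ord])]
}

# Row indices of the highest-scoring candidate per spectrum; ties break to
# the lowest original rank.
promote_best <- function(scored) {
  ord <- order(scored$spectrum_id, -scored$discriminant_score, scored$rank)
  ord[!duplicated(scored$spectrum_id[ord])]
}
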