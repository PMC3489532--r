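#' Semiparametric mixture fit with decoy-anchored kernel densities
#'
#' Replaces the parametric score components with kernel density estimates
#' when the Gamma/Normal forms visibly misfit (e.g. skewed correct-score
#' distributions from constrained searches). The negative (incorrect)
#' component is a KDE over the decoy scores with unit weights, built once
#' and held fixed; the positive (correct) component is a KDE over the
#' high-confidence target scores. The algorithm iterates:
#'
#' 1. rebuild the positive KDE from targets whose current PEP is at most
#'    `pep_threshold`,
#' 2. recompute PEPs by the Bayes ratio with the kernel components,
#' 3. update `pi0` as the mean target PEP ([m_step_pi0()]),
#'
#' until the maximum PEP change falls below `epsilon`. Decoy PEPs are pinned
#' at 1 and decoys are excluded from `pi0`.
#'
#' The positive component deliberately hard-assigns its training scores
#' rather than weighting every target by `1 - PEP`: with a free-form kernel
#' component, soft weights let the positive density absorb incorrect-match
#' mass in the overlap region, and the mixing weight drifts away in a
#' self-reinforcing loop (smaller bandwidths make the collapse worse).
#' Thresholding breaks that feedback while the fixed decoy KDE anchors the
#' negative side; see the methods vignette for the measured comparison.
#'
#' Because kernel components can overfit small samples, the fit refuses to
#' run with fewer than 500 target records unless `force = TRUE`; the
#' semiparametric variant is intended for strong, visible deviations from
#' the parametric fit, not as a default.
#'
#' Inside the loop, densities are tabulated on a `grid_size`-point grid and
#' linearly interpolated at the observed scores (the resolution
#' `stats::density()` uses by default); the returned models carry the exact
#' KDE objects.
#'
#' @param table A PSM table with `discriminant_score` and decoy records.
#' @param bandwidth Bandwidth selection method, `"silverman"` or `"cv"`,
#'   passed to [select_bandwidth()].
#' @param pep_threshold Targets with PEP at or below this value train the
#'   positive KDE (default 0.5).
#' @param min_decoys Minimum decoy records per charge (default 50); below
#'   this the error suggests the parametric fallback.
#' @param min_records Minimum target records per charge.
#' @param force Logical; allow fewer than 500 targets.
#' @param epsilon Convergence tolerance on the maximum PEP change.
#' @param max_iter Maximum iterations.
#' @param grid_size Number of grid points used to tabulate the densities.
#' @return A `psmix_fit` with kernel components in each charge's model.
#' @export
fit_semiparametric <- function(table, bandwidth = c("silverman", "cv"),
                               pep_threshold = 0.5,
                               min_decoys = 50, min_records = 100,
                               force = FALSE, epsilon = 1e-4, max_iter = 100,
                               grid_size = 512) {
  bandwidth <- match.arg(bandwidth)
  table <- validate_psm_table(table)
  if (!"discriminant_score" %in% names(table) ||
      anyNA(table$discriminant_score))
    stop("`discriminant_score` must be present for every record", call. = FALSE)
  if (!"is_decoy" %in% names(table) || !any(table$is_decoy))
    stop("the semiparametric fit needs decoy records; none found",
         call. = FALSE)
  if (!any(!table$is_decoy))
    stop("the table has no target records", call. = FALSE)

  charges <- sort(unique(table$charge))
  models <- list(); n_iter <- integer(0); converged <- logical(0)
  loglik <- numeric(0); n_records <- integer(0); skipped <- integer(0)
  pep_out <- rep(NA_real_, nrow(table))
  trace_list <- list()

  for (ch in charges) {
    idx <- which(table$charge == ch)
    s <- table$discriminant_score[idx]
    decoy <- table$is_decoy[idx]
    n_targets <- sum(!decoy)
    n_decoys <- sum(decoy)
    if (n_targets < min_records) {
      warning("charge ", ch, ": only ", n_targets, " target records (< ",
              min_records, "); charge skipped", call. = FALSE)
      skipped <- c(skipped, ch); next
    }
    if (n_decoys < min_decoys)
      stop("charge ", ch, ": only ", n_decoys, " decoys (< ", min_decoys,
           "); use the parametric fit_em(use_decoys = TRUE) instead",
           call. = FALSE)
    if (n_targets < 500 && !force)
      stop("charge ", ch, ": ", n_targets, " targets < 500; the ",
           "semiparametric fit overfits small samples - set force = TRUE ",
           "only if the parametric fit deviates strongly", call. = FALSE)

    st <- s[!decoy]
    neg_kde <- kde_estimate(s[decoy],
                            bandwidth = select_bandwidth(s[decoy], 1, bandwidth))
    grid <- seq(min(s) - 4 * neg_kde$bandwidth,
                max(s) + 4 * neg_kde$bandwidth, length.out = grid_size)
    f0_grid <- kde_density(neg_kde, grid)
    f0_t <- stats::approx(grid, f0_grid, xout = st, rule = 2)$y
    # kernel-to-grid distances, computed once per charge
    D <- outer(grid, st, "-")

    pi0 <- 0.9
    pep_t <- rep(pi0, n_targets)   # neutral start; the fixed decoy KDE drives
    iter <- 0; conv <- FALSE       # separation from the first iteration on
    trace <- list()
    pos_kde <- NULL
    repeat {
      iter <- iter + 1
      w_pos <- as.numeric(pep_t <= pep_threshold)
      if (sum(w_pos) < 2) w_pos <- pmax(1 - pep_t, 1e-12)
      h1 <- select_bandwidth(st, w_pos, bandwidth)
      pos_kde <- kde_estimate(st, w_pos, bandwidth = h1)
      f1_grid <- as.numeric(stats::dnorm(D / h1) %*% w_pos) / (sum(w_pos) * h1)
      f1_t <- stats::approx(grid, f1_grid, xout = st, rule = 2)$y
      num0 <- pi0 * f0_t
      den <- num0 + (1 - pi0) * f1_t
      pep_new <- ifelse(den > 0, num0 / den, pi0)
      delta <- max(abs(pep_new - pep_t))
      pep_t <- pep_new
      pi0 <- m_step_pi0(pep_t)
      trace[[iter]] <- c(iteration = iter, pi0 = pi0, bandwidth = h1,
                         delta = delta)
      if (delta < epsilon) { conv <- TRUE; break }
      if (iter >= max_iter) break
    }

    model <- mixture_model(ch, pi0, dist_kernel(neg_kde), dist_kernel(pos_kde))
    models[[as.character(ch)]] <- model
    n_iter[as.character(ch)] <- iter
    converged[as.character(ch)] <- conv
    n_records[as.character(ch)] <- length(idx)
    pep_out[idx[!decoy]] <- pep_t
    pep_out[idx[decoy]] <- 1
    f1_t_final <- stats::approx(
      grid, as.numeric(stats::dnorm(D / pos_kde$bandwidth) %*% pos_kde$weights) /
        (sum(pos_kde$weights) * pos_kde$bandwidth),
      xout = st, rule = 2)$y
    loglik[as.character(ch)] <-
      sum(log(pmax(pi0 * f0_t + (1 - pi0) * f1_t_final, 1e-300)))
    tr <- tibble::as_tibble(do.call(rbind, trace))
    tr <- tidyr::pivot_longer(tr, -"iteration", names_to = "term",
                              values_to = "value")
    tr$charge <- ch
    trace_list[[as.character(ch)]] <- tr[, c("charge", "iteration", "term", "value")]
  }
  if (length(models) == 0)
    stop("no charge had at least `min_records` target records", call. = FALSE)

  structure(
    list(models = models, pep = pep_out, n_iterations = n_iter,
         converged = converged, loglik = loglik, n_records = n_records,
         skipped = skipped, trace = dplyr::bind_rows(trace_list),
         options = list(method = "semiparametric", bandwidth = bandwidth,
                        pep_threshold = pep_threshold,
                        min_decoys = min_decoys, min_records = min_records,
                        epsilon = epsilon, max_iter = max_iter)),
    class = "psmix_fit"
  )
}
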