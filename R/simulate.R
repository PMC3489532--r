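#' Configure one charge block of a synthetic PSM simulation
#'
#' Describes the generative structure the mixture model assumes, for one
#' precursor charge: each target record is incorrect with probability `pi0`
#' (score drawn from the negative component, discrete levels from the
#' incorrect-side tables) and correct otherwise (positive component,
#' correct-side tables); decoy records are drawn from the negative component
#' with `is_decoy = TRUE`. Every record carries its ground-truth label, so
#' estimated error rates can be compared with [true_fdr()].
#'
#' The defaults encode the reference simulation used throughout the
#' package's tests: `pi0 = 0.7`, negative = shift −3 + Gamma(shape 4,
#' rate 2), positive = Normal(3, 1), 10,000 targets.
#'
#' In `raw` feature mode the block additionally emits class-conditional
#' multivariate-Normal engine features (equal covariance across classes, so
#' the Bayes-optimal score combiner is linear and recoverable by
#' [fit_adaptive()]), optionally with `n_candidates` ranked candidates per
#' spectrum: candidate ranks are assigned by a crude engine ordering
#' (descending first feature), and every candidate beyond the first is
#' incorrect.
#'
#' @param charge Integer charge label.
#' @param pi0 Proportion of incorrect target identifications.
#' @param negative,positive Parametric [components] for incorrect and
#'   correct scores.
#' @param n_targets,n_decoys Record counts (decoy count is configured
#'   independently of the target count; decoy competition within a
#'   concatenated search is not modeled mechanistically).
#' @param discrete Named list of [discrete_feature_table()] objects; names
#'   `"ntt"` and `"nmc"` fill those columns, `"delta_mass_bin"` fills
#'   `delta_mass` with the level plus sub-bin jitter.
#' @param raw Optional list enabling raw feature mode:
#'   `list(mu_neg =, mu_pos =, sigma =, features =, n_candidates = 1)` with
#'   mean vectors per class, a shared covariance matrix (or scalar for
#'   spherical), feature names, and candidates per spectrum.
#' @return A `psmix_sim_charge` list.
#' @export
sim_charge <- function(charge = 2, pi0 = 0.7,
                       negative = dist_shifted_gamma(4, 2, -3),
                       positive = dist_normal(3, 1),
                       n_targets = 10000, n_decoys = 0,
                       discrete = list(), raw = NULL) {
  stopifnot(pi0 >= 0, pi0 <= 1, n_targets >= 0, n_decoys >= 0)
  stopifnot(inherits(negative, "psmix_dist"), inherits(positive, "psmix_dist"))
  if (!is.null(raw)) {
    k <- length(raw$mu_neg)
    stopifnot(length(raw$mu_pos) == k, k >= 1)
    if (is.null(raw$features)) raw$features <- paste0("F", seq_len(k))
    if (is.null(raw$sigma)) raw$sigma <- diag(k)
    if (is.matrix(raw$sigma)) stopifnot(nrow(raw$sigma) == k)
    if (is.null(raw$n_candidates)) raw$n_candidates <- 1L
  }
  structure(list(charge = as.integer(charge), pi0 = pi0,
                 negative = negative, positive = positive,
                 n_targets = as.integer(n_targets),
                 n_decoys = as.integer(n_decoys),
                 discrete = discrete, raw = raw),
            class = "psmix_sim_charge")
}

rmvn <- function(n, mu, sigma) {
  k <- length(mu)
  if (!is.matrix(sigma)) sigma <- diag(rep(sigma, k), k)
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% chol(sigma), 2, mu, "+")
}

sample_discrete_levels <- function(n, discrete, component) {
  out <- list()
  for (nm in names(discrete)) {
    tab <- discrete[[nm]]
    p <- if (component == "incorrect") tab$p_incorrect else tab$p_correct
    out[[nm]] <- sample(tab$levels, n, replace = TRUE, prob = p)
  }
  out
}

#' Simulate a synthetic PSM table
#'
#' Draws a fully labeled PSM table from one or more [sim_charge()] blocks
#' under a fixed seed. In score-only mode the `discriminant_score` column is
#' filled directly from the configured mixture; in raw feature mode the
#' engine feature columns are filled instead (score the table with
#' [apply_discriminant()] or [fit_adaptive()]).
#'
#' @param config A `psmix_sim_charge` block or list of blocks.
#' @param seed Integer seed; the output is fully reproducible.
#' @return A PSM tibble with `true_label` set on every record.
#' @examples
#' tab <- simulate_psms(list(sim_charge(2, n_targets = 1000, n_decoys = 200)),
#'                      seed = 7)
#' table(tab$true_label, tab$is_decoy)
#' @export
simulate_psms <- function(config, seed = 1) {
  if (inherits(config, "psmix_sim_charge")) config <- list(config)
  stopifnot(all(vapply(config, inherits, logical(1), "psmix_sim_charge")))
  set.seed(seed)
  blocks <- lapply(config, simulate_one_charge)
  tab <- dplyr::bind_rows(blocks)
  validate_psm_table(tab)
  tab
}

simulate_one_charge <- function(cfg) {
  n <- cfg$n_targets
  incorrect <- stats::runif(n) < cfg$pi0
  n_inc <- sum(incorrect); n_cor <- n - n_inc
  scores <- numeric(n)
  scores[incorrect] <- component_sample(cfg$negative, n_inc)
  scores[!incorrect] <- component_sample(cfg$positive, n_cor)

  tab <- tibble::tibble(
    spectrum_id = sprintf("C%d_S%06d", cfg$charge, seq_len(n)),
    charge = cfg$charge,
    rank = 1L,
    is_decoy = FALSE,
    true_label = ifelse(incorrect, "incorrect", "correct")
  )
  lv <- list()
  for (nm in names(cfg$discrete)) lv[[nm]] <- rep(NA_real_, n)
  if (n_inc > 0) {
    drawn <- sample_discrete_levels(n_inc, cfg$discrete, "incorrect")
    for (nm in names(drawn)) lv[[nm]][incorrect] <- drawn[[nm]]
  }
  if (n_cor > 0) {
    drawn <- sample_discrete_levels(n_cor, cfg$discrete, "correct")
    for (nm in names(drawn)) lv[[nm]][!incorrect] <- drawn[[nm]]
  }
  tab <- attach_levels(tab, lv)

  if (is.null(cfg$raw)) {
    tab$discriminant_score <- scores
  } else {
    feats <- matrix(NA_real_, n, length(cfg$raw$features),
                    dimnames = list(NULL, cfg$raw$features))
    if (n_inc > 0) feats[incorrect, ] <- rmvn(n_inc, cfg$raw$mu_neg, cfg$raw$sigma)
    if (n_cor > 0) feats[!incorrect, ] <- rmvn(n_cor, cfg$raw$mu_pos, cfg$raw$sigma)
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(feats))
  }

  if (cfg$n_decoys > 0) {
    dt <- tibble::tibble(
      spectrum_id = sprintf("C%d_D%06d", cfg$charge, seq_len(cfg$n_decoys)),
      charge = cfg$charge,
      rank = 1L,
      is_decoy = TRUE,
      true_label = "incorrect"
    )
    dlv <- sample_discrete_levels(cfg$n_decoys, cfg$discrete, "incorrect")
    dt <- attach_levels(dt, dlv)
    if (is.null(cfg$raw)) {
      dt$discriminant_score <- component_sample(cfg$negative, cfg$n_decoys)
    } else {
      feats <- rmvn(cfg$n_decoys, cfg$raw$mu_neg, cfg$raw$sigma)
      colnames(feats) <- cfg$raw$features
      dt <- dplyr::bind_cols(dt, tibble::as_tibble(feats))
    }
    tab <- dplyr::bind_rows(tab, dt)
  }
  if (!is.null(cfg$raw) && cfg$raw$n_candidates > 1)
    tab <- expand_candidates(tab, cfg$raw)
  tab
}

# Add n_candidates - 1 lower-quality candidates per spectrum (always from the
# incorrect feature class; decoy spectra get decoy extras, so target and
# decoy best-candidates arise from the same competition) and assign ranks by
# a crude engine ordering on the first feature.
expand_candidates <- function(tab, raw) {
  n <- nrow(tab)
  extras <- lapply(2:raw$n_candidates, function(k) {
    ex <- tab
    ex$true_label <- "incorrect"
    f <- rmvn(n, raw$mu_neg, raw$sigma)
    colnames(f) <- raw$features
    ex[, raw$features] <- tibble::as_tibble(f)
    ex
  })
  all_cand <- dplyr::bind_rows(c(list(tab), extras))
  all_cand |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::mutate(rank = as.integer(rank(-.data[[raw$features[1]]],
                                         ties.method = "first"))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$spectrum_id, .data$rank)
}

attach_levels <- function(tab, lv) {
  for (nm in names(lv)) {
    if (nm == "delta_mass_bin") {
      # bin center plus sub-bin jitter; bin_delta_mass() recovers the level
      tab$delta_mass <- lv[[nm]] + stats::runif(nrow(tab), -0.45, 0.45)
    } else {
      tab[[nm]] <- as.integer(lv[[nm]])
    }
  }
  tab
}

#' Label-based true FDR of a synthetic table
#'
#' The realized fraction of incorrect matches among target records with
#' scores above the cutoff — the quantity every FDR estimator tries to
#' recover — computable only when ground-truth labels are present.
#'
#' @param table A PSM table with `true_label` on all target records.
#' @param t Score cutoff (scalar); the accepted set is `score > t`, decoys
#'   excluded.
#' @return The true FDR in `[0, 1]`.
#' @export
true_fdr <- function(table, t) {
  stopifnot(length(t) == 1)
  if (!"true_label" %in% names(table) ||
      anyNA(table$true_label[!table$is_decoy]))
    stop("`true_label` must be present on all target records", call. = FALSE)
  if (!"is_decoy" %in% names(table)) table$is_decoy <- FALSE
  keep <- !table$is_decoy & table$discriminant_score > t
  if (!any(keep))
    stop("no target records above cutoff ", signif(t, 6), call. = FALSE)
  mean(table$true_label[keep] == "incorrect")
}

#' Read a simulation config from YAML
#'
#' Plain-text counterpart of [sim_charge()] for the command line. Each
#' top-level list element describes one charge block:
#' ```
#' - charge: 2
#'   pi0: 0.7
#'   n_targets: 10000
#'   n_decoys: 2000
#'   negative: {kind: shifted_gamma, alpha: 4, beta: 2, shift: -3}
#'   positive: {kind: normal, mu: 3, sigma: 1}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A list of `psmix_sim_charge` blocks.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(b) {
    sim_charge(
      charge = b$charge %||% 2, pi0 = b$pi0 %||% 0.7,
      negative = dist_from_list(b$negative) %||% dist_shifted_gamma(4, 2, -3),
      positive = dist_from_list(b$positive) %||% dist_normal(3, 1),
      n_targets = b$n_targets %||% 10000, n_decoys = b$n_decoys %||% 0,
      discrete = discrete_from_list(b$discrete)
    )
  })
}

dist_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  switch(x$kind,
         normal = dist_normal(x$mu, x$sigma),
         shifted_gamma = dist_shifted_gamma(x$alpha, x$beta, x$shift),
         gumbel = dist_gumbel(x$location, x$scale),
         stop("unknown component kind: ", x$kind, call. = FALSE))
}

discrete_from_list <- function(x) {
  if (is.null(x)) return(list())
  purrr::imap(x, function(b, nm)
    discrete_feature_table(nm, unlist(b$levels), unlist(b$p_incorrect),
                           unlist(b$p_correct)))
}
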