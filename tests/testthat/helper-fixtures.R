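# Shared fixtures, all generated in code under fixed seeds.

# Reference simulation: the conditions the whole package is benchmarked
# under (70% incorrect, shifted-Gamma negative, Normal positive; decoys
# sized like the incorrect-target population).
reference_sim <- function(n_targets = 10000, n_decoys = 7000, seed = 1,
                          pi0 = 0.7) {
  simulate_psms(list(sim_charge(2, pi0 = pi0,
                                negative = dist_shifted_gamma(4, 2, -3),
                                positive = dist_normal(3, 1),
                                n_targets = n_targets, n_decoys = n_decoys)),
                seed = seed)
}

# Small hand-written PSM table with raw engine features.
tiny_psm_table <- function() {
  tibble::tibble(
    spectrum_id = c("s1", "s2", "s3"),
    charge = c(2L, 2L, 3L),
    rank = 1L,
    XCorr = c(3, 2.5, 1),
    deltaCn = c(0.4, 0.2, 0.05),
    SpRank = c(5, 12, 80),
    ntt = c(2L, 2L, 1L),
    nmc = c(0L, 1L, 0L),
    delta_mass = c(0.01, -0.02, 1.1),
    is_decoy = c(FALSE, FALSE, TRUE),
    discriminant_score = c(4.2, 1.1, -2.0),
    peptide = c("PEPTIDEA", "PEPTIDEB", NA),
    true_label = c("correct", "incorrect", "incorrect")
  )
}

# Independent Bayes-ratio oracle, coded separately from e_step().
oracle_pep <- function(pi0, f0, f1) pi0 * f0 / (pi0 * f0 + (1 - pi0) * f1)

# Raw-feature candidate simulation used by the adaptive tests.
adaptive_sim <- function(seed, n_targets = 1500, n_decoys = 900, pi0 = 0.6,
                         n_candidates = 3) {
  sigma <- matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3, 3)
  cand <- simulate_psms(list(sim_charge(
    2, pi0 = pi0, n_targets = n_targets, n_decoys = n_decoys,
    raw = list(mu_neg = c(0, 0, 0), mu_pos = c(1.6, 1.2, 0.8),
               sigma = sigma, n_candidates = n_candidates))), seed = seed)
  list(candidates = cand, sigma = sigma,
       bayes_direction = {
         d <- solve(sigma, c(1.6, 1.2, 0.8)); d / sqrt(sum(d^2))
       })
}

# Largest accepted-target count whose decoy-ratio FDR stays at or below
# fdr_max (scan over observed target scores).
n_accepted_at_decoy_fdr <- function(table, fdr_max = 0.05) {
  s <- sort(table$discriminant_score[!table$is_decoy], decreasing = TRUE)
  cnt <- 0
  for (t in s) {
    f <- tryCatch(fdr_decoy_ratio(table, t - 1e-9), error = function(e) NA)
    if (!is.na(f) && f <= fdr_max)
      cnt <- sum(table$discriminant_score[!table$is_decoy] >= t)
  }
  cnt
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
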