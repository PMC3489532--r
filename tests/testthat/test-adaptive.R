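test_that("the Fisher discriminant separates simple classes", {
  # symmetric 1-D case: positive weight, intercept ~ 0, perfect separation
  cf <- train_linear_discriminant(matrix(c(2, 3), ncol = 1),
                                  matrix(c(-3, -2), ncol = 1))
  expect_gt(cf$weights[[1]], 0)
  expect_equal(cf$intercept, 0, tolerance = 1e-12)
  score <- function(x) cf$intercept + cf$weights[[1]] * x
  expect_true(all(score(c(2, 3)) > 0) && all(score(c(-3, -2)) < 0))
  # identical class means: no direction to find
  set.seed(2)
  a <- matrix(rnorm(40), ncol = 2); b <- a + 1e-9
  cf0 <- train_linear_discriminant(a, b)
  expect_lt(sum(abs(cf0$weights)) * 0 + abs(sum(cf0$weights * colMeans(a)) +
                                              cf0$intercept), 1e-6)
  expect_error(train_linear_discriminant(matrix(1, 1, 1), matrix(0, 2, 1)),
               "2 rows")
})

test_that("the learned direction matches the closed-form LDA oracle", {
  set.seed(19)
  sigma <- matrix(c(1, 0.5, 0.5, 2), 2, 2)
  R <- chol(sigma)
  pos <- matrix(rnorm(4000), ncol = 2) %*% R
  pos <- sweep(pos, 2, c(2, 1), "+")
  neg <- matrix(rnorm(4000), ncol = 2) %*% R
  cf <- train_linear_discriminant(pos, neg)
  truth <- solve(sigma, c(2, 1))
  # within 5 degrees of the true Bayes direction
  expect_gt(cosine_sim(unname(cf$weights), truth), cos(5 * pi / 180))
  # cross-check against an independent LDA implementation
  ld <- MASS::lda(rbind(pos, neg), grouping = rep(c("p", "n"), each = 2000))
  expect_gt(abs(cosine_sim(unname(cf$weights), as.numeric(ld$scaling))), 0.999)
})

test_that("averaged coefficients are exactly the mean of the subsample fits", {
  set.seed(7)
  pos <- matrix(rnorm(60, 2), ncol = 3)
  neg <- matrix(rnorm(300), ncol = 3)
  colnames(pos) <- colnames(neg) <- c("F1", "F2", "F3")
  fits <- lapply(1:10, function(i) {
    take <- sample(nrow(pos), 14)
    psmix:::coeff_vector(train_linear_discriminant(pos[take, ], neg))
  })
  avg <- rowMeans(do.call(cbind, fits))
  expect_identical(avg, colMeans(do.call(rbind, fits)))
})

test_that("candidate promotion picks the top new score, ties to lowest rank", {
  cand <- tibble::tibble(
    spectrum_id = rep(c("a", "b"), each = 3),
    charge = 2L, rank = rep(1:3, 2), is_decoy = FALSE,
    F1 = c(1, 5, 2, 3, 3, 1))
  scored <- apply_discriminant(cand, discriminant_coefficients(0, c(F1 = 1)))
  best <- psmix:::promote_best(scored)
  picked <- scored[sort(best), c("spectrum_id", "rank")]
  expect_equal(picked$rank[picked$spectrum_id == "a"], 2L)  # rank-2 wins on score
  expect_equal(picked$rank[picked$spectrum_id == "b"], 1L)  # tie -> lowest rank
})

test_that("fit_adaptive recovers a known Bayes direction from a weak start", {
  sim <- adaptive_sim(seed = 3, n_targets = 3000, n_decoys = 1500)
  init <- discriminant_coefficients(0, c(F1 = 1, F2 = 0.1, F3 = 0.1))
  res <- fit_adaptive(sim$candidates, init,
                      adaptive_options(top_k = 3, max_rounds = 40),
                      seed = 11, use_decoys = TRUE, min_records = 100)
  expect_true(res$converged)
  expect_gt(cosine_sim(unname(res$coefficients$weights), sim$bayes_direction),
            0.95)
  # promoted best candidates maximize the final score within each spectrum
  rescored <- apply_discriminant(sim$candidates, res$coefficients)
  by_spec <- split(rescored$discriminant_score, rescored$spectrum_id)
  best_by_spec <- split(res$best$discriminant_score, res$best$spectrum_id)
  expect_true(all(vapply(names(best_by_spec), function(id)
    best_by_spec[[id]] >= max(by_spec[[id]]) - 1e-9, logical(1))))
})

test_that("an already-optimal start converges immediately on separated data", {
  # cleanly separated classes, single candidate per spectrum (the round map
  # is then a pure function of the coefficients): retraining from the
  # previously converged coefficients is a fixed point
  sigma <- matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3, 3)
  cand <- simulate_psms(list(sim_charge(
    2, pi0 = 0.5, n_targets = 2000, n_decoys = 1000,
    raw = list(mu_neg = c(0, 0, 0), mu_pos = c(3.5, 3, 2.5),
               sigma = sigma, n_candidates = 1))), seed = 9)
  init <- discriminant_coefficients(0, c(F1 = 0.6, F2 = 0.55, F3 = 0.5))
  first <- fit_adaptive(cand, init, adaptive_options(top_k = 1, max_rounds = 40),
                        seed = 4, use_decoys = TRUE, min_records = 100)
  again <- fit_adaptive(cand, first$coefficients,
                        adaptive_options(top_k = 1, max_rounds = 40),
                        seed = 4, use_decoys = TRUE, min_records = 100)
  expect_true(again$converged)
  expect_lte(again$n_rounds, 2)
})

test_that("fit_adaptive is reproducible under a fixed seed", {
  sim <- adaptive_sim(seed = 6, n_targets = 1500, n_decoys = 900)
  init <- discriminant_coefficients(0, c(F1 = 1, F2 = 0.1, F3 = 0.1))
  r1 <- fit_adaptive(sim$candidates, init, adaptive_options(top_k = 3),
                     seed = 2, use_decoys = TRUE, min_records = 100)
  r2 <- fit_adaptive(sim$candidates, init, adaptive_options(top_k = 3),
                     seed = 2, use_decoys = TRUE, min_records = 100)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$trace, r2$trace)
})

test_that("adaptive coefficients admit more targets at a fixed decoy FDR", {
  # constrained-search mimic: weakly informative fixed coefficients versus
  # the adaptive refit, scored by targets passing decoy-ratio FDR <= 0.05
  wins <- 0; n_ok <- 0
  weak <- discriminant_coefficients(-0.8, c(F1 = 1, F2 = 0.05, F3 = 0.05))
  for (r in 1:10) {
    sim <- adaptive_sim(seed = 200 + r)
    n_fixed <- n_accepted_at_decoy_fdr(
      apply_discriminant(sim$candidates[sim$candidates$rank == 1, ], weak))
    res <- tryCatch(suppressWarnings(
      fit_adaptive(sim$candidates, weak,
                   adaptive_options(top_k = 3, max_rounds = 25),
                   seed = 5, use_decoys = TRUE, min_records = 100)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    if (n_accepted_at_decoy_fdr(res$best) >= n_fixed) wins <- wins + 1
  }
  expect_gte(n_ok, 8)
  expect_gt(wins / n_ok, 0.5)
})

test_that("adaptive option validation and selection errors are informative", {
  expect_error(adaptive_options(pep_low = 0.9, pep_high = 0.5), "pep_low")
  sim <- adaptive_sim(seed = 6, n_targets = 300, n_decoys = 200)
  init <- discriminant_coefficients(0, c(F1 = 1, F2 = 0.1, F3 = 0.1))
  expect_error(
    fit_adaptive(sim$candidates, init,
                 adaptive_options(top_k = 3, min_positives = 0,
                                  pep_low = 1e-12, pep_high = 1 - 1e-15),
                 seed = 1, min_records = 100),
    "training set too small")
})
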