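test_that("the E-step is the Bayes ratio", {
  # symmetry: equal densities and pi0 = 0.5 give PEP 0.5
  m <- mixture_model(2, 0.5, dist_normal(0, 1), dist_normal(0, 1))
  expect_equal(e_step(m, c(-1, 0, 2)), rep(0.5, 3))
  # boundary: pi0 = 1 forces PEP 1 wherever the negative density is positive
  m1 <- mixture_model(2, 1, dist_normal(0, 1), dist_normal(5, 1))
  expect_equal(e_step(m1, c(-2, 0, 3)), rep(1, 3))
  # frozen hand computation of the ratio 0.96*0.0724 / (0.96*0.0724 + 0.04*0.1473)
  expect_equal(oracle_pep(0.96, 0.0724, 0.1473), 0.9218526, tolerance = 1e-7)
})

test_that("e_step equals an independent Bayes-ratio oracle to 1e-12", {
  set.seed(12)
  for (i in 1:50) {
    pi0 <- runif(1)
    neg <- dist_shifted_gamma(runif(1, 1, 6), runif(1, 0.5, 3), runif(1, -5, -1))
    pos <- dist_normal(runif(1, 0, 4), runif(1, 0.5, 2))
    m <- mixture_model(2, pi0, neg, pos)
    s <- runif(5, -2, 6)
    expect_equal(e_step(m, s),
                 oracle_pep(pi0, component_density(neg, s),
                            component_density(pos, s)),
                 tolerance = 1e-12)
  }
})

test_that("e_step includes discrete factors and errors on degenerate density", {
  tab_nmc <- discrete_feature_table("nmc", c(0, 1), c(0.404, 0.596),
                                    c(0.926, 0.074))
  m <- mixture_model(2, 0.5, dist_normal(0, 1), dist_normal(0, 1),
                     list(nmc = tab_nmc))
  pep <- e_step(m, 0, levels = list(nmc = 0))
  expect_equal(pep, oracle_pep(0.5, dnorm(0) * 0.404, dnorm(0) * 0.926))
  # NA level skips the factor
  expect_equal(e_step(m, 0, levels = list(nmc = NA)), 0.5)
  # both components zero at a score below the gamma shift with a far positive
  md <- mixture_model(2, 0.5, dist_shifted_gamma(2, 1, 0), dist_normal(100, 0.1))
  expect_error(e_step(md, -5), "degenerate")
})

test_that("M-step estimators reproduce the printed formulas", {
  expect_equal(m_step_pi0(c(1, 0, 1, 0)), 0.5)
  expect_equal(m_step_pi0(rep(1, 7)), 1)
  expect_equal(m_step_pi0(c(0.2, 0.4, 0.9)), 0.5)
  expect_error(m_step_pi0(numeric(0)), "empty")

  # unweighted MLE (biased variance form)
  nm <- m_step_normal(c(1, 2, 3), rep(0, 3))
  expect_equal(unname(nm), c(2, sqrt(2 / 3)))
  expect_equal(unname(m_step_normal(c(0, 2), c(0.5, 0.5))), c(1, 1))
  # a single effective point has zero variance
  expect_error(m_step_normal(c(10, 4), c(1, 0)), "degenerate")
  expect_error(m_step_normal(c(1, 2), c(1, 1)), "weights")

  # hand computation: shift 1, m1 = 1, m2 = 2/3
  gm <- m_step_gamma(c(1, 2, 3), rep(1, 3))
  expect_equal(unname(gm), c(1.5, 1.5, 1))
  expect_error(m_step_gamma(c(0, 0, 5), c(1, 1, 0)), "degenerate")
  expect_error(m_step_gamma(c(1, 2), c(0, 0)), "weights")
})

test_that("gamma moment estimates are consistent when the shift is known", {
  # shape 1: the sample minimum converges to the shift at rate 1/n,
  # so the printed estimator recovers the truth
  set.seed(77)
  x <- -2 + rgamma(50000, 1, 2)
  gm <- m_step_gamma(x, rep(1, 50000))
  expect_equal(unname(gm["alpha"]), 1, tolerance = 0.05)
  expect_equal(unname(gm["beta"]), 2, tolerance = 0.05)
  # shape 4: the sample minimum overshoots the true shift by O(n^(-1/4)),
  # biasing alpha downward; the moments about the TRUE shift recover it
  set.seed(77)
  x4 <- -2 + rgamma(50000, 4, 2)
  m1 <- mean(x4 + 2); m2 <- mean((x4 + 2 - m1)^2)
  expect_equal(m1^2 / m2, 4, tolerance = 0.1)
  expect_equal(m1 / m2, 2, tolerance = 0.05)
  gm4 <- m_step_gamma(x4, rep(1, 50000))
  expect_gt(gm4[["shift"]], -2)          # min is above the true shift
  expect_lt(gm4[["alpha"]], 4)           # hence alpha is biased down
  expect_equal(gm4[["alpha"]], 4, tolerance = 0.45)
})

test_that("gumbel moment matching inverts the variance identity", {
  set.seed(13)
  x <- -1 - 0.8 * log(-log(runif(50000)))
  gm <- m_step_gumbel(x, rep(1, 50000))
  expect_equal(unname(gm["scale"]), 0.8, tolerance = 0.02)
  expect_equal(unname(gm["location"]), -1, tolerance = 0.02)
})

test_that("discrete M-step computes weighted multinomial frequencies", {
  tab <- m_step_discrete(c(0, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(tab$p_incorrect, c(0.5, 0.5))
  expect_equal(tab$p_correct, c(1, 0))
  # all records on one level: both vectors are point masses
  tab1 <- m_step_discrete(rep(2, 5), rep(0.5, 5))
  expect_equal(tab1$p_incorrect, 1)
  expect_equal(tab1$p_correct, 1)
  expect_error(m_step_discrete(c(0, 1), c(1, 1)), "zero total weight")
  # recovery of known per-component tables from a large simulation
  set.seed(14)
  n <- 50000
  inc <- runif(n) < 0.6
  lv <- ifelse(inc, sample(0:2, n, TRUE, c(0.5, 0.3, 0.2)),
               sample(0:2, n, TRUE, c(0.1, 0.2, 0.7)))
  tab2 <- m_step_discrete(lv, as.numeric(inc))
  expect_equal(tab2$p_incorrect, c(0.5, 0.3, 0.2), tolerance = 0.02)
  expect_equal(tab2$p_correct, c(0.1, 0.2, 0.7), tolerance = 0.02)
})

test_that("fit_em recovers the generating parameters", {
  tab <- reference_sim(n_targets = 10000, n_decoys = 0, seed = 1)
  fit <- fit_em(tab)
  m <- fit$models[["2"]]
  expect_true(fit$converged[["2"]])
  expect_equal(m$pi0, 0.7, tolerance = 0.02)
  expect_equal(m$positive$mu, 3, tolerance = 0.05)
  expect_equal(m$positive$sigma, 1, tolerance = 0.05)
})

test_that("EM iterations do not decrease the log-likelihood beyond MoM noise", {
  # the Gamma update is the printed method-of-moments surrogate, not an
  # exact maximizer, so ascent holds up to a small numerical slack
  tab <- reference_sim(n_targets = 5000, n_decoys = 0, seed = 9)
  fit <- fit_em(tab)
  ll <- fit$trace$value[fit$trace$term == "loglik"]
  expect_gt(length(ll), 3)
  expect_true(all(diff(ll) > -1e-4 * abs(ll[length(ll)])))
})

test_that("semisupervised decoys are pinned and contribute only negatively", {
  tab <- reference_sim(n_targets = 3000, n_decoys = 1500, seed = 5)
  fit <- fit_em(tab, use_decoys = TRUE)
  expect_true(all(fit$pep[tab$is_decoy] == 1))
  expect_true(all(fit$pep >= 0 & fit$pep <= 1))
  # the gamma shift uses the global minimum including decoys
  expect_equal(fit$models[["2"]]$negative$shift, min(tab$discriminant_score))
})

test_that("semisupervised fits beat unsupervised on the negative component", {
  # hard-overlap conditions; compared on the (mean, sd) moment scale over
  # 20 seeded replicates, as in the decoy-assisted-fitting rationale
  truth <- component_moments(dist_shifted_gamma(4, 2, -3))
  wins <- 0; n_ok <- 0
  for (r in 1:20) {
    tab <- simulate_psms(list(sim_charge(2, pi0 = 0.85,
                                         negative = dist_shifted_gamma(4, 2, -3),
                                         positive = dist_normal(1.2, 1),
                                         n_targets = 2000, n_decoys = 1000)),
                         seed = 100 + r)
    f_semi <- tryCatch(fit_em(tab, use_decoys = TRUE), error = function(e) NULL)
    f_uns <- tryCatch(fit_em(tab), error = function(e) NULL)
    if (is.null(f_semi) || is.null(f_uns)) next
    n_ok <- n_ok + 1
    err <- function(f) mean((component_moments(f$models[["2"]]$negative) - truth)^2)
    if (err(f_semi) <= err(f_uns)) wins <- wins + 1
  }
  expect_gte(n_ok, 18)
  expect_gt(wins / n_ok, 0.5)
})

test_that("degenerate and sparse inputs are handled per contract", {
  tab <- tibble::tibble(spectrum_id = paste0("s", 1:200), charge = 2L,
                        rank = 1L, is_decoy = FALSE, discriminant_score = 1)
  expect_error(fit_em(tab), "identical")
  # sparse charge skipped with a warning, other charges still fit
  tab2 <- reference_sim(n_targets = 1000, n_decoys = 0, seed = 2)
  tab3 <- dplyr::bind_rows(tab2, tibble::tibble(
    spectrum_id = paste0("x", 1:5), charge = 4L, rank = 1L, is_decoy = FALSE,
    true_label = "incorrect", discriminant_score = rnorm(5)))
  expect_warning(fit <- fit_em(tab3), "charge 4")
  expect_setequal(names(fit$models), "2")
  expect_equal(fit$skipped, 4L)
  expect_true(all(is.na(fit$pep[tab3$charge == 4])))
  # every charge sparse -> error
  expect_error(suppressWarnings(fit_em(tab3[tab3$charge == 4, ])), "min_records")
})

test_that("discrete features sharpen the posterior in the fitted direction", {
  nmc_tab <- discrete_feature_table("nmc", c(0, 1), c(0.404, 0.596),
                                    c(0.926, 0.074))
  tab <- simulate_psms(list(sim_charge(2, n_targets = 8000,
                                       discrete = list(nmc = nmc_tab))), seed = 6)
  fit <- fit_em(tab, discrete = "nmc")
  m <- fit$models[["2"]]
  expect_equal(m$discrete$nmc$p_incorrect, c(0.404, 0.596), tolerance = 0.03)
  expect_equal(m$discrete$nmc$p_correct, c(0.926, 0.074), tolerance = 0.03)
  expect_equal(sum(m$discrete$nmc$p_incorrect), 1, tolerance = 1e-9)
  expect_equal(sum(m$discrete$nmc$p_correct), 1, tolerance = 1e-9)
  # at the same score, an NMC of 0 lowers the PEP relative to NMC of 1
  pep0 <- e_step(m, 1, levels = list(nmc = 0))
  pep1 <- e_step(m, 1, levels = list(nmc = 1))
  expect_lt(pep0, pep1)
})

test_that("the gumbel negative family fits the same structure", {
  tab <- simulate_psms(list(sim_charge(2, pi0 = 0.7,
                                       negative = dist_gumbel(-1.16, 0.76),
                                       positive = dist_normal(2.6, 1.0),
                                       n_targets = 8000)), seed = 8)
  fit <- fit_em(tab, negative = "gumbel")
  m <- fit$models[["2"]]
  expect_equal(m$pi0, 0.7, tolerance = 0.03)
  expect_equal(m$negative$location, -1.16, tolerance = 0.08)
  expect_equal(m$negative$scale, 0.76, tolerance = 0.05)
})
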