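ref_model <- function() {
  mixture_model(2, 0.7, dist_shifted_gamma(4, 2, -3), dist_normal(3, 1))
}

test_that("p-values and FPR are the negative-component tail, identically", {
  m <- ref_model()
  expect_equal(p_value_at(m, -3), 1)            # full support above the shift
  expect_lt(p_value_at(m, 50), 1e-12)           # vanishes in the far tail
  g <- mixture_model(2, 0.5, dist_gumbel(0, 1), dist_normal(3, 1))
  expect_equal(p_value_at(g, 0), 1 - exp(-1))   # Gumbel CDF closed form
  # definitional identity on random models and cutoffs
  set.seed(15)
  for (i in 1:100) {
    mm <- mixture_model(2, runif(1),
                        dist_shifted_gamma(runif(1, 1, 5), runif(1, 0.5, 2),
                                           runif(1, -4, 0)),
                        dist_normal(runif(1, 1, 4), runif(1, 0.5, 2)))
    t0 <- runif(1, -4, 6)
    expect_identical(fpr_at(mm, t0), p_value_at(mm, t0))
  }
  # median cutoff gives 0.5 and the tail is non-increasing
  med <- -3 + qgamma(0.5, 4, 2)
  expect_equal(fpr_at(m, med), 0.5)
  grid <- seq(-4, 8, length.out = 50)
  expect_true(all(diff(fpr_at(m, grid)) <= 0))
})

test_that("model-based FDR follows the two-tail formula", {
  m_sym <- mixture_model(2, 0.5, dist_normal(0, 1), dist_normal(0, 1))
  expect_equal(fdr_model(m_sym, c(-2, 0, 1.7)), rep(0.5, 3))
  m <- ref_model()
  expect_equal(fdr_model(m, -1e6), 0.7, tolerance = 1e-9)  # all rejected -> pi0
  a0 <- component_tail(m$negative, 2); a1 <- component_tail(m$positive, 2)
  expect_equal(fdr_model(m, 2), 0.7 * a0 / (0.7 * a0 + 0.3 * a1))
  # far above all mass the rejection region is empty
  expect_error(fdr_model(m, 1e6), "empty rejection region")
})

test_that("conditioning on a favorable discrete level lowers the FDR", {
  nmc <- discrete_feature_table("nmc", c(0, 1), c(0.404, 0.596),
                                c(0.926, 0.074))
  m <- mixture_model(2, 0.96, dist_gumbel(-1.16, 0.76), dist_normal(2.6, 1.9),
                     list(nmc = nmc))
  for (t in c(-1, 0, 1, 2)) {
    un <- fdr_model(m, t)
    cond <- fdr_model(m, t, condition = list(nmc = 0))
    expect_lt(cond, un)
    # worked form: tails scaled by 0.404 and 0.926
    a0 <- component_tail(m$negative, t) * 0.404
    a1 <- component_tail(m$positive, t) * 0.926
    expect_equal(cond, 0.96 * a0 / (0.96 * a0 + 0.04 * a1))
  }
  expect_error(fdr_model(m, 0, condition = list(ntt = 2)), "ntt")
  expect_error(fdr_model(m, 0, condition = list(nmc = 7)), "level")
})

test_that("mean-PEP FDR averages over the accepted set", {
  expect_equal(fdr_mean_pep(c(0.1, 0.2, 0.3), c(5, 6, 7), 1), 0.2)
  expect_equal(fdr_mean_pep(c(0.1, 0.2, 0.3), c(5, 6, 7), 6), 0.25) # >= t
  expect_equal(fdr_mean_pep(0.42, 3, 3), 0.42)
  expect_error(fdr_mean_pep(c(0.1), c(1), 2), "cutoff")
})

test_that("decoy-ratio FDR counts decoys over targets above the cutoff", {
  tab <- tibble::tibble(
    spectrum_id = paste0("s", 1:60), charge = 2L, rank = 1L,
    is_decoy = rep(c(TRUE, FALSE), c(10, 50)),
    discriminant_score = c(rep(2, 5), rep(-2, 5), rep(3, 50)))
  expect_equal(fdr_decoy_ratio(tab, 0), 5 / 50)
  expect_equal(fdr_decoy_ratio(tab, 2.5), 0)   # cutoff above every decoy
  expect_error(fdr_decoy_ratio(tab, 10), "cutoff")
  expect_error(fdr_decoy_ratio(tab[!tab$is_decoy, ], 0), "decoy")
})

test_that("q-values are the running minimum FDR over lower cutoffs", {
  expect_equal(q_values(c(1, 2, 3), c(0.05, 0.03, 0.04)), c(0.05, 0.03, 0.03))
  # monotone-decreasing FDR passes through unchanged
  expect_equal(q_values(1:5, c(0.5, 0.4, 0.3, 0.2, 0.1)),
               c(0.5, 0.4, 0.3, 0.2, 0.1))
  # brute-force oracle on 1,000 random FDR sequences, unordered scores
  set.seed(16)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    s <- runif(n); f <- runif(n)
    brute <- vapply(s, function(si) min(f[s <= si]), numeric(1))
    expect_identical(q_values(s, f), brute)
  }
  # function-style accessor
  m <- ref_model()
  s <- c(0, 1, 2)
  expect_equal(q_values(s, function(t) fdr_model(m, t)),
               cummin(fdr_model(m, s)))
})

test_that("the confidence table assembles consistent per-record measures", {
  tab <- reference_sim(n_targets = 5000, n_decoys = 3500, seed = 2)
  fit <- fit_em(tab, use_decoys = TRUE)
  conf <- build_confidence_table(fit, tab)
  expect_equal(nrow(conf), nrow(tab))
  expect_true(all(conf$pep >= 0 & conf$pep <= 1))
  expect_true(all(conf$q_value >= 0 & conf$q_value <= 1))
  # q-values non-increasing in score within the targets
  o <- order(conf$score)
  qt <- conf$q_value[o][!conf$is_decoy[o]]
  expect_true(all(diff(qt) <= 1e-12))
  # pep column equals an e_step re-evaluation for targets
  m <- fit$models[["2"]]
  tgt <- !conf$is_decoy
  expect_equal(conf$pep[tgt], e_step(m, conf$score[tgt]))
  # model vs mean-PEP q-values agree closely on a well-specified fit
  conf2 <- build_confidence_table(fit, tab, fdr_method = "mean_pep")
  expect_lt(max(abs(conf$q_value[tgt] - conf2$q_value[tgt])), 0.02)
  # a charge with no model is refused
  tab_bad <- tab; tab_bad$charge[1] <- 5L
  tab_bad$spectrum_id[1] <- "other"
  expect_error(build_confidence_table(fit, tab_bad), "charge 5")
})

test_that("all three FDR estimators track the label-based truth", {
  tab <- reference_sim(n_targets = 10000, n_decoys = 7000, seed = 1)
  fit <- fit_em(tab, use_decoys = TRUE)
  m <- fit$models[["2"]]
  tgt <- !tab$is_decoy
  scores <- tab$discriminant_score[tgt]
  cuts <- quantile(scores, seq(0.05, 0.975, by = 0.025))
  cuts <- cuts[vapply(cuts, function(t) sum(scores > t) >= 200, logical(1))]
  truth <- vapply(cuts, function(t) true_fdr(tab, t), numeric(1))
  est_model <- vapply(cuts, function(t) fdr_model(m, t), numeric(1))
  est_pep <- vapply(cuts, function(t) fdr_mean_pep(fit$pep[tgt], scores, t),
                    numeric(1))
  est_decoy <- vapply(cuts, function(t) fdr_decoy_ratio(tab, t), numeric(1))
  expect_lt(max(abs(est_model - truth)), 0.02)
  expect_lt(max(abs(est_pep - truth)), 0.02)
  expect_lt(max(abs(est_decoy - truth)), 0.02)
})
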