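test_that("category probabilities match hand-computed values and sum to one", {
  expect_equal(as.numeric(category_probs(0, c(0, 0, 0, 0))), rep(0.2, 5))
  expect_equal(as.numeric(category_probs(0, 0)), c(0.5, 0.5))

  # cumulative exponents at theta = 1, delta = (0.5, 1.5): (0, 0.5, 0)
  e <- exp(c(0, 0.5, 0))
  expect_equal(as.numeric(category_probs(1, c(0.5, 1.5))), e / sum(e),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(category_probs(1, c(0.5, 1.5))), 4),
               c(0.2741, 0.4519, 0.2741))

  th <- seq(-6, 6, by = 0.25)
  p <- category_probs(th, c(-1.3, -0.2, 1.2, 0.1))
  expect_equal(rowSums(p), rep(1, length(th)), tolerance = 1e-12)

  # expected item score strictly increasing in theta
  es <- as.numeric(p %*% (0:4))
  expect_true(all(diff(es) > 0))
})

test_that("MML-EM recovers generating parameters and the likelihood behaves", {
  delta <- recovery_delta()
  m <- recovery_matrix(n = 2000L, seed = 1)
  fit <- fit_pcm(m)

  expect_true(fit$converged)
  rmse <- sqrt(mean((unlist(fit$delta) - unlist(delta))^2))
  expect_lte(rmse, 0.1)
  expect_equal(fit$prior_sd, 1, tolerance = 0.1)

  # EM trajectory never decreases
  expect_true(all(diff(fit$loglik_trace) > -1e-8))

  # the fitted optimum dominates the generating parameters on the same data
  ll_gen <- pcm_marginal_loglik(m, delta, prior_sd = 1)
  expect_gte(fit$loglik, ll_gen)

  # duplicating every person leaves the estimates unchanged
  small <- response_matrix(m$values[1:400, ], n_categories = m$n_categories)
  doubled <- response_matrix(rbind(small$values, small$values),
                             n_categories = m$n_categories)
  f1 <- fit_pcm(small)
  f2 <- fit_pcm(doubled)
  expect_equal(unlist(f1$delta), unlist(f2$delta), tolerance = 1e-3)
  expect_equal(f1$prior_sd, f2$prior_sd, tolerance = 1e-3)
})

test_that("unobserved categories abort the fit with advice to recode", {
  vals <- matrix(sample(c(0L, 1L, 3L), 200, TRUE), 100, 2)
  m <- response_matrix(vals, n_categories = c(4, 4))
  expect_error(fit_pcm(m), "unobserved categor")
})

test_that("reverse-coding every item flips the sign of the step difficulties", {
  delta <- recovery_delta()
  m <- recovery_matrix(n = 1500L, seed = 23)
  mr <- response_matrix(4L - m$values, n_categories = m$n_categories)
  f <- fit_pcm(m, estimate_prior_sd = FALSE)
  fr <- fit_pcm(mr, estimate_prior_sd = FALSE)
  # reversing categories maps delta_k -> -delta_{K-k} in reverse order
  for (i in seq_along(delta)) {
    expect_equal(fr$delta[[i]], -rev(f$delta[[i]]), tolerance = 1e-6)
  }
})

test_that("EAP scores are symmetric, monotone, and match fine-grid integration", {
  # mirror-symmetric items, sd fixed at 1: the middle raw sum scores 0
  delta <- list(a = c(-1, 1), b = c(-0.5, 0.5))
  gen <- pcm_model(delta, prior_sd = 1)
  mid <- response_matrix(matrix(c(1L, 1L), 1, 2), n_categories = c(3, 3))
  expect_equal(eap_scores(gen, mid)$eap, 0, tolerance = 1e-10)

  # all-best strictly below all-worst
  both <- response_matrix(rbind(c(0L, 0L), c(2L, 2L)),
                          n_categories = c(3, 3))
  sc <- eap_scores(gen, both)
  expect_lt(sc$eap[1], sc$eap[2])
  expect_true(all(sc$se > 0))

  # refined-quadrature oracle within 1e-3 logits
  delta2 <- list(a = c(-0.7, 0.4), b = c(-1.1, 0.2, 0.9))
  gen2 <- pcm_model(delta2, prior_sd = 1.2)
  pats <- as.matrix(expand.grid(0:2, 0:3))
  m2 <- response_matrix(pats, item_ids = c("a", "b"), n_categories = c(3, 4))
  got <- eap_scores(gen2, m2)$eap
  want <- apply(pats, 1, oracle_eap, delta = delta2, prior_sd = 1.2)
  expect_equal(got, unname(want), tolerance = 1e-3)
})

test_that("equal raw sums imply equal EAP scores (sum-score sufficiency)", {
  delta <- list(a = c(-1.2, 0.3), b = c(-0.4, 0.8), c = c(0.1, 1.1))
  gen <- pcm_model(delta, prior_sd = 1)
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  m <- response_matrix(pats, item_ids = c("a", "b", "c"),
                       n_categories = rep(3, 3))
  eap <- eap_scores(gen, m)$eap
  for (s in unique(rowSums(pats))) {
    expect_lt(diff(range(eap[rowSums(pats) == s])), 1e-12)
  }
})

test_that("threshold report flags disorder and closeness and picks the merge", {
  fit <- pcm_model(list(ok = c(-2, -1, 0, 1),
                        bad = c(-2, -1, 1, 0.5),
                        tight = c(-1, -0.9, 1, 2)))
  rep_ <- andrich_thresholds(fit, tol = 0.2)
  expect_false(any(rep_$items$ok$disordered) || any(rep_$items$ok$close))
  expect_null(rep_$items$ok$merge)

  # disorder between the 3rd and 4th steps -> merge the two worst options
  expect_true(rep_$items$bad$disordered[3])
  expect_equal(rep_$items$bad$merge, c(3L, 4L))

  # closeness only
  expect_true(rep_$items$tight$close[1])
  expect_equal(rep_$items$tight$merge, c(1L, 2L))
  expect_true(rep_$any_flag)
})

test_that("auto_collapse leaves ordered data alone and repairs disorder", {
  # widely separated generating gaps (1 logit): no spurious closeness flags
  m <- simulate_responses(cohort_spec("cts_tasks", seed = 29))
  ac <- auto_collapse(m)
  expect_equal(nrow(ac$merges), 0L)
  expect_identical(ac$data$values, m$values)
  expect_false(ac$thresholds$any_flag)

  # reversed top steps on every item of the dupuytren-like cohort
  dup <- simulate_responses(cohort_spec("dupuytren_tasks", seed = 37))
  fit0 <- fit_pcm(dup)
  rep0 <- andrich_thresholds(fit0)
  n_disordered <- sum(vapply(rep0$items, function(it) it$disordered[3], TRUE))
  expect_gte(n_disordered, 5)

  ac2 <- auto_collapse(dup)
  top_merges <- ac2$merges[ac2$merges$cat_low == 3 & ac2$merges$cat_high == 4, ]
  expect_gte(length(unique(top_merges$item)), 5)
  expect_false(ac2$thresholds$any_flag)
  # cumulative map reproduces the final data from the original
  expect_identical(apply_recode(dup, ac2$recode)$values, ac2$data$values)
})
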