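test_that("standardized residuals have the defined scale and center", {
  # dichotomous item with P = 0.5 at theta = 0: response 1 gives z = 1
  fit <- pcm_model(list(a = 0, b = 0))
  m <- response_matrix(matrix(c(1L, 0L), 1, 2), item_ids = c("a", "b"),
                       n_categories = c(2, 2))
  z <- standardized_residuals(fit, m, data.frame(eap = 0))
  expect_equal(as.numeric(z), c(1, -1), tolerance = 1e-12)

  # under the model the residual mean is near zero
  m2 <- recovery_matrix(n = 1000L, seed = 47)
  f2 <- fit_pcm(m2)
  z2 <- standardized_residuals(f2, m2, eap_scores(f2, m2))
  expect_lt(abs(mean(z2)), 0.05)
})

test_that("infit/outfit calibrate near 1 under the model and stay in band", {
  m <- recovery_matrix(n = 2000L, seed = 42)
  fit <- fit_pcm(m)
  io <- infit_outfit(fit, m)
  expect_true(all(io$outfit > 0.5 & io$outfit < 1.7))
  expect_true(all(io$infit > 0.5 & io$infit < 1.7))
  expect_true(all(abs(io$outfit - 1) < 0.15))
  expect_false(any(io$flagged))
})

test_that("median infit/outfit per item sit in [0.9, 1.1] across replicates", {
  delta <- recovery_delta()
  set.seed(53)
  reps <- 200
  stats_arr <- array(NA_real_, c(reps, 6, 2))
  for (r in seq_len(reps)) {
    m <- simulate_responses(sim_spec(400L, delta, seed = 53000 + r))
    fit <- fit_pcm(m)
    io <- infit_outfit(fit, m)
    stats_arr[r, , 1] <- io$infit
    stats_arr[r, , 2] <- io$outfit
  }
  med <- apply(stats_arr, c(2, 3), stats::median)
  expect_true(all(med >= 0.9 & med <= 1.1))
})

test_that("noise inflates outfit past 1.7 and determinism deflates infit below 0.5", {
  # uniform-noise item in the 6-item scale
  m <- recovery_matrix(n = 2000L, seed = 42)
  set.seed(12)
  mn <- m
  mn$values[, 3] <- sample(0:4, nrow(m$values), TRUE)
  fn <- fit_pcm(mn)
  ion <- infit_outfit(fn, mn)
  expect_gt(ion$outfit[3], 1.7)
  expect_true(ion$flagged[3])
  expect_false(any(ion$flagged[-3]))

  # deterministic (Guttman) item inside a longer scale: the sharper trait
  # posterior exposes the missing response noise
  centers <- seq(-0.9, 0.9, length.out = 12)
  delta12 <- lapply(centers, function(c0) c0 + c(-1, -0.35, 0.35, 1))
  names(delta12) <- paste0("it", 1:12)
  mg <- simulate_responses(sim_spec(2000L, delta12, seed = 42))
  th <- attr(mg, "theta")
  mg$values[, 12] <- as.integer(cut(th, c(-Inf, delta12[[12]], Inf))) - 1L
  fg <- fit_pcm(mg)
  iog <- infit_outfit(fg, mg)
  expect_lt(iog$infit[12], 0.5)
  expect_true(iog$flagged[12])
})

test_that("sum-score chi-square calibrates to its nominal level", {
  delta <- recovery_delta()
  rej <- logical(0)
  for (r in 1:120) {
    m <- simulate_responses(sim_spec(500L, delta, seed = 91000 + r))
    fit <- fit_pcm(m)
    chi <- suppressWarnings(item_chisq(fit, m))
    rej <- c(rej, chi$p < 0.05)
  }
  rate <- mean(rej, na.rm = TRUE)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})

test_that("sum-score chi-square detects a steep non-Rasch item", {
  delta <- recovery_delta()
  set.seed(61)
  th <- stats::rnorm(2000)
  vals <- draw_pcm(th, delta)
  # item 3 generated with slope 2.5 (generalized partial credit shape)
  a <- 2.5
  d3 <- delta[[3]]
  cum <- c(0, cumsum(d3))
  lognum <- outer(a * th, 0:4) - matrix(a * cum, 2000, 5, byrow = TRUE)
  p <- exp(lognum - apply(lognum, 1, max))
  p <- p / rowSums(p)
  cump <- t(apply(p, 1, cumsum))
  vals[, 3] <- as.integer(rowSums(stats::runif(2000) > cump))
  m <- response_matrix(vals, item_ids = names(delta),
                       n_categories = rep(5, 6))
  fit <- fit_pcm(m)
  chi <- item_chisq(fit, m)
  expect_lt(chi$p[3], 0.01)
})

test_that("Q3 flags injected dependence and nothing else", {
  delta <- recovery_delta()
  base <- sim_spec(2000L, delta, seed = 67)

  # locally independent: all pairwise Q3 at or below 0.2
  m0 <- simulate_responses(base)
  f0 <- fit_pcm(m0)
  q0 <- q3_matrix(standardized_residuals(f0, m0, eap_scores(f0, m0)))
  expect_true(all(q0$Q3[upper.tri(q0$Q3)] <= 0.2))
  expect_equal(nrow(q0$flagged), 0L)
  expect_equal(q0$Q3, t(q0$Q3))

  # a testlet pair is flagged, all other pairs stay below threshold
  m1 <- simulate_responses(inject_ld(base, c("DASH2", "DASH5"), 1.5))
  f1 <- fit_pcm(m1)
  q1 <- q3_matrix(standardized_residuals(f1, m1, eap_scores(f1, m1)))
  expect_equal(nrow(q1$flagged), 1L)
  expect_setequal(c(q1$flagged$item_i, q1$flagged$item_j), c("DASH2", "DASH5"))

  # a very strong testlet dominates every other pair by a wide margin
  m2 <- simulate_responses(inject_ld(base, c("DASH2", "DASH5"), 3))
  f2 <- fit_pcm(m2)
  q2 <- q3_matrix(standardized_residuals(f2, m2, eap_scores(f2, m2)))
  pair_q3 <- q2$Q3["DASH2", "DASH5"]
  others <- q2$Q3[upper.tri(q2$Q3)]
  others <- others[others != pair_q3]
  expect_gte(pair_q3 - max(others), 0.2)

  # orthogonal residual columns give exactly zero
  res <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(q3_matrix(res)$Q3["a", "b"], 0)
})

test_that("cronbach alpha matches the closed form and its limits", {
  # var 1, var 1, cov 0.5 -> alpha = 2/3
  m <- toy_matrix(cbind(c(1L, 2L, 3L), c(1L, 3L, 2L)))
  expect_equal(cronbach_alpha(m), 2 / 3, ignore_attr = TRUE)

  x <- c(0L, 2L, 1L, 4L, 3L, 2L)
  ident <- toy_matrix(cbind(x, x, x))
  expect_equal(cronbach_alpha(ident), 1, ignore_attr = TRUE)
  expect_equal(attr(cronbach_alpha(ident), "flag"), "redundant")

  set.seed(71)
  indep <- toy_matrix(cbind(sample(0:4, 4000, TRUE), sample(0:4, 4000, TRUE),
                            sample(0:4, 4000, TRUE)))
  expect_lt(abs(cronbach_alpha(indep)), 0.08)
  expect_equal(attr(cronbach_alpha(indep), "flag"), "low")
})

test_that("scale indices accept the generating model and reject two dimensions", {
  m <- recovery_matrix(n = 2000L, seed = 42)
  fit <- fit_pcm(m)
  sf <- scale_fit_indices(fit, m)
  expect_lt(sf$rmsea, 0.060)
  expect_gte(sf$cfi, 0.950)
  expect_gte(sf$tli, 0.950)
  expect_lte(sf$srmr, 0.080)
  expect_lte(sf$cfi, 1)
  expect_lte(sf$tli, 1)

  # two independent 3-item traits forced into one scale
  delta <- recovery_delta()
  set.seed(7)
  thA <- stats::rnorm(2000)
  thB <- stats::rnorm(2000)
  vals <- cbind(draw_pcm(thA, delta[1:3]), draw_pcm(thB, delta[4:6]))
  m2 <- response_matrix(vals, item_ids = names(delta),
                        n_categories = rep(5, 6))
  f2 <- fit_pcm(m2)
  sf2 <- scale_fit_indices(f2, m2)
  expect_true(sf2$cfi < 0.950 || sf2$tli < 0.950 ||
                sf2$rmsea >= 0.060 || sf2$srmr > 0.080)
})

test_that("the saturated comparison gives exactly zero chi-square", {
  m <- recovery_matrix(n = 400L, seed = 73)
  fit <- fit_pcm(m)
  blocks <- raschdash:::margin_blocks(fit, m)
  n <- nrow(m$values)
  sat <- raschdash:::li_chisq(blocks$obs,
                              lapply(blocks$obs, function(o) o / sum(o)),
                              n)
  expect_equal(sat$x2, 0)
})

test_that("smoothed option curves track the model and handle edge cases", {
  m <- recovery_matrix(n = 4000L, seed = 79)
  fit <- fit_pcm(m)
  sc <- eap_scores(fit, m)
  oc <- empirical_option_curves(fit, m, sc)
  # compare inside +/- 0.8 logits (within one trait SD): outside it the EAP
  # shrinkage systematically displaces the empirical curves from the model
  central <- abs(oc$theta) <= 0.8
  for (i in seq_along(oc$items)) {
    dev <- abs(oc$items[[i]]$observed[central, ] -
                 oc$items[[i]]$expected[central, ])
    expect_lt(max(dev), 0.05)
  }

  # constant item: flat curve at 1 for its only category
  mc <- m
  mc$values[, 2] <- 1L
  occ <- empirical_option_curves(fit, mc, sc)
  expect_equal(occ$items[[2]]$observed[, 2], rep(1, length(occ$theta)))

  # degenerate trait estimates cannot be smoothed
  expect_error(
    empirical_option_curves(fit, m, data.frame(eap = rep(0, nrow(m$values)))),
    "identical")
})

test_that("the item-person map summarizes targeting faithfully", {
  # well-targeted: gap near zero
  m <- recovery_matrix(n = 2000L, seed = 83)
  fit <- fit_pcm(m)
  ipm <- item_person_map(fit, eap_scores(fit, m), m)
  expect_lt(abs(ipm$targeting_gap), 0.1)

  # dupuytren-like cohort: negative skew, thresholds above the person mean
  dup <- simulate_responses(cohort_spec("dupuytren_tasks", seed = 89))
  fd <- fit_pcm(dup)
  ipd <- item_person_map(fd, eap_scores(fd, dup), dup)
  expect_lt(ipd$skewness, 0)
  expect_gt(ipd$threshold_mean, ipd$person_mean)
  expect_lt(ipd$targeting_gap, -0.5)

  # a single person occupies a single histogram bin
  one <- response_matrix(matrix(2L, 1, 6), item_ids = names(recovery_delta()),
                         n_categories = rep(5, 6))
  ip1 <- item_person_map(fit, eap_scores(fit, one), one)
  expect_equal(sum(ip1$hist_counts > 0), 1L)
})
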