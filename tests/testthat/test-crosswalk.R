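test_that("sum-score distributions match exhaustive enumeration", {
  # two fair dichotomous items at theta = 0: binomial(2, 1/2)
  fit <- pcm_model(list(a = 0, b = 0))
  expect_equal(as.numeric(sum_score_distribution(fit, 0)),
               c(0.25, 0.5, 0.25), tolerance = 1e-12)

  # 3 items x 3 categories at theta = 0.7 vs all 27 patterns
  delta <- list(a = c(-0.8, 0.2), b = c(-0.1, 0.9), c = c(-1.2, 0.4))
  fit3 <- pcm_model(delta)
  expect_equal(as.numeric(sum_score_distribution(fit3, 0.7)),
               oracle_sum_dist(delta, 0.7), tolerance = 1e-12)

  # every toy instance with <= 4 items x <= 4 categories, several thetas
  set.seed(43)
  for (rep in 1:6) {
    n_items <- sample(2:4, 1)
    delta_r <- lapply(seq_len(n_items),
                      function(i) sort(stats::rnorm(sample(1:3, 1), 0, 1.2)))
    names(delta_r) <- paste0("i", seq_len(n_items))
    fit_r <- pcm_model(delta_r)
    for (th in c(-1.3, 0, 0.8)) {
      expect_equal(as.numeric(sum_score_distribution(fit_r, th)),
                   oracle_sum_dist(delta_r, th), tolerance = 1e-12)
    }
  }

  # conservation across theta
  ss <- sum_score_distribution(fit3, seq(-5, 5, by = 0.5))
  expect_equal(rowSums(ss), rep(1, nrow(ss)), tolerance = 1e-12)
})

test_that("crosswalk endpoints, monotonicity, symmetry, and EAP oracle", {
  delta <- recovery_delta()
  fit <- pcm_model(delta, prior_sd = 1)
  xw <- build_crosswalk(fit, condition = "cts", subscale = "tasks")
  expect_equal(xw$rasch_score[1], 0L)
  expect_equal(xw$rasch_score[nrow(xw)], 100L)
  expect_equal(xw$raw_score, 6:30)
  expect_true(all(diff(xw$theta_eap) > 0))
  expect_true(all(diff(xw$rasch_score) > 0))

  # mirror-symmetric items: unrounded scale antisymmetric about the middle
  sym <- pcm_model(list(a = c(-1.5, -0.5, 0.5, 1.5), b = c(-1, 0, 1) - 0,
                        c = c(-1.5, -0.5, 0.5, 1.5)), prior_sd = 1)
  xs <- build_crosswalk(sym)
  expect_equal(xs$theta_eap + rev(xs$theta_eap), rep(0, nrow(xs)),
               tolerance = 1e-10)
  unrounded <- 100 * (xs$theta_eap - xs$theta_eap[1]) /
    (xs$theta_eap[nrow(xs)] - xs$theta_eap[1])
  expect_equal(unrounded + rev(unrounded), rep(100, nrow(xs)),
               tolerance = 1e-8)

  # 2-item fit: sum-conditional EAP equals fine-grid integration
  delta2 <- list(a = c(-0.7, 0.4), b = c(-1.1, 0.2, 0.9))
  fit2 <- pcm_model(delta2, prior_sd = 1)
  xw2 <- build_crosswalk(fit2)
  th <- seq(-6, 6, length.out = 4001)
  w <- stats::dnorm(th)
  for (s in 0:5) {
    lik <- oracle_sum_lik <- vapply(th, function(t) {
      oracle_sum_dist(delta2, t)[s + 1]
    }, numeric(1))
    expect_equal(xw2$theta_eap[s + 1], sum(th * w * lik) / sum(w * lik),
                 tolerance = 1e-3)
  }
})

test_that("pattern scoring and sum-score crosswalk give identical EAPs", {
  delta <- list(a = c(-1, 0.2), b = c(-0.3, 1), c = c(0, 0.7))
  gen <- pcm_model(delta, prior_sd = 1)
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  m <- response_matrix(pats, item_ids = names(delta), n_categories = rep(3, 3))
  eap_pat <- eap_scores(gen, m)$eap
  xw <- build_crosswalk(gen)
  eap_sum <- xw$theta_eap[match(rowSums(pats) + 3, xw$raw_score)]
  expect_equal(eap_pat, eap_sum, tolerance = 1e-10)
})

test_that("fitted crosswalks are stable across seeds and close to truth", {
  delta <- recovery_delta()
  xw_gen <- build_crosswalk(pcm_model(delta, prior_sd = 1))
  xw_a <- build_crosswalk(fit_pcm(recovery_matrix(2000L, seed = 101)))
  xw_b <- build_crosswalk(fit_pcm(recovery_matrix(2000L, seed = 202)))
  expect_lte(max(abs(xw_a$rasch_score - xw_gen$rasch_score)), 2)
  expect_lte(max(abs(xw_a$rasch_score - xw_b$rasch_score)), 2)
})

test_that("apply_conversion looks up exactly and guards range and labels", {
  tabs <- load_published_tables(condition = "cts")
  cts_tasks <- tabs$cts_tasks
  expect_equal(apply_conversion(8, cts_tasks), 16L)   # the worked example
  expect_equal(apply_conversion(c(6, 30), cts_tasks), c(0L, 100L))
  expect_error(apply_conversion(31, cts_tasks), "outside the attainable range")
  expect_error(apply_conversion(8, cts_tasks, condition = "dupuytren"),
               "not interchangeable")

  dup_tasks <- load_published_tables("dupuytren", "tasks")
  expect_equal(apply_conversion(6, dup_tasks), 0L)
  expect_error(apply_conversion(25, dup_tasks), "25")
})

test_that("the four published tables have the printed shapes and anchors", {
  tabs <- suppressWarnings(load_published_tables())
  expect_named(tabs, c("cts_tasks", "dupuytren_tasks",
                       "cts_symptoms", "dupuytren_symptoms"),
               ignore.order = TRUE)
  expect_equal(nrow(tabs$cts_tasks), 25)        # raw 6..30
  expect_equal(nrow(tabs$dupuytren_tasks), 19)  # raw 6..24
  expect_equal(tabs$cts_symptoms$raw_score, 3:11)
  expect_equal(tabs$dupuytren_symptoms$raw_score, 3:12)
  for (tb in tabs) {
    expect_equal(tb$rasch_score[1], 0L)
    expect_equal(tb$rasch_score[nrow(tb)], 100L)
    expect_true(all(diff(tb$rasch_score) > 0))
    expect_equal(attr(tb, "provenance"), "published")
  }
  expect_warning(load_published_tables("dupuytren", "symptoms"),
                 "not recommended")
})

test_that("conversion tables survive a CSV round trip", {
  xw <- build_crosswalk(pcm_model(recovery_delta()), condition = "cts",
                        subscale = "tasks")
  path <- file.path(withr::local_tempdir(), "xw.csv")
  write_conversion_table(xw, path)
  back <- read_conversion_table(path)
  expect_equal(back$rasch_score, xw$rasch_score)
  expect_equal(back$theta_eap, xw$theta_eap, tolerance = 1e-9)
  expect_equal(attr(back, "condition"), "cts")
  expect_equal(attr(back, "provenance"), "fitted")
})
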