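# Model mean and variance of each item score at given theta values.
pcm_item_moments <- function(theta, delta) {
  p <- category_probs(theta, delta)
  k <- seq_len(ncol(p)) - 1
  mean <- as.numeric(p %*% k)
  var <- as.numeric(p %*% k^2) - mean^2
  list(mean = mean, var = var)
}

#' Standardized response residuals
#'
#' `z_ni = (x_ni - E_ni) / sqrt(W_ni)` with `E` and `W` the model mean and
#' variance of item `i`'s score at the person's trait estimate. The
#' substrate for infit/outfit and Yen's Q3.
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()] scored.
#' @param scores person scores from [eap_scores()] on the same fit (a
#'   data.frame with column `eap`).
#' @return Persons x items matrix of standardized residuals; cells with
#'   zero model variance are `NA` with a warning.
#' @export
standardized_residuals <- function(fit, m, scores) {
  theta <- scores$eap
  z <- matrix(NA_real_, nrow(m$values), length(fit$item_ids),
              dimnames = list(NULL, fit$item_ids))
  degenerate <- FALSE
  for (i in seq_along(fit$item_ids)) {
    mom <- pcm_item_moments(theta, fit$delta[[i]])
    ok <- mom$var > 0
    degenerate <- degenerate || any(!ok)
    z[ok, i] <- (m$values[ok, i] - mom$mean[ok]) / sqrt(mom$var[ok])
  }
  if (degenerate) {
    warning("residuals with zero model variance excluded", call. = FALSE)
  }
  z
}

#' Infit and outfit mean squares
#'
#' Outfit is the unweighted mean of squared standardized residuals per
#' item; infit is the information-weighted version
#' `sum (x - E)^2 / sum W`. Both are evaluated in posterior expectation:
#' each person's squared residual is integrated over their latent-trait
#' posterior (the EM quadrature weights) rather than plugged in at a point
#' estimate. This keeps the mean squares calibrated near 1 under the model
#' — point-estimate plug-in versions are attenuated well below 1 on short
#' scales because the trait estimate absorbs part of each item's own
#' variation. Values outside the acceptance band (default 0.5-1.7) are
#' flagged: high outfit indicates noisy misfit, low infit indicates
#' overdetermined (near-deterministic) responses.
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()].
#' @param band acceptance band for the mean squares.
#' @return `data.frame` with columns `item`, `outfit`, `infit`, `flagged`.
#' @export
infit_outfit <- function(fit, m, band = c(0.5, 1.7)) {
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  logL <- pcm_pattern_loglik(m$values, fit$delta, nodes)
  A <- sweep(logL, 2, log(w), "+")
  post <- exp(A - row_logsumexp(A))
  out <- lapply(seq_along(fit$item_ids), function(i) {
    mom <- pcm_item_moments(nodes, fit$delta[[i]])
    R2 <- (outer(m$values[, i], mom$mean, "-"))^2      # n x Q
    outfit <- mean(rowSums(post * sweep(R2, 2, mom$var, "/")))
    infit <- sum(rowSums(post * R2)) /
      sum(rowSums(post * matrix(mom$var, nrow(post), length(nodes), byrow = TRUE)))
    data.frame(item = fit$item_ids[i], outfit = outfit, infit = infit)
  })
  out <- do.call(rbind, out)
  out$flagged <- out$outfit <= band[1] | out$outfit >= band[2] |
    out$infit <= band[1] | out$infit >= band[2]
  attr(out, "band") <- band
  out
}

#' Sum-score based item chi-square (Orlando-Thissen style)
#'
#' Per item, observed category frequencies within each total-score group
#' are compared with the model-implied conditional frequencies
#' `P(X_i = k | S = s)` obtained from the Lord-Wingersky distribution of
#' the remaining items. Deterministic extreme sums are excluded, sparse
#' adjacent cells (expected < `min_expected`) are pooled within score
#' groups, rows reduced to a single cell are dropped, and the statistic is
#' `sum (O - E)^2 / E` with `df = sum_s (cells_s - 1) - (categories - 1)`.
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()].
#' @param min_expected pooling threshold for expected cell counts.
#' @return `data.frame` with columns `item`, `chisq`, `df`, `p`. Items with
#'   no usable cells report `NA` with a warning.
#' @export
item_chisq <- function(fit, m, min_expected = 5) {
  X <- m$values
  n <- nrow(X)
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  S <- rowSums(X)
  s_max <- sum(fit$n_categories - 1L)
  out <- lapply(seq_along(fit$item_ids), function(i) {
    K <- fit$n_categories[i]
    P_i <- category_probs(nodes, fit$delta[[i]])          # Q x K
    P_rest <- lw_recursion(fit$delta[-i], nodes)           # Q x (s_max-K+2)
    rest_max <- ncol(P_rest) - 1L
    # joint[s+1, k+1] = integral P_i(k) P_rest(s-k) dG(theta)
    joint <- matrix(0, s_max + 1L, K)
    for (k in seq_len(K) - 1L) {
      contrib <- colSums(w * P_i[, k + 1L] * P_rest)       # over rest sums
      joint[k + seq_len(rest_max + 1L), k + 1L] <-
        joint[k + seq_len(rest_max + 1L), k + 1L] + contrib
    }
    chisq <- 0
    df <- 0L
    for (s in seq_len(s_max - 1L)) {                       # exclude 0 and max
      ns <- sum(S == s)
      if (ns == 0) next
      ks <- which(joint[s + 1L, ] > 0) - 1L                # attainable cats
      if (length(ks) < 2) next
      p_cond <- joint[s + 1L, ks + 1L] / sum(joint[s + 1L, ks + 1L])
      obs <- vapply(ks, function(k) sum(S == s & X[, i] == k), numeric(1))
      exp_ <- ns * p_cond
      # pool adjacent sparse cells left to right
      grp <- integer(length(exp_))
      g <- 1L
      acc <- 0
      for (j in seq_along(exp_)) {
        grp[j] <- g
        acc <- acc + exp_[j]
        if (acc >= min_expected && j < length(exp_)) {
          g <- g + 1L
          acc <- 0
        }
      }
      if (acc < min_expected && g > 1L) grp[grp == g] <- g - 1L
      O <- tapply(obs, grp, sum)
      E <- tapply(exp_, grp, sum)
      if (length(O) < 2) next
      chisq <- chisq + sum((O - E)^2 / E)
      df <- df + length(O) - 1L
    }
    df <- df - (K - 1L)
    if (df < 1L) {
      warning(sprintf("item %s: too few cells after pooling; chi-square undefined",
                      fit$item_ids[i]), call. = FALSE)
      data.frame(item = fit$item_ids[i], chisq = NA_real_, df = NA_integer_,
                 p = NA_real_)
    } else {
      data.frame(item = fit$item_ids[i], chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE))
    }
  })
  do.call(rbind, out)
}

#' Yen's Q3 local dependence matrix
#'
#' Pearson correlations of the standardized residual columns for every
#' item pair; values above the threshold (default 0.2) indicate local
#' dependence.
#'
#' @param residuals persons x items residual matrix from
#'   [standardized_residuals()].
#' @param threshold flagging cutoff.
#' @return An object of class `ld_result`: the symmetric `Q3` matrix
#'   (diagonal `NA`), the threshold, and a data.frame of `flagged` pairs.
#' @export
q3_matrix <- function(residuals, threshold = 0.2) {
  Q3 <- stats::cor(residuals, use = "pairwise.complete.obs")
  diag(Q3) <- NA_real_
  idx <- which(upper.tri(Q3) & Q3 > threshold, arr.ind = TRUE)
  flagged <- data.frame(item_i = colnames(Q3)[idx[, 1]],
                        item_j = colnames(Q3)[idx[, 2]],
                        q3 = Q3[idx])
  structure(list(Q3 = Q3, threshold = threshold, flagged = flagged),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> Q3 threshold %.2f\n", x$threshold))
  if (nrow(x$flagged)) {
    print(x$flagged, row.names = FALSE, digits = 3)
  } else {
    cat("  no locally dependent pairs\n")
  }
  invisible(x)
}

#' Cronbach alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of total)`.
#' Values of 0.7 or less suggest inadequate internal consistency; 0.95 or
#' more can indicate item redundancy (both reported via the `flag`
#' attribute).
#'
#' @param m a [response_matrix()] with at least 2 items.
#' @return The coefficient, with attribute `flag` one of `"ok"`, `"low"`,
#'   `"redundant"`.
#' @export
cronbach_alpha <- function(m) {
  X <- m$values
  k <- ncol(X)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) {
    warning("zero total-score variance; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  a <- k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / total_var)
  attr(a, "flag") <- if (a <= 0.7) "low" else if (a >= 0.95) "redundant" else "ok"
  a
}

# Pearson X^2 over one margin table with left-to-right pooling of sparse
# cells. Returns NULL when fewer than 2 pooled cells remain.
pooled_pearson <- function(obs, exp_prob, n, min_expected = 5) {
  keep <- exp_prob > 0 | obs > 0
  obs <- obs[keep]
  exp_ <- n * exp_prob[keep] / sum(exp_prob[keep])
  if (length(obs) < 2) return(NULL)
  grp <- integer(length(exp_))
  g <- 1L
  acc <- 0
  for (j in seq_along(exp_)) {
    grp[j] <- g
    acc <- acc + exp_[j]
    if (acc >= min_expected && j < length(exp_)) {
      g <- g + 1L
      acc <- 0
    }
  }
  if (acc < min_expected && g > 1L) grp[grp == g] <- g - 1L
  O <- tapply(obs, grp, sum)
  E <- tapply(exp_, grp, sum)
  if (length(O) < 2) return(NULL)
  list(x2 = sum((O - E)^2 / E), cells = length(O))
}

# Limited-information chi-square from univariate and bivariate margins:
# block-diagonal multinomial weighting reduces to summed Pearson X^2 over
# the margin tables (with sparse-cell pooling), so no weight-matrix
# inversion is involved.
li_chisq <- function(obs_blocks, exp_blocks, n, min_expected = 5) {
  x2 <- 0
  cells <- 0L
  blocks <- 0L
  for (b in seq_along(obs_blocks)) {
    pp <- pooled_pearson(obs_blocks[[b]], exp_blocks[[b]], n, min_expected)
    if (is.null(pp)) next
    x2 <- x2 + pp$x2
    cells <- cells + pp$cells
    blocks <- blocks + 1L
  }
  list(x2 = x2, cells = cells, blocks = blocks)
}

# Univariate and bivariate observed counts and model-implied probabilities.
margin_blocks <- function(fit, m) {
  X <- m$values
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  K <- fit$n_categories
  P <- lapply(seq_along(K), function(i) category_probs(nodes, fit$delta[[i]]))
  obs_uni <- lapply(seq_along(K), function(i) tabulate(X[, i] + 1L, K[i]))
  exp_uni <- lapply(seq_along(K), function(i) as.numeric(w %*% P[[i]]))
  pairs <- utils::combn(seq_along(K), 2, simplify = FALSE)
  obs_bi <- lapply(pairs, function(pr) {
    as.vector(table(factor(X[, pr[1]], 0:(K[pr[1]] - 1)),
                    factor(X[, pr[2]], 0:(K[pr[2]] - 1))))
  })
  exp_bi <- lapply(pairs, function(pr) {
    as.vector(crossprod(P[[pr[1]]] * w, P[[pr[2]]]))
  })
  list(obs = c(obs_uni, obs_bi), exp = c(exp_uni, exp_bi),
       pairs = pairs, P = P, obs_uni = obs_uni)
}

#' Scale-level fit indices
#'
#' A limited-information chi-square built from univariate and bivariate
#' margin residuals (observed vs model-implied category and category-pair
#' proportions, block-diagonal multinomial weighting with sparse-cell
#' pooling), compared against an independence baseline with the observed
#' univariate margins. From the two statistics: RMSEA, CFI, TLI (clamped to
#' at most 1), and SRMR as the root-mean-square difference between observed
#' and model-implied inter-item Pearson correlations. The construction
#' carries no correction for parameter estimation and is conservative for
#' the absolute chi-square; the derived indices are the quantities
#' interpreted against the acceptance rules (chi-square p > 0.05,
#' CFI >= 0.950, TLI >= 0.950, RMSEA < 0.060, SRMR <= 0.080).
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()].
#' @param min_expected pooling threshold for expected counts.
#' @return An object of class `scale_fit` with fields `chisq`, `df`, `p`,
#'   `baseline_chisq`, `baseline_df`, `cfi`, `tli`, `rmsea`, `srmr`, `n`,
#'   and the pass/fail `rules`.
#' @export
scale_fit_indices <- function(fit, m, min_expected = 5) {
  n <- nrow(m$values)
  blocks <- margin_blocks(fit, m)
  K <- fit$n_categories
  npar <- sum(K - 1L) + as.integer(isTRUE(fit$estimate_prior_sd))

  mod <- li_chisq(blocks$obs, blocks$exp, n, min_expected)
  df_m <- mod$cells - mod$blocks - npar

  base_exp <- c(
    lapply(blocks$obs_uni, function(o) o / sum(o)),
    lapply(seq_along(blocks$pairs), function(j) {
      pr <- blocks$pairs[[j]]
      as.vector(outer(blocks$obs_uni[[pr[1]]] / n, blocks$obs_uni[[pr[2]]] / n))
    })
  )
  base <- li_chisq(blocks$obs, base_exp, n, min_expected)
  df_b <- base$cells - base$blocks - sum(K - 1L)

  rmsea <- if (df_m > 0) sqrt(max(0, (mod$x2 - df_m) / (df_m * n))) else NA_real_
  num <- max(0, mod$x2 - df_m)
  den <- max(base$x2 - df_b, mod$x2 - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df_b > 0 && df_m > 0 && base$x2 / df_b > 1) {
    min(1, (base$x2 / df_b - mod$x2 / df_m) / (base$x2 / df_b - 1))
  } else {
    1
  }

  # observed vs model-implied inter-item Pearson correlations
  mu <- vapply(seq_along(K), function(i) {
    sum(blocks$exp[[i]] * (seq_len(K[i]) - 1))
  }, numeric(1))
  sd_imp <- vapply(seq_along(K), function(i) {
    sqrt(sum(blocks$exp[[i]] * (seq_len(K[i]) - 1)^2) - mu[i]^2)
  }, numeric(1))
  r_diff <- vapply(seq_along(blocks$pairs), function(j) {
    pr <- blocks$pairs[[j]]
    pj <- matrix(blocks$exp[[length(K) + j]], K[pr[1]], K[pr[2]])
    exy <- sum(outer(seq_len(K[pr[1]]) - 1, seq_len(K[pr[2]]) - 1) * pj)
    r_imp <- (exy - mu[pr[1]] * mu[pr[2]]) / (sd_imp[pr[1]] * sd_imp[pr[2]])
    r_obs <- stats::cor(m$values[, pr[1]], m$values[, pr[2]])
    r_obs - r_imp
  }, numeric(1))
  srmr <- sqrt(mean(r_diff^2))

  p <- if (df_m > 0) stats::pchisq(mod$x2, df_m, lower.tail = FALSE) else NA_real_
  rules <- c(chisq_p = !is.na(p) && p > 0.05,
             cfi = cfi >= 0.950, tli = tli >= 0.950,
             rmsea = !is.na(rmsea) && rmsea < 0.060, srmr = srmr <= 0.080)
  structure(
    list(chisq = mod$x2, df = df_m, p = p,
         baseline_chisq = base$x2, baseline_df = df_b,
         cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr, n = n,
         rules = rules),
    class = "scale_fit"
  )
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("<scale_fit> chisq %.1f (df %d, p %.3g)\n", x$chisq, x$df, x$p))
  cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.3f  SRMR %.3f  (n = %d)\n",
              x$cfi, x$tli, x$rmsea, x$srmr, x$n))
  bad <- names(x$rules)[!x$rules]
  cat(if (length(bad)) paste("  failing rules:", paste(bad, collapse = ", "), "\n")
      else "  all acceptance rules satisfied\n")
  invisible(x)
}

#' Smoothed empirical option curves
#'
#' Kernel-weighted local-linear regression of each response-option
#' indicator on the EAP trait estimates, evaluated on the model's ICC grid
#' so observed and expected curves superimpose — the generalized-additive
#' style diagnostic for item discrimination misfit. Bandwidth defaults to
#' Silverman's rule on the trait estimates with a floor of 0.3 logits.
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()].
#' @param scores person scores from [eap_scores()].
#' @param bandwidth smoothing bandwidth in logits; default Silverman.
#' @return An object of class `option_curves`: `theta` grid, per-item
#'   `observed` and `expected` probability matrices (grid x categories),
#'   and the `bandwidth` used.
#' @export
empirical_option_curves <- function(fit, m, scores, bandwidth = NULL) {
  theta_hat <- scores$eap
  if (stats::var(theta_hat) == 0) {
    stop("all trait estimates identical; cannot smooth", call. = FALSE)
  }
  if (is.null(bandwidth)) {
    bandwidth <- max(0.3, 1.06 * stats::sd(theta_hat) * length(theta_hat)^(-1 / 5))
  }
  grid <- fit$quadrature$nodes
  items <- lapply(seq_along(fit$item_ids), function(i) {
    K <- fit$n_categories[i]
    obs <- vapply(seq_len(K) - 1L, function(k) {
      y <- as.numeric(m$values[, i] == k)
      if (stats::var(y) == 0) {
        rep(y[1], length(grid))
      } else {
        sm <- KernSmooth::locpoly(theta_hat, y, degree = 1,
                                  bandwidth = bandwidth,
                                  range.x = range(grid),
                                  gridsize = length(grid))
        pmin(pmax(sm$y, 0), 1)
      }
    }, numeric(length(grid)))
    list(observed = obs, expected = category_probs(grid, fit$delta[[i]]))
  })
  names(items) <- fit$item_ids
  structure(list(theta = grid, items = items, bandwidth = bandwidth),
            class = "option_curves")
}

# third standardized moment (sample skewness)
sample_skewness <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}

#' Item-person targeting summary
#'
#' Compares the person trait distribution with the item threshold
#' locations: trait histogram, all Andrich thresholds, the targeting gap
#' (mean person trait minus mean threshold), trait skewness, and floor and
#' ceiling percentages (share of persons at the minimum / maximum
#' attainable raw sum).
#'
#' @param fit a `pcm_fit`.
#' @param scores person scores from [eap_scores()].
#' @param m the [response_matrix()] (for the floor/ceiling counts).
#' @return An object of class `item_person_map`.
#' @export
item_person_map <- function(fit, scores, m) {
  theta_hat <- scores$eap
  h <- graphics::hist(theta_hat, breaks = seq(-6, 6, by = 0.25), plot = FALSE)
  thr <- fit$delta
  all_thr <- unlist(thr)
  S <- rowSums(m$values)
  s_max <- sum(fit$n_categories - 1L)
  structure(
    list(hist_mids = h$mids, hist_counts = h$counts,
         thresholds = thr,
         person_mean = mean(theta_hat),
         threshold_mean = mean(all_thr),
         targeting_gap = mean(theta_hat) - mean(all_thr),
         skewness = if (length(theta_hat) > 2 && stats::sd(theta_hat) > 0)
           sample_skewness(theta_hat) else NA_real_,
         floor_pct = 100 * mean(S == 0L),
         ceiling_pct = 100 * mean(S == s_max)),
    class = "item_person_map"
  )
}

#' @export
print.item_person_map <- function(x, ...) {
  cat("<item_person_map>\n")
  cat(sprintf("  person mean %.2f, threshold mean %.2f, gap %.2f logits\n",
              x$person_mean, x$threshold_mean, x$targeting_gap))
  cat(sprintf("  trait skewness %.2f; floor %.1f%%, ceiling %.1f%%\n",
              x$skewness, x$floor_pct, x$ceiling_pct))
  invisible(x)
}
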