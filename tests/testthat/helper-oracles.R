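# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths: covariance maximization by exhaustive
# enumeration of couplings, sum-score distributions by exhaustive pattern
# enumeration, and EAPs by brute-force fine-grid integration.

# Enumerate all integer contingency tables with the margins of (x, y) and
# return the maximum attainable covariance (sample convention, n - 1).
oracle_max_cov <- function(x, y) {
  xv <- sort(unique(x))
  yv <- sort(unique(y))
  rcount <- as.integer(table(factor(x, levels = xv)))
  ccount <- as.integer(table(factor(y, levels = yv)))
  n <- length(x)
  best <- -Inf
  fill_row <- function(i, remaining_cols, acc_xy) {
    if (i > length(rcount)) {
      if (all(remaining_cols == 0)) best <<- max(best, acc_xy)
      return(invisible())
    }
    # all compositions of rcount[i] over the columns, bounded by remaining
    compose <- function(j, left, row_acc) {
      if (j == length(ccount)) {
        if (left <= remaining_cols[j]) {
          remaining_cols[j] <<- remaining_cols[j] - left
          fill_row(i + 1, remaining_cols,
                   acc_xy + row_acc + left * xv[i] * yv[j])
          remaining_cols[j] <<- remaining_cols[j] + left
        }
        return(invisible())
      }
      for (cnt in 0:min(left, remaining_cols[j])) {
        remaining_cols[j] <<- remaining_cols[j] - cnt
        compose(j + 1, left - cnt, row_acc + cnt * xv[i] * yv[j])
        remaining_cols[j] <<- remaining_cols[j] + cnt
      }
    }
    compose(1, rcount[i], 0)
  }
  fill_row(1, ccount, 0)
  (best - n * mean(x) * mean(y)) / (n - 1)
}

oracle_pairwise_H <- function(x, y) {
  stats::cov(x, y) / oracle_max_cov(x, y)
}

# Exhaustive-pattern sum-score distribution for a list of step-difficulty
# vectors at a single theta.
oracle_sum_dist <- function(delta, theta) {
  cats <- lapply(delta, function(d) 0:length(d))
  patterns <- as.matrix(expand.grid(cats))
  probs <- vapply(seq_along(delta), function(i) {
    p <- raschdash::category_probs(theta, delta[[i]])
    p[1, patterns[, i] + 1]
  }, numeric(nrow(patterns)))
  prob <- apply(probs, 1, prod)
  s <- rowSums(patterns)
  as.numeric(tapply(prob, factor(s, levels = 0:max(s)), sum))
}

# Fine-grid EAP for one response pattern under known parameters.
oracle_eap <- function(pattern, delta, prior_sd = 1, n_points = 4001L,
                       range = c(-6, 6)) {
  th <- seq(range[1], range[2], length.out = n_points)
  w <- stats::dnorm(th, 0, prior_sd)
  lik <- rep(1, n_points)
  for (i in seq_along(delta)) {
    p <- raschdash::category_probs(th, delta[[i]])
    lik <- lik * p[, pattern[i] + 1]
  }
  sum(th * w * lik) / sum(w * lik)
}

# Draw responses from a PCM at fixed theta values (independent of the
# package's simulator).
draw_pcm <- function(theta, delta) {
  vapply(seq_along(delta), function(i) {
    p <- raschdash::category_probs(theta, delta[[i]])
    cum <- t(apply(p, 1, cumsum))
    as.integer(rowSums(stats::runif(length(theta)) > cum))
  }, integer(length(theta)))
}
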