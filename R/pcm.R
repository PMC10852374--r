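#' Partial credit model category probabilities
#'
#' For an item with step difficulties `delta` (logits, one per step; the
#' zeroth step is fixed at 0 by convention), the probability of category
#' `k` at trait value `theta` is
#' `P(X = k | theta) = exp(k*theta - sum_{j<=k} delta_j) / Z(theta)`.
#' Computed with log-sum-exp stabilization.
#'
#' @param theta numeric vector of trait values (logits).
#' @param delta numeric vector of step difficulties, length = categories - 1.
#' @return Matrix `length(theta) x (length(delta) + 1)` of category
#'   probabilities; rows sum to 1.
#' @export
category_probs <- function(theta, delta) {
  stopifnot(all(is.finite(theta)), all(is.finite(delta)))
  cum <- c(0, cumsum(delta))
  k <- seq_along(cum) - 1
  lognum <- outer(theta, k) - matrix(cum, length(theta), length(cum), byrow = TRUE)
  mx <- lognum[, 1]
  for (j in seq_along(cum)[-1]) mx <- pmax(mx, lognum[, j])
  p <- exp(lognum - mx)
  p / rowSums(p)
}

# column-wise reverse cumulative sums (survivor sums) of a K x Q matrix
rev_cumsum_cols <- function(M) {
  K <- nrow(M)
  if (K > 1) for (k in (K - 1):1) M[k, ] <- M[k, ] + M[k + 1, ]
  M
}

# Quadrature grid: equally spaced nodes with renormalized normal weights.
pcm_quadrature <- function(n_points = 61L, range = c(-6, 6), prior_sd = 1) {
  nodes <- seq(range[1], range[2], length.out = n_points)
  w <- stats::dnorm(nodes, 0, prior_sd)
  list(nodes = nodes, weights = w / sum(w))
}

row_logsumexp <- function(A) {
  mx <- A[, 1]
  for (j in seq_len(ncol(A))[-1]) mx <- pmax(mx, A[, j])
  mx + log(rowSums(exp(A - mx)))
}

# Per-person log-likelihood on the grid: n x Q matrix of sum_i log P_i(x_ni).
pcm_pattern_loglik <- function(X, delta, nodes) {
  n <- nrow(X)
  logL <- matrix(0, n, length(nodes))
  for (i in seq_len(ncol(X))) {
    lp <- log(category_probs(nodes, delta[[i]]))   # Q x K
    logL <- logL + t(lp)[X[, i] + 1L, , drop = FALSE]
  }
  logL
}

#' Marginal log-likelihood of a PCM at given parameters
#'
#' Useful for comparing a fitted solution with the generating parameters on
#' the same data.
#'
#' @param m a [response_matrix()].
#' @param delta list of step-difficulty vectors, one per item.
#' @param prior_sd standard deviation of the normal latent prior.
#' @param quadrature_points,quadrature_range grid settings.
#' @return The marginal log-likelihood (sum over persons).
#' @export
pcm_marginal_loglik <- function(m, delta, prior_sd = 1,
                                quadrature_points = 61L,
                                quadrature_range = c(-6, 6)) {
  quad <- pcm_quadrature(quadrature_points, quadrature_range, prior_sd)
  logL <- pcm_pattern_loglik(m$values, delta, quad$nodes)
  A <- sweep(logL, 2, log(quad$weights), "+")
  sum(row_logsumexp(A))
}

# Newton maximization of one item's expected complete-data log-likelihood.
# counts: K x Q expected category counts at the quadrature nodes.
# Parameterized in eta_k = cumsum(delta)_k, whose gradient/Hessian involve
# only the category survivor probabilities Pr(X >= j | theta_q).
pcm_item_update <- function(delta, counts, nodes, max_iter = 50L, tol = 1e-10) {
  K <- nrow(counts)
  Nq <- colSums(counts)
  n_ge <- rev_cumsum_cols(counts)[-1, , drop = FALSE]
  eta <- cumsum(delta)
  idx <- pmax(row(diag(K - 1)), col(diag(K - 1)))
  for (it in seq_len(max_iter)) {
    P <- t(category_probs(nodes, c(eta[1], diff(eta))))    # K x Q
    S <- rev_cumsum_cols(P)[-1, , drop = FALSE]            # Pr(X >= j | theta_q)
    SN <- S * rep(Nq, each = K - 1)
    grad <- rowSums(SN - n_ge)
    R <- rowSums(SN)
    H <- -(matrix(R[idx], K - 1, K - 1) - tcrossprod(S * rep(sqrt(Nq), each = K - 1)))
    step <- tryCatch(solve(H, grad), error = function(e) grad / diag(H))
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -2), 2)   # damp wild early steps
    eta <- eta - step
    if (max(abs(step)) < tol) break
  }
  c(eta[1], diff(eta))
}

#' Fit the partial credit model by marginal maximum likelihood
#'
#' EM estimation with a normal latent-trait prior, mean fixed at 0 for
#' identification (all step difficulties free). The E-step places posterior
#' person weights on a fixed quadrature grid; the M-step runs per-item
#' Newton updates of the step difficulties and, optionally, updates the
#' prior standard deviation. The marginal log-likelihood is monitored and
#' must not decrease across cycles.
#'
#' @param m a [response_matrix()]; every category of every item must be
#'   observed at least once.
#' @param estimate_prior_sd estimate the prior SD (default) or fix it at
#'   `prior_sd`.
#' @param prior_sd starting (or fixed) prior SD.
#' @param quadrature_points number of equally spaced nodes (default 61).
#' @param quadrature_range node range in logits (default `c(-6, 6)`).
#' @param tol convergence tolerance: maximum absolute parameter change
#'   (logits) between cycles.
#' @param max_cycles maximum EM cycles.
#' @return An object of class `pcm_fit`: step difficulties `delta` (list per
#'   item), `prior_sd`, `loglik`, `loglik_trace`, `n_cycles`, `converged`,
#'   the quadrature spec, and the item metadata.
#' @export
fit_pcm <- function(m, estimate_prior_sd = TRUE, prior_sd = 1,
                    quadrature_points = 61L, quadrature_range = c(-6, 6),
                    tol = 1e-4, max_cycles = 500L) {
  X <- m$values
  n <- nrow(X)
  K <- m$n_categories
  for (i in seq_along(m$item_ids)) {
    tab <- tabulate(X[, i] + 1L, K[i])
    if (any(tab == 0L)) {
      stop(sprintf(
        "item %s has unobserved categor%s (%s); recode/collapse before fitting",
        m$item_ids[i], if (sum(tab == 0) > 1) "ies" else "y",
        paste(which(tab == 0L) - 1L, collapse = ", ")), call. = FALSE)
    }
  }
  # start from adjacent-category log-odds of the marginal frequencies
  delta <- lapply(seq_along(K), function(i) {
    tab <- tabulate(X[, i] + 1L, K[i])
    log(tab[-K[i]]) - log(tab[-1])
  })
  sd_cur <- prior_sd
  nodes <- pcm_quadrature(quadrature_points, quadrature_range, 1)$nodes
  loglik_trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    w <- stats::dnorm(nodes, 0, sd_cur)
    w <- w / sum(w)
    logL <- pcm_pattern_loglik(X, delta, nodes)
    A <- sweep(logL, 2, log(w), "+")
    ll_person <- row_logsumexp(A)
    loglik_trace <- c(loglik_trace, sum(ll_person))
    post <- exp(A - ll_person)                      # rows sum to 1
    new_delta <- vector("list", length(K))
    for (i in seq_along(K)) {
      ind <- matrix(0, n, K[i])
      ind[cbind(seq_len(n), X[, i] + 1L)] <- 1
      counts <- crossprod(ind, post)                # K x Q
      new_delta[[i]] <- pcm_item_update(delta[[i]], counts, nodes)
    }
    new_sd <- if (estimate_prior_sd) {
      max(sqrt(sum(colSums(post) * nodes^2) / n), 0.05)
    } else {
      sd_cur
    }
    if (estimate_prior_sd && new_sd == 0.05 && sd_cur > 0.05) {
      warning("latent variance collapsed toward zero (no common trait?); prior sd floored at 0.05",
              call. = FALSE)
    }
    change <- max(abs(unlist(new_delta) - unlist(delta)), abs(new_sd - sd_cur))
    delta <- new_delta
    sd_cur <- new_sd
    if (change < tol) {
      converged <- TRUE
      break
    }
    if (cycle >= max_cycles) break
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d cycles (last change %.2e)",
                    cycle, change), call. = FALSE)
  }
  names(delta) <- m$item_ids
  w <- stats::dnorm(nodes, 0, sd_cur)
  structure(
    list(delta = delta, prior_mean = 0, prior_sd = sd_cur,
         estimate_prior_sd = estimate_prior_sd,
         loglik = loglik_trace[length(loglik_trace)],
         loglik_trace = loglik_trace,
         n_cycles = cycle, converged = converged,
         quadrature = list(nodes = nodes, weights = w / sum(w)),
         item_ids = m$item_ids, n_categories = K),
    class = "pcm_fit"
  )
}

#' Construct a PCM object from known parameters
#'
#' Builds a `pcm_fit` directly from given step difficulties, e.g. to score
#' new data with a previously calibrated or published item bank, or to
#' evaluate a generating model in simulations.
#'
#' @param delta list of step-difficulty vectors (one per item, named).
#' @param prior_sd latent prior SD.
#' @param quadrature_points,quadrature_range grid settings.
#' @return A `pcm_fit` with `converged = TRUE` and no likelihood record.
#' @export
pcm_model <- function(delta, prior_sd = 1, quadrature_points = 61L,
                      quadrature_range = c(-6, 6)) {
  if (is.null(names(delta))) names(delta) <- paste0("item", seq_along(delta))
  quad <- pcm_quadrature(quadrature_points, quadrature_range, prior_sd)
  structure(
    list(delta = delta, prior_mean = 0, prior_sd = prior_sd,
         estimate_prior_sd = FALSE,
         loglik = NA_real_, loglik_trace = numeric(0),
         n_cycles = 0L, converged = TRUE,
         quadrature = quad,
         item_ids = names(delta),
         n_categories = vapply(delta, length, 1L) + 1L),
    class = "pcm_fit"
  )
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("<pcm_fit> %d items, prior sd %.3f%s\n",
              length(x$delta), x$prior_sd,
              if (x$estimate_prior_sd) " (estimated)" else " (fixed)"))
  if (is.finite(x$loglik)) {
    cat(sprintf("  logLik %.2f after %d EM cycles (%s)\n", x$loglik,
                x$n_cycles, if (x$converged) "converged" else "NOT converged"))
  }
  for (i in seq_along(x$delta)) {
    cat(sprintf("  %-8s %s\n", x$item_ids[i],
                paste(sprintf("% .2f", x$delta[[i]]), collapse = " ")))
  }
  invisible(x)
}

#' Expected a posteriori person scores
#'
#' Posterior mean and SD of the latent trait for every person, integrating
#' the response-pattern likelihood against the fitted normal prior on the
#' quadrature grid.
#'
#' @param fit a `pcm_fit`.
#' @param m the [response_matrix()] to score (items must match the fit).
#' @return `data.frame` with columns `eap` and `se` (posterior SD), in
#'   logits.
#' @export
eap_scores <- function(fit, m) {
  if (!isTRUE(fit$converged)) {
    warning("scoring from a non-converged fit", call. = FALSE)
  }
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  logL <- pcm_pattern_loglik(m$values, fit$delta, nodes)
  A <- sweep(logL, 2, log(w), "+")
  post <- exp(A - row_logsumexp(A))
  eap <- as.numeric(post %*% nodes)
  second <- as.numeric(post %*% nodes^2)
  se <- sqrt(pmax(second - eap^2, 0))
  data.frame(eap = eap, se = se)
}

#' Andrich thresholds with disorder and closeness flags
#'
#' Under the adjacent-category parameterization the step difficulties are
#' the Andrich thresholds: the trait values at which neighbouring category
#' probability curves cross. Thresholds should increase with category
#' severity; a step that fails to do so (`delta_k >= delta_{k+1}`) is
#' disordered, and a gap smaller than `tol` is flagged as close. For each
#' flagged item the recommended merge is the category pair straddling the
#' worst (most negative) gap, ties broken toward the most severe categories.
#'
#' @param fit a `pcm_fit`.
#' @param tol closeness tolerance in logits (default 0.2).
#' @return An object of class `threshold_report`: per item the thresholds,
#'   gaps, disorder/closeness flags and recommended merge pair (0-based
#'   category codes), plus `any_flag`.
#' @export
andrich_thresholds <- function(fit, tol = 0.2) {
  items <- lapply(seq_along(fit$delta), function(i) {
    thr <- fit$delta[[i]]
    gaps <- diff(thr)
    disordered <- gaps <= 0
    close <- gaps > 0 & gaps < tol
    merge <- NULL
    if (length(gaps) && any(disordered | close)) {
      worst <- max(which(gaps == min(gaps)))   # ties -> most severe pair
      merge <- c(worst, worst + 1L)            # 0-based category codes
    }
    list(item = fit$item_ids[i], thresholds = thr, gaps = gaps,
         disordered = disordered, close = close, merge = merge)
  })
  names(items) <- fit$item_ids
  structure(
    list(items = items, tol = tol,
         any_flag = any(vapply(items, function(x) !is.null(x$merge), TRUE))),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> closeness tol %.2f logits\n", x$tol))
  for (it in x$items) {
    flags <- character(0)
    if (any(it$disordered)) {
      flags <- c(flags, sprintf("disordered@%s",
                                paste(which(it$disordered), collapse = ",")))
    }
    if (any(it$close)) {
      flags <- c(flags, sprintf("close@%s", paste(which(it$close), collapse = ",")))
    }
    cat(sprintf("  %-8s %s %s\n", it$item,
                paste(sprintf("% .2f", it$thresholds), collapse = " "),
                if (length(flags)) paste0("[", paste(flags, collapse = "; "), "]") else ""))
  }
  invisible(x)
}

# One-step recode merging categories `pair` = c(k, k+1) (0-based) of `item`.
merge_pair_recode <- function(m, item, pair) {
  maps <- lapply(seq_along(m$item_ids), function(i) {
    codes <- seq.int(0L, m$n_categories[i] - 1L)
    if (m$item_ids[i] == item) {
      ifelse(codes > pair[1], codes - 1L, codes)
    } else {
      codes
    }
  })
  names(maps) <- m$item_ids
  recode_map(maps)
}

#' Data-driven category collapsing
#'
#' Iterates fit -> threshold report -> merge of the single worst flagged
#' category pair (across all items) -> refit, until no disorder or closeness
#' flags remain or every flagged item is down to 2 categories. An iteration
#' guard caps the number of merges at the total number of collapsible steps.
#'
#' @param m a [response_matrix()].
#' @param tol closeness tolerance passed to [andrich_thresholds()].
#' @param fit_args list of arguments for [fit_pcm()] (e.g. `tol`,
#'   `max_cycles`, `estimate_prior_sd`).
#' @return A list: `recode` (cumulative [recode_map()]), `fit` (final
#'   `pcm_fit`), `thresholds` (final [andrich_thresholds()] report), `data`
#'   (recoded matrix), `merges` (data.frame log of the merges applied).
#' @export
auto_collapse <- function(m, tol = 0.2, fit_args = list()) {
  cum_map <- identity_recode(m)
  cur <- m
  merges <- data.frame(item = character(0), cat_low = integer(0),
                       cat_high = integer(0))
  max_merges <- sum(m$n_categories - 2L)
  repeat {
    fit <- do.call(fit_pcm, c(list(m = cur), fit_args))
    rep_ <- andrich_thresholds(fit, tol = tol)
    cand <- Filter(function(it) {
      !is.null(it$merge) && cur$n_categories[match(it$item, cur$item_ids)] > 2L
    }, rep_$items)
    if (length(cand) == 0 || nrow(merges) >= max_merges) break
    worst_gap <- vapply(cand, function(it) min(it$gaps), numeric(1))
    pick <- cand[[which.min(worst_gap)]]
    step <- merge_pair_recode(cur, pick$item, pick$merge)
    cur <- apply_recode(cur, step)
    cum_map <- compose_recode(cum_map, step)
    merges <- rbind(merges, data.frame(item = pick$item,
                                       cat_low = pick$merge[1],
                                       cat_high = pick$merge[2]))
  }
  list(recode = cum_map, fit = fit, thresholds = rep_, data = cur,
       merges = merges)
}

#' Sample the category probability curves of a fit
#'
#' @param fit a `pcm_fit`.
#' @param theta trait grid; defaults to the fit's quadrature nodes.
#' @return Long `data.frame` (item, theta, category, prob), ready for CSV
#'   export or plotting.
#' @export
icc_curves <- function(fit, theta = fit$quadrature$nodes) {
  out <- lapply(seq_along(fit$delta), function(i) {
    p <- category_probs(theta, fit$delta[[i]])
    data.frame(item = fit$item_ids[i],
               theta = rep(theta, ncol(p)),
               category = rep(seq_len(ncol(p)) - 1L, each = length(theta)),
               prob = as.vector(p))
  })
  do.call(rbind, out)
}

#' Serialize a PCM fit to JSON
#' @param fit a `pcm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pcm_fit <- function(fit, path) {
  jsonlite::write_json(
    list(item_ids = fit$item_ids,
         delta = fit$delta,
         prior_mean = fit$prior_mean, prior_sd = fit$prior_sd,
         loglik = fit$loglik, n_cycles = fit$n_cycles,
         converged = fit$converged,
         quadrature = list(n_points = length(fit$quadrature$nodes),
                           range = range(fit$quadrature$nodes))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
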