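#' Loevinger H for one item pair
#'
#' Scalability of a polytomous item pair as the ratio of the observed
#' covariance to the maximum covariance attainable given both marginal
#' frequency distributions. The maximum is reached by the comonotonic
#' coupling (pair the largest values of one margin with the largest of the
#' other), so `cov_max = cov(sort(x), sort(y))`.
#'
#' @param m a [response_matrix()].
#' @param i,j item indices or ids.
#' @return The coefficient `H_ij`, or `NA` with a warning when either item
#'   has zero variance.
#' @export
pairwise_H <- function(m, i, j) {
  x <- m$values[, i]
  y <- m$values[, j]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance item; H undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cov(x, y) / stats::cov(sort(x), sort(y))
}

#' Mokken scalability coefficients for a scale
#'
#' Computes the pairwise coefficient matrix `H_pair`, the per-item
#' coefficients `H_item` (ratio of summed observed to summed maximal
#' covariances over the remaining items), and the scale coefficient
#' `H_scale` (same ratio over all pairs — not the mean of `H_pair`). Items
#' with `H_item` at or below the threshold are flagged; scales screened this
#' way are considered scalable when all coefficients exceed 0.3.
#'
#' @param m a [response_matrix()] with at least 2 items.
#' @param threshold acceptance cutoff for the coefficients (default 0.3).
#' @return An object of class `mokken_result` with fields `H_pair`,
#'   `H_item`, `H_scale`, `threshold`, `flagged`.
#' @export
scale_H <- function(m, threshold = 0.3) {
  k <- length(m$item_ids)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  X <- m$values
  covs <- maxs <- matrix(NA_real_, k, k, dimnames = list(m$item_ids, m$item_ids))
  vars <- apply(X, 2, stats::var)
  if (any(vars == 0)) {
    warning(sprintf("zero-variance item(s): %s",
                    paste(m$item_ids[vars == 0], collapse = ", ")), call. = FALSE)
  }
  sorted <- apply(X, 2, sort)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      covs[i, j] <- covs[j, i] <- stats::cov(X[, i], X[, j])
      maxs[i, j] <- maxs[j, i] <- stats::cov(sorted[, i], sorted[, j])
    }
  }
  H_pair <- covs / maxs
  H_item <- vapply(seq_len(k), function(i) {
    sum(covs[i, -i]) / sum(maxs[i, -i])
  }, numeric(1))
  names(H_item) <- m$item_ids
  upper <- upper.tri(covs)
  H_scale <- sum(covs[upper]) / sum(maxs[upper])
  structure(
    list(H_pair = H_pair, H_item = H_item, H_scale = H_scale,
         threshold = threshold,
         flagged = m$item_ids[!is.na(H_item) & H_item <= threshold]),
    class = "mokken_result"
  )
}

#' @export
print.mokken_result <- function(x, ...) {
  cat(sprintf("<mokken_result> H_scale = %.3f (threshold %.2f)\n",
              x$H_scale, x$threshold))
  cat("  H_item:\n")
  print(round(x$H_item, 3))
  if (length(x$flagged)) {
    cat("  flagged (H <= threshold):", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  all items above threshold\n")
  }
  invisible(x)
}
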