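# Lord-Wingersky recursion over the items of a PCM: distribution of the
# internal (0-based) sum score at each theta.
lw_recursion <- function(delta, theta) {
  f <- matrix(1, length(theta), 1)
  for (d in delta) {
    P <- category_probs(theta, d)                 # Q x K
    K <- ncol(P)
    old_max <- ncol(f) - 1L
    g <- matrix(0, length(theta), old_max + K)
    for (k in seq_len(K) - 1L) {
      cols <- (k + 0:old_max) + 1L
      g[, cols] <- g[, cols] + f * P[, k + 1L]
    }
    f <- g
  }
  f
}

#' Model-implied sum-score distribution
#'
#' Probability of each attainable internal sum score at a given trait value,
#' computed by the Lord-Wingersky recursion (fold the items in one at a
#' time by shifted multiplication).
#'
#' @param fit a `pcm_fit`.
#' @param theta trait value(s), logits.
#' @return Matrix `length(theta) x (max sum + 1)`; each row sums to 1.
#'   Column `s + 1` is `P(S = s | theta)` for the internal 0-based sum `s`.
#' @export
sum_score_distribution <- function(fit, theta) {
  lw_recursion(fit$delta, theta)
}

# round half up: the only rounding consistent with integer 0/100 endpoints
round_half_up <- function(x) floor(x + 0.5)

#' Build a raw-sum to 0-100 conversion table
#'
#' For every attainable raw sum `s`, the expected a posteriori trait
#' `EAP(theta | S = s)` is computed on the quadrature grid via the
#' Lord-Wingersky sum-score likelihood, then rescaled linearly so the
#' minimum sum maps to 0 and the maximum to 100, and rounded half-up to
#' integers. Raw sums are reported on the questionnaire scale (minimum =
#' item count).
#'
#' @param fit a `pcm_fit` over the (possibly recoded) items.
#' @param condition,subscale labels stamped on the table; conversions are
#'   condition-specific and not interchangeable.
#' @return An object of class `conversion_table`: a `data.frame` with
#'   columns `raw_score`, `theta_eap`, `rasch_score` and attributes
#'   `condition`, `subscale`, `provenance = "fitted"`, `n_items`.
#' @export
build_crosswalk <- function(fit, condition = NULL, subscale = NULL) {
  nodes <- fit$quadrature$nodes
  w <- fit$quadrature$weights
  Ps <- lw_recursion(fit$delta, nodes)            # Q x (Smax+1)
  n_sums <- ncol(Ps)
  if (n_sums < 2) stop("degenerate scale: a single attainable sum", call. = FALSE)
  joint <- Ps * w                                  # w recycles down columns
  marg <- colSums(joint)
  eap <- colSums(joint * nodes) / marg
  n_items <- length(fit$delta)
  raw <- seq.int(0L, n_sums - 1L) + n_items
  span <- eap[n_sums] - eap[1]
  score <- round_half_up(100 * (eap - eap[1]) / span)
  tab <- data.frame(raw_score = raw, theta_eap = eap, rasch_score = as.integer(score))
  conversion_table(tab, condition = condition, subscale = subscale,
                   provenance = "fitted", n_items = n_items)
}

#' Conversion table constructor
#'
#' @param tab data.frame with columns `raw_score`, `theta_eap`,
#'   `rasch_score`; raw sums must be contiguous and the rescaled scores
#'   strictly increasing from 0 to 100.
#' @param condition,subscale labels; `provenance` is `"fitted"` or
#'   `"published"`; `n_items` the item count (minimum raw sum).
#' @return The validated `conversion_table`.
#' @export
conversion_table <- function(tab, condition = NULL, subscale = NULL,
                             provenance = c("fitted", "published"),
                             n_items = tab$raw_score[1]) {
  provenance <- match.arg(provenance)
  stopifnot(all(c("raw_score", "theta_eap", "rasch_score") %in% names(tab)))
  if (any(diff(tab$raw_score) != 1L)) {
    stop("raw scores must be contiguous", call. = FALSE)
  }
  if (tab$rasch_score[1] != 0L || tab$rasch_score[nrow(tab)] != 100L) {
    stop("rescaled scores must run from 0 to 100", call. = FALSE)
  }
  if (any(diff(tab$rasch_score) <= 0)) {
    stop("rescaled scores must be strictly increasing", call. = FALSE)
  }
  structure(tab, class = c("conversion_table", "data.frame"),
            condition = condition, subscale = subscale,
            provenance = provenance, n_items = n_items)
}

#' @export
print.conversion_table <- function(x, ...) {
  cat(sprintf("<conversion_table> %s / %s (%s), raw %d..%d\n",
              attr(x, "condition") %||% "?", attr(x, "subscale") %||% "?",
              attr(x, "provenance"),
              x$raw_score[1], x$raw_score[nrow(x)]))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert raw sum scores with a conversion table
#'
#' Exact lookup of each raw questionnaire sum in the table. Scores outside
#' the attainable range raise an error naming the offending value, and when
#' `condition`/`subscale` are supplied they must match the table's labels
#' (the condition-specific conversions are not interchangeable).
#'
#' @param raw integer vector of raw questionnaire sums (post-recode coding).
#' @param table a [conversion_table()].
#' @param condition,subscale optional guard labels.
#' @return Integer vector of 0-100 converted scores.
#' @export
apply_conversion <- function(raw, table, condition = NULL, subscale = NULL) {
  if (!is.null(condition) && !identical(condition, attr(table, "condition"))) {
    stop(sprintf("table is for condition '%s', not '%s'; conversions are not interchangeable",
                 attr(table, "condition"), condition), call. = FALSE)
  }
  if (!is.null(subscale) && !identical(subscale, attr(table, "subscale"))) {
    stop(sprintf("table is for subscale '%s', not '%s'",
                 attr(table, "subscale"), subscale), call. = FALSE)
  }
  idx <- match(raw, table$raw_score)
  if (anyNA(idx)) {
    bad <- raw[is.na(idx)][1]
    stop(sprintf("raw score %s outside the attainable range %d..%d",
                 format(bad), table$raw_score[1], table$raw_score[nrow(table)]),
         call. = FALSE)
  }
  table$rasch_score[idx]
}

#' Write a conversion table as CSV with a JSON header line
#' @param table a [conversion_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  hdr <- jsonlite::toJSON(
    list(condition = attr(table, "condition"),
         subscale = attr(table, "subscale"),
         provenance = attr(table, "provenance"),
         n_items = attr(table, "n_items")),
    auto_unbox = TRUE, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a conversion table written by [write_conversion_table()]
#' @param path CSV path with a leading `# {json}` header line.
#' @return A [conversion_table()].
#' @export
read_conversion_table <- function(path) {
  first <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", first))
  tab <- utils::read.csv(path, comment.char = "#")
  conversion_table(tab, condition = meta$condition, subscale = meta$subscale,
                   provenance = meta$provenance, n_items = meta$n_items)
}

#' Published QuickDASH conversion tables
#'
#' The condition-specific reference tables converting modified raw
#' questionnaire sums to 0-100 interval-level scores: tasks (items 1-6) and
#' symptoms (items 9-11) for carpal tunnel syndrome and Dupuytren disease.
#' The raw sums assume the condition-specific recoding from
#' [quickdash_recode()] has been applied. Loading the Dupuytren symptoms
#' table warns that the symptom subscale is not recommended in Dupuytren
#' disease. Reference logit values are not part of the published tables, so
#' `theta_eap` is `NA`.
#'
#' @param condition,subscale optionally select one table instead of all
#'   four.
#' @return A single [conversion_table()] if both labels are given, else a
#'   named list of the four tables (`cts_tasks`, `dupuytren_tasks`,
#'   `cts_symptoms`, `dupuytren_symptoms`).
#' @export
load_published_tables <- function(condition = NULL, subscale = NULL) {
  dir <- system.file("extdata", package = "raschdash")
  want <- expand.grid(condition = c("cts", "dupuytren"),
                      subscale = c("tasks", "symptoms"),
                      stringsAsFactors = FALSE)
  if (!is.null(condition)) want <- want[want$condition == condition, ]
  if (!is.null(subscale)) want <- want[want$subscale == subscale, ]
  if (nrow(want) == 0) stop("unknown condition/subscale", call. = FALSE)
  tabs <- lapply(seq_len(nrow(want)), function(r) {
    if (want$condition[r] == "dupuytren" && want$subscale[r] == "symptoms") {
      warning("the symptom items (9-11) are not recommended for use in Dupuytren disease",
              call. = FALSE)
    }
    read_conversion_table(file.path(dir, sprintf(
      "conversion_%s_%s.csv", want$condition[r], want$subscale[r])))
  })
  names(tabs) <- paste(want$condition, want$subscale, sep = "_")
  if (nrow(want) == 1) tabs[[1]] else tabs
}
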