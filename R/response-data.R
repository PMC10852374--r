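#' Ordinal response matrix
#'
#' Container for a persons x items table of ordinal category codes, the
#' substrate for every analysis stage in the package. Codes are stored
#' 0-based internally (0 = best response, e.g. "no difficulty"); all
#' questionnaire-facing I/O uses the 1-based Likert coding printed on the
#' instrument.
#'
#' @param values integer matrix, persons in rows, items in columns, codes
#'   `0 .. n_categories[item] - 1` with no missing values.
#' @param item_ids character vector of item labels; defaults to the column
#'   names of `values`.
#' @param n_categories integer vector, number of scoring categories per item
#'   (after any recode). Defaults to `max(code) + 1` per item, but should be
#'   given explicitly when a category may be unobserved.
#' @param condition optional condition tag, `"dupuytren"` or `"cts"`.
#' @param subscale optional subscale tag, `"tasks"` (items 1-6) or
#'   `"symptoms"` (items 9-11).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, item_ids = colnames(values),
                            n_categories = NULL,
                            condition = NULL, subscale = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(item_ids)) {
    item_ids <- paste0("item", seq_len(ncol(values)))
  }
  if (length(item_ids) != ncol(values)) {
    stop("`item_ids` must name every column of `values`", call. = FALSE)
  }
  colnames(values) <- item_ids
  if (anyNA(values)) {
    stop("response matrix contains missing values; drop incomplete rows first",
         call. = FALSE)
  }
  if (nrow(values) > 0 && any(values < 0L)) {
    stop("internal codes must be >= 0", call. = FALSE)
  }
  if (is.null(n_categories)) {
    n_categories <- apply(values, 2, max) + 1L
  }
  n_categories <- as.integer(rep_len(n_categories, ncol(values)))
  if (any(n_categories < 2L)) {
    stop("every item needs at least 2 scoring categories", call. = FALSE)
  }
  bad <- which(apply(values, 2, max) > n_categories - 1L)
  if (nrow(values) > 0 && length(bad)) {
    stop(sprintf("codes exceed n_categories - 1 for item(s): %s",
                 paste(item_ids[bad], collapse = ", ")), call. = FALSE)
  }
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("dupuytren", "cts"))
  }
  if (!is.null(subscale)) {
    subscale <- match.arg(subscale, c("tasks", "symptoms"))
  }
  structure(
    list(values = values, item_ids = item_ids, n_categories = n_categories,
         condition = condition, subscale = subscale,
         n_dropped = attr(values, "n_dropped")),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items\n",
              nrow(x$values), length(x$item_ids)))
  cat("  items:      ", paste(x$item_ids, collapse = ", "), "\n")
  cat("  categories: ", paste(x$n_categories, collapse = ", "), "\n")
  if (!is.null(x$condition) || !is.null(x$subscale)) {
    cat("  tags:       ", paste(c(x$condition, x$subscale), collapse = " / "), "\n")
  }
  if (!is.null(x$n_dropped)) {
    cat("  dropped incomplete rows:", x$n_dropped, "\n")
  }
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Read questionnaire responses from CSV
#'
#' Reads a person x item CSV with a header row of item ids and cells coded on
#' the 1-based questionnaire scale (QuickDASH: 1 = "no difficulty" ...
#' 5 = "unable"), shifts to the internal 0-based coding, and drops rows with
#' any blank or invalid cell among the requested items (complete-case
#' filtering). The number of dropped rows is reported via the `n_dropped`
#' field and a message.
#'
#' @param path CSV file path.
#' @param items character vector of item ids to keep, in order. Defaults to
#'   all columns.
#' @param n_categories categories per requested item on the questionnaire
#'   scale (default 5, the QuickDASH Likert scale).
#' @param condition,subscale optional tags stored on the result.
#' @param quiet suppress the dropped-row message.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, items = NULL, n_categories = 5L,
                           condition = NULL, subscale = NULL, quiet = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (is.null(items)) items <- colnames(raw)
  missing_items <- setdiff(items, colnames(raw))
  if (length(missing_items)) {
    stop(sprintf("unknown item id(s) in `items`: %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[, items, drop = FALSE]
  n_categories <- as.integer(rep_len(n_categories, length(items)))

  num <- suppressWarnings(
    vapply(seq_along(items), function(j) as.numeric(raw[[j]]), numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw))
  valid <- matrix(TRUE, nrow(raw), length(items))
  for (j in seq_along(items)) {
    v <- num[, j]
    ok <- !is.na(v) & v == round(v) & v >= 1 & v <= n_categories[j]
    out_of_range <- !is.na(v) & (v != round(v) | v < 1 | v > 5)
    if (any(out_of_range)) {
      stop(sprintf("item %s has value(s) outside the 1..5 questionnaire range",
                   items[j]), call. = FALSE)
    }
    valid[, j] <- ok
  }
  keep <- rowSums(valid) == length(items)
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no complete rows remain after filtering", call. = FALSE)
  }
  values <- matrix(as.integer(num[keep, , drop = FALSE] - 1),
                   ncol = length(items), dimnames = list(NULL, items))
  if (n_dropped > 0 && !quiet) {
    message(sprintf("read_responses: dropped %d incomplete row(s)", n_dropped))
  }
  m <- response_matrix(values, item_ids = items, n_categories = n_categories,
                       condition = condition, subscale = subscale)
  m$n_dropped <- n_dropped
  m
}

#' Write responses back to CSV (questionnaire coding)
#'
#' Cells are written 1-based. When a recode map is supplied, a JSON sidecar
#' `<path>.json` records the map and the complete-case drop count so the
#' recoded file is self-describing.
#'
#' @param m a [response_matrix()].
#' @param path output CSV path.
#' @param recode optional [recode_map()] to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_responses <- function(m, path, recode = NULL) {
  out <- as.data.frame(m$values + 1L)
  colnames(out) <- m$item_ids
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(recode)) {
    sidecar <- list(
      recode_map = lapply(recode, function(v) as.integer(v)),
      n_dropped = if (is.null(m$n_dropped)) 0L else m$n_dropped,
      condition = m$condition, subscale = m$subscale
    )
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Order-preserving category recode map
#'
#' A per-item mapping of old 0-based category codes to new ones. Only
#' order-preserving merges are allowed: the mapping must be monotone
#' non-decreasing in the old code and its image must be the contiguous set
#' `0..m'` with no gaps.
#'
#' @param maps named list (one entry per item) of integer vectors `v` with
#'   `v[old_code + 1] = new_code`.
#' @return An object of class `recode_map`.
#' @export
recode_map <- function(maps) {
  for (nm in names(maps)) {
    v <- as.integer(maps[[nm]])
    if (any(diff(v) < 0L)) {
      stop(sprintf("recode for item %s is not monotone non-decreasing", nm),
           call. = FALSE)
    }
    img <- sort(unique(v))
    if (!identical(img, seq.int(0L, max(v)))) {
      stop(sprintf("recode for item %s has a gapped image (must be 0..m')", nm),
           call. = FALSE)
    }
    maps[[nm]] <- v
  }
  structure(maps, class = "recode_map")
}

#' Identity recode for a response matrix
#' @param m a [response_matrix()].
#' @return A [recode_map()] mapping every code to itself.
#' @export
identity_recode <- function(m) {
  maps <- lapply(seq_along(m$item_ids),
                 function(i) seq.int(0L, m$n_categories[i] - 1L))
  names(maps) <- m$item_ids
  recode_map(maps)
}

#' Compose two recode maps (apply `first`, then `second`)
#' @param first,second [recode_map()] objects over the same items;
#'   `second` must be defined on the image of `first`.
#' @return The composed [recode_map()].
#' @export
compose_recode <- function(first, second) {
  maps <- lapply(names(first), function(nm) {
    second[[nm]][first[[nm]] + 1L]
  })
  names(maps) <- names(first)
  recode_map(maps)
}

#' Apply a recode map to a response matrix
#'
#' Category merges only: total response count is unchanged and the frequency
#' of a merged category equals the sum of its source categories.
#'
#' @param m a [response_matrix()].
#' @param r a [recode_map()] covering every item of `m`.
#' @return The recoded [response_matrix()] with updated `n_categories`.
#' @export
apply_recode <- function(m, r) {
  if (!inherits(r, "recode_map")) r <- recode_map(r)
  missing_items <- setdiff(m$item_ids, names(r))
  if (length(missing_items)) {
    stop(sprintf("recode map does not cover item(s): %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  }
  values <- m$values
  n_cat <- m$n_categories
  for (i in seq_along(m$item_ids)) {
    v <- r[[m$item_ids[i]]]
    if (length(v) != m$n_categories[i]) {
      stop(sprintf("recode for item %s has %d entries but the item has %d categories",
                   m$item_ids[i], length(v), m$n_categories[i]), call. = FALSE)
    }
    values[, i] <- v[m$values[, i] + 1L]
    n_cat[i] <- max(v) + 1L
  }
  out <- response_matrix(values, item_ids = m$item_ids, n_categories = n_cat,
                         condition = m$condition, subscale = m$subscale)
  out$n_dropped <- m$n_dropped
  out
}

# Published per-item recode rules on the original 5-category QuickDASH scale.
# merge_worst: "severe difficulty" and "unable" score alike (internal 4 -> 3);
# merge_best: "no difficulty" and "mild difficulty" score alike (internal 1 -> 0).
.qd_merge_worst <- c(0L, 1L, 2L, 3L, 3L)
.qd_merge_best  <- c(0L, 0L, 1L, 2L, 3L)
.qd_merge_both  <- c(0L, 0L, 1L, 2L, 2L)

#' Condition-specific QuickDASH recoding rules
#'
#' Applies the published scoring modifications that make the QuickDASH
#' subscales fit the partial credit model:
#'
#' * **dupuytren / tasks** (items 1-6): the two worst options are merged on
#'   every item — "severe difficulty" and "unable" both receive the
#'   questionnaire score 4.
#' * **cts / tasks**: no modification; item scores are summed as-is.
#' * **cts / symptoms** (items 9-11): items 9 and 10 merge the two best
#'   options ("mild difficulty" scores 1, like "no difficulty"); item 11
#'   additionally merges the two worst ("unable" scores 3, like "severe
#'   difficulty").
#' * **dupuytren / symptoms**: the two worst options are merged on every
#'   item; the symptom subscale is, however, not recommended for use in
#'   Dupuytren disease and a warning is emitted.
#'
#' Items already holding fewer than 5 categories are left unchanged, which
#' makes the operation idempotent.
#'
#' @param m a [response_matrix()]. For the symptoms rules the columns must be
#'   ordered items 9, 10, 11.
#' @param condition `"dupuytren"` or `"cts"`.
#' @param subscale `"tasks"` or `"symptoms"`.
#' @return A list with elements `matrix` (recoded [response_matrix()], tagged
#'   with the condition/subscale) and `recode` (the [recode_map()] applied).
#' @export
quickdash_recode <- function(m, condition = c("dupuytren", "cts"),
                             subscale = c("tasks", "symptoms")) {
  condition <- match.arg(condition)
  subscale <- match.arg(subscale)
  nitems <- length(m$item_ids)
  rule_for <- function(pos) {
    if (condition == "dupuytren") {
      if (subscale == "tasks") .qd_merge_worst else .qd_merge_worst
    } else {
      if (subscale == "tasks") {
        0:4
      } else {
        # symptoms in CTS: items 9,10 merge best pair; item 11 merges both ends
        if (pos < nitems) .qd_merge_best else .qd_merge_both
      }
    }
  }
  maps <- lapply(seq_len(nitems), function(i) {
    k <- m$n_categories[i]
    if (k == 5L) rule_for(i)[seq_len(k)] else seq.int(0L, k - 1L)
  })
  names(maps) <- m$item_ids
  r <- recode_map(maps)
  if (condition == "dupuytren" && subscale == "symptoms") {
    warning("the symptom items (9-11) are not recommended for use in Dupuytren disease",
            call. = FALSE)
  }
  out <- apply_recode(m, r)
  out$condition <- condition
  out$subscale <- subscale
  list(matrix = out, recode = r)
}

#' Raw sum scores
#'
#' @param m a [response_matrix()].
#' @param coding `"questionnaire"` sums the 1-based item scores (minimum sum
#'   equals the item count, matching the published conversion tables);
#'   `"internal"` sums the 0-based codes.
#' @return Integer vector of per-person sum scores.
#' @export
raw_sum <- function(m, coding = c("questionnaire", "internal")) {
  coding <- match.arg(coding)
  s <- rowSums(m$values)
  if (coding == "questionnaire") s <- s + length(m$item_ids)
  as.integer(s)
}
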