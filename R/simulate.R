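#' Simulation specification for partial-credit response cohorts
#'
#' Describes a synthetic cohort: person count, per-item step difficulties,
#' the latent-trait distribution (normal, or skew-normal for negatively
#' skewed cohorts), optional testlet structure inducing local dependence,
#' and a root seed. Identical specs (including the seed) reproduce
#' identical data bit-for-bit.
#'
#' @param n number of persons (>= 1).
#' @param delta list of step-difficulty vectors (logits), one per item;
#'   names become item ids. Threshold disorder is injected simply by
#'   specifying reversed adjacent steps — the model generates from them
#'   as-is.
#' @param trait either `list(dist = "normal", mean, sd)` or
#'   `list(dist = "skewnormal", location, scale, shape)`.
#' @param testlets optional list of `list(items = <ids>, gamma = <loading>)`;
#'   items in a testlet share an extra standard-normal person component
#'   scaled by `gamma`, added to the trait when generating their responses.
#' @param seed integer root seed. Child seeds are derived per stream
#'   (trait, testlet, response) so that toggling testlets does not perturb
#'   the trait or response draws.
#' @param condition,subscale optional tags propagated to the generated
#'   [response_matrix()].
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n, delta, trait = list(dist = "normal", mean = 0, sd = 1),
                     testlets = NULL, seed = 1L,
                     condition = NULL, subscale = NULL) {
  stopifnot(n >= 1, length(delta) >= 1)
  if (is.null(names(delta))) names(delta) <- paste0("item", seq_along(delta))
  if (any(vapply(delta, length, 1L) < 1L)) {
    stop("every item needs at least 2 categories (1 step)", call. = FALSE)
  }
  trait$dist <- match.arg(trait$dist, c("normal", "skewnormal"))
  if (trait$dist == "normal") {
    stopifnot(trait$sd > 0)
  } else {
    stopifnot(trait$scale > 0)
  }
  if (!is.null(testlets)) {
    all_items <- unlist(lapply(testlets, `[[`, "items"))
    if (anyDuplicated(all_items)) {
      stop("testlets overlap: an item may belong to at most one testlet",
           call. = FALSE)
    }
    if (!all(all_items %in% names(delta))) {
      stop("testlet references unknown item(s)", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), delta = delta, trait = trait,
         testlets = testlets, seed = as.integer(seed),
         condition = condition, subscale = subscale),
    class = "sim_spec"
  )
}

# Skew-normal sampler via the |Z0| construction:
# X = location + scale * (d*|Z0| + sqrt(1-d^2)*Z1), d = shape/sqrt(1+shape^2).
rskewnorm <- function(n, location, scale, shape) {
  d <- shape / sqrt(1 + shape^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  location + scale * (d * z0 + sqrt(1 - d^2) * z1)
}

# Skew-normal location/scale achieving a target mean and sd at given shape.
skewnorm_params <- function(mean = 0, sd = 1, shape = -4) {
  d <- shape / sqrt(1 + shape^2)
  b <- sqrt(2 / pi)
  scale <- sd / sqrt(1 - b^2 * d^2)
  list(location = mean - scale * b * d, scale = scale, shape = shape)
}

#' Generate a response cohort from a simulation spec
#'
#' Draws person traits from the spec's distribution, adds testlet
#' components (`theta + gamma * u` for items in a testlet, `u` standard
#' normal per person and testlet), and draws each item response from the
#' partial-credit category probabilities. Deterministic given the spec.
#'
#' @param spec a [sim_spec()].
#' @return A [response_matrix()] carrying the spec's tags; the generated
#'   trait values are attached as attribute `"theta"`.
#' @export
simulate_responses <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  child <- sample.int(.Machine$integer.max - 1L, 3L)

  set.seed(child[1])
  theta <- if (spec$trait$dist == "normal") {
    stats::rnorm(spec$n, spec$trait$mean, spec$trait$sd)
  } else {
    rskewnorm(spec$n, spec$trait$location, spec$trait$scale, spec$trait$shape)
  }

  item_ids <- names(spec$delta)
  eff <- matrix(theta, spec$n, length(item_ids),
                dimnames = list(NULL, item_ids))
  if (!is.null(spec$testlets)) {
    set.seed(child[2])
    for (tl in spec$testlets) {
      u <- stats::rnorm(spec$n)
      eff[, tl$items] <- eff[, tl$items] + tl$gamma * u
    }
  }

  set.seed(child[3])
  values <- matrix(0L, spec$n, length(item_ids),
                   dimnames = list(NULL, item_ids))
  for (i in seq_along(item_ids)) {
    p <- category_probs(eff[, i], spec$delta[[i]])
    cum <- t(apply(p, 1, cumsum))
    u <- stats::runif(spec$n)
    values[, i] <- as.integer(rowSums(u > cum))
  }
  m <- response_matrix(values, item_ids = item_ids,
                       n_categories = vapply(spec$delta, length, 1L) + 1L,
                       condition = spec$condition, subscale = spec$subscale)
  attr(m, "theta") <- theta
  m
}

#' Reference cohort templates
#'
#' Documented simulation specs emulating the qualitative structure of
#' preoperative QuickDASH cohorts in the two conditions:
#'
#' * `cts_tasks` — n = 1851, 6 items x 5 categories, trait N(0, 1), item
#'   thresholds spanning the trait range (well-targeted, ordered steps).
#' * `dupuytren_tasks` — n = 731, 6 items x 5 categories, negatively skewed
#'   trait (skew-normal, shape -4, rescaled to mean 0 / sd 1.4), item
#'   locations at least 1 logit above the trait mean (mistargeted toward
#'   poor hand function) with a deep first step so the lower trait range
#'   retains some measurement, and the two most severe steps reversed on
#'   every item so the "severe difficulty"/"unable" thresholds are
#'   disordered.
#' * `cts_symptoms` / `dupuytren_symptoms` — 3-item analogues of the above.
#'
#' The generating constants were fixed at design time so that every
#' category of every item is observed with near-certainty at the cohort
#' size (a precondition of the PCM fit).
#'
#' @param name one of `"cts_tasks"`, `"dupuytren_tasks"`, `"cts_symptoms"`,
#'   `"dupuytren_symptoms"`.
#' @param seed root seed for the spec.
#' @return A [sim_spec()].
#' @export
cohort_spec <- function(name = c("cts_tasks", "dupuytren_tasks",
                                 "cts_symptoms", "dupuytren_symptoms"),
                        seed = 1L) {
  name <- match.arg(name)
  ordered_steps <- c(-1.5, -0.5, 0.5, 1.5)
  disordered_steps <- c(-2.05, 0.05, 1.55, 0.45)   # top two reversed
  mk_delta <- function(centers, steps, ids) {
    d <- lapply(centers, function(c0) c0 + steps)
    names(d) <- ids
    d
  }
  task_ids <- paste0("DASH", 1:6)
  sym_ids <- paste0("DASH", 9:11)
  skew_trait <- c(skewnorm_params(mean = 0, sd = 1.4, shape = -4),
                  dist = "skewnormal")
  switch(name,
    cts_tasks = sim_spec(
      n = 1851L,
      delta = mk_delta(c(-1.2, -0.7, -0.2, 0.3, 0.8, 1.3), ordered_steps, task_ids),
      trait = list(dist = "normal", mean = 0, sd = 1),
      seed = seed, condition = "cts", subscale = "tasks"),
    dupuytren_tasks = sim_spec(
      n = 731L,
      delta = mk_delta(c(0.95, 1.05, 1.35, 1.0, 1.25, 1.1), disordered_steps, task_ids),
      trait = skew_trait,
      seed = seed, condition = "dupuytren", subscale = "tasks"),
    cts_symptoms = sim_spec(
      n = 1851L,
      delta = mk_delta(c(-0.6, 0, 0.6), ordered_steps, sym_ids),
      trait = list(dist = "normal", mean = 0, sd = 1),
      seed = seed, condition = "cts", subscale = "symptoms"),
    dupuytren_symptoms = sim_spec(
      n = 731L,
      delta = mk_delta(c(1.0, 1.25, 1.1), disordered_steps, sym_ids),
      trait = skew_trait,
      seed = seed, condition = "dupuytren", subscale = "symptoms")
  )
}

#' Add a local-dependence testlet to a spec
#'
#' Returns the spec with the given item pair sharing a testlet of loading
#' `gamma`, for exercising local-dependence diagnostics (Yen's Q3).
#'
#' @param spec a [sim_spec()].
#' @param pair character vector of two item ids.
#' @param gamma testlet loading (0 = no dependence).
#' @return The modified [sim_spec()].
#' @export
inject_ld <- function(spec, pair, gamma) {
  stopifnot(length(pair) == 2)
  sim_spec(n = spec$n, delta = spec$delta, trait = spec$trait,
           testlets = c(spec$testlets, list(list(items = pair, gamma = gamma))),
           seed = spec$seed, condition = spec$condition,
           subscale = spec$subscale)
}
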