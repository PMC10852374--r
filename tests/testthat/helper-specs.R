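# Shared simulation designs for the tests.

# Moderate 6-item x 5-category benchmark whose steps are all well observed
# at n = 2000: the parameter-recovery design.
recovery_delta <- function() {
  centers <- c(-0.8, -0.5, -0.2, 0.2, 0.5, 0.8)
  offs <- c(-1, -0.35, 0.35, 1)
  d <- lapply(centers, function(c0) c0 + offs)
  names(d) <- paste0("DASH", 1:6)
  d
}

recovery_matrix <- function(n = 2000L, seed = 1L) {
  simulate_responses(sim_spec(n, recovery_delta(), seed = seed))
}

# Small deterministic response matrix for exact-arithmetic tests.
toy_matrix <- function(values, n_categories = NULL) {
  response_matrix(as.matrix(values), n_categories = n_categories)
}

# CSV fixture on disk; returns the path.
write_csv_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "responses.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
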