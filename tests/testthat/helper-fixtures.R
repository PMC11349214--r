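# Shared fixtures, memoized so expensive cohorts are built once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small mixed cohort for unit tests
small_cohort <- function() memo("small_cohort", {
  make_copd_like(cohort_spec(n_subjects = 600, n_observed = 12, n_latent = 1,
                             mb_size = 6, seed = 42))
})

# study-scale cohort (shared by several acceptance blocks)
study_cohort <- function(seed = 1) memo(paste0("study_", seed), {
  make_copd_like(cohort_spec(seed = seed))
})

# plain continuous dataset from independent Gaussians
gaussian_md <- function(n, p, seed = 1) {
  vals <- with_seed(seed, as.data.frame(matrix(stats::rnorm(n * p), n, p)))
  names(vals) <- paste0("x", seq_len(p))
  mixed_dataset(vals, data.frame(name = names(vals), kind = "continuous"))
}

# tiny helper to build an all-continuous ground-truth DAG from a parent list
cont_dag <- function(nodes, parents, latent = character(0)) {
  ground_truth_dag(data.frame(name = nodes,
                              kind = ifelse(nodes %in% latent, "latent", "continuous"),
                              levels = NA_integer_),
                   parents)
}
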