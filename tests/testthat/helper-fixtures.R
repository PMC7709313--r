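# Shared in-code fixtures for the test suite.

# Two sibling diseases under one root plus one disjoint lineage: the sibling
# pair has semantic similarity exactly 1/3 at delta = 0.5.
sibling_codes <- function() {
  tibble::tibble(
    disease = c("alpha", "beta", "gamma"),
    code = c("C01.100", "C01.200", "D05.300")
  )
}

# Default planted-structure dataset used by the pipeline-level tests.
fixture_data <- function(seed = 42, ...) {
  as_fvtlda_data(simulate_tripartite(seed = seed, ...))
}

# Walk restart used for evaluations on the synthetic fixture (see the
# methods vignette: on a small network the benchmark-tuned restart of 0.001
# lets the walk mix to its stationary state and erases the seed signal).
fixture_params <- function() {
  fvtlda_params(r1 = 0.3, r2 = 0.3)
}

random_stochastic_matrix <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m / rowSums(m)
}
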