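# shared oracles and generators for the test suite

# fine-grid numerical quadrature of the input function, independent of the
# analytic antiderivative in auc.biexp
quadrature_auc <- function(ifn, t) {
  if (t == 0) return(0)
  stats::integrate(function(x) predict(ifn, x), 0, t,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

# random valid input functions for property-style tests
random_ifns <- function(n, seed) {
  set.seed(seed)
  replicate(n, {
    biexp(amp_fast = runif(1, 1, 30), rate_fast = -runif(1, 0.05, 0.3),
          amp_slow = runif(1, 1, 30), rate_slow = -runif(1, 0.002, 0.02))
  }, simplify = FALSE)
}

fixture_names <- c("huJ591-like", "trastuzumab-like", "pertuzumab-like")

candidate_times <- c(24, 48, 96, 144, 192)

# reference parameter grid of the canonical design
ref_grid <- expand.grid(ki = c(1e-3, 5e-3, 20e-3), vt = c(0.1, 0.2, 0.5))
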