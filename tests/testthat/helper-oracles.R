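# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# brute-force twin covariance: Kronecker assembly from component matrices
oracle_twin_covariance <- function(paths, zygosity) {
  L <- function(t) matrix(c(t[1], t[2], 0, t[3]), 2, 2)
  A <- tcrossprod(L(paths$a))
  S <- tcrossprod(L(paths$cd))
  E <- tcrossprod(L(paths$e))
  wA <- if (zygosity == "MZ") 1 else 0.5
  wS <- if (paths$model == "ACE") 1 else if (zygosity == "MZ") 1 else 0.25
  diag(2) %x% (A + S + E) + (matrix(1, 2, 2) - diag(2)) %x% (wA * A + wS * S)
}

# generic zero-mean multivariate-normal log-density, one row at a time
oracle_mvn_loglik <- function(X, S) {
  ch <- chol(S)
  sum(apply(X, 1, function(x) {
    z <- backsolve(ch, x, transpose = TRUE)
    -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }))
}

# literal step-up definition of the BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# random valid path set for property tests
random_paths <- function(model = sample(c("ACE", "ADE"), 1)) {
  trip <- function(dmin = 0) c(abs(rnorm(1)) + dmin, rnorm(1),
                               abs(rnorm(1)) + dmin)
  path_coefficients(model, a = trip(),
                    c = if (model == "ACE") trip(),
                    d = if (model == "ADE") trip(),
                    e = trip(0.1))
}

# standard small fixture cohort shared by several tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_config(
        n_mz_pairs = 100L, n_dz_pairs = 40L, n_cpgs = 8L,
        scenarios = rep(scenario_levels(), 2), seed = 99L))
    cache
  }
})
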