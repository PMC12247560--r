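# Independent numerical oracles used across the suite.

# adaptive quadrature over the real line
quad <- function(f, lower = -Inf, upper = Inf, rel.tol = 1e-10) {
  stats::integrate(f, lower, upper, rel.tol = rel.tol,
                   subdivisions = 500L)$value
}

# r-th non-central moment of the basic SHASH law by quadrature over the
# whole real line (the infinite-range transformation in integrate()
# covers the heavy tails that a fixed window under-covers at small delta)
quad_shash_moment <- function(r, epsilon, delta) {
  quad(function(x) x^r * dshash(x, epsilon, delta))
}

# central-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- x
    e[i] <- e[i] + h
    up <- f(e)
    e[i] <- e[i] - 2 * h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}

# small default cohort for structural tests
tiny_cohort <- function(n_sites = 3, n_per_site = 40, seed = 99, ...) {
  simulate_cohort(sim_config(n_sites = n_sites, n_per_site = n_per_site,
                             seed = seed, ...))
}

# bind a spec to a cohort without the hbr_fit wrapper
cohort_model <- function(spec, d) {
  X <- build_design_matrix(d$age, d$sex)
  bi <- batch_index_of(d$site)
  hbr_model(spec, X, bi, d$y)
}

batch_index_of <- function(site) {
  as.integer(factor(as.character(site), levels = sort(unique(as.character(site)))))
}
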