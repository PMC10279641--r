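# Shared fixtures, built in code at test time.

# one valid tree, overridable field by field
make_tree <- function(...) {
  base <- tibble::tibble(
    tree_id = "t1", species = "Abies", pft = "EC",
    a_bh = 0.04, height = 15, crown_base_height = 8,
    a_cb = NA_real_, leaf_area = NA_real_, leaf_mass = NA_real_
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# ln-scale power-law sample with lognormal noise, for regression tests
make_loglog <- function(n, slope, elevation, sd, seed,
                        xmin = 1e-4, xmax = 0.5) {
  set.seed(seed)
  x <- exp(runif(n, log(xmin), log(xmax)))
  data.frame(
    x = log(x),
    y = log(elevation) + slope * log(x) + rnorm(n, 0, sd)
  )
}

# a CF-consistent test allometry: constant ln-scale interval half-width,
# CF = exp(sigma^2 / 2) so the point estimate is the predictive mean
make_flat_pi_allometry <- function(delta = 0.6, elevation = 2742,
                                   slope = 0.955, response = "LA",
                                   predictor = "a_cb_est") {
  sigma <- delta / qnorm(0.975)
  allometry(
    response = response, predictor = predictor,
    elevation = elevation, slope = slope,
    cf = exp(sigma^2 / 2), scope = "site-specific",
    pi = pi_approximation("quadratic", c0 = delta, c1 = 0, c2 = 0),
    range = c(1e-6, 10)
  )
}
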