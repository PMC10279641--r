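test_that("registry constants match the published global coefficients exactly", {
  reg <- tidy(qpipe_registry())
  expect_equal(nrow(reg), 6)
  chk <- function(key, elevation, slope, cf, n) {
    row <- reg[reg$key == key, ]
    expect_identical(row$elevation, elevation)
    expect_identical(row$slope, slope)
    expect_identical(row$cf, cf)
    expect_identical(row$n, as.integer(n))
  }
  chk("pipe_la_pooled", 2370, 0.940, 1.065, 768)
  chk("qpipe_la_pooled", 2742, 0.955, 1.077, 768)
  chk("qpipe_lm_EC", 854.4, 1.078, 1.023, 221)
  chk("qpipe_lm_DC", 571.4, 1.172, 1.059, 57)
  chk("qpipe_lm_EB", 293.8, 0.973, 1.073, 447)
  chk("qpipe_lm_DB", 180.3, 1.017, 1.073, 227)
  # interval coefficient rows
  pic <- function(key, c0, c1, c2, c3 = NA_real_, c4 = NA_real_) {
    row <- reg[reg$key == key, ]
    expect_identical(c(row$c0, row$c1, row$c2), c(c0, c1, c2))
    expect_identical(c(row$c3, row$c4), c(c3, c4))
  }
  pic("pipe_la_pooled", 0.71655, 0.00590, 0.00052)
  pic("qpipe_la_pooled", 0.77894, 0.00622, 0.00054)
  pic("qpipe_lm_EC", 0.48920, 0.01772, 0.00181)
  pic("qpipe_lm_DC", 2.004, 0.3389, 57, -5.206, 62.89)
  pic("qpipe_lm_EB", 0.78223, 0.01286, 0.00112)
  pic("qpipe_lm_DB", 0.81205, 0.01924, 0.00159)
})

test_that("prediction at 1 m2 returns CF x Elevation for every registry entry", {
  for (e in qpipe_registry()) {
    expect_equal(predict(e, 1), e$cf * e$elevation)
  }
  # forced arithmetic for the pooled qPipe LA line
  expect_equal(predict(qpipe_registry()$qpipe_la_pooled, 1), 1.077 * 2742)
})

test_that("prediction is monotone and rejects non-positive predictors", {
  a <- qpipe_registry()$qpipe_la_pooled
  xs <- exp(seq(log(1e-4), log(1), length.out = 50))
  expect_true(all(diff(predict(a, xs)) > 0))
  expect_error(predict(a, 0), class = "qpipe_domain_error")
  expect_error(predict(a, -3), class = "qpipe_domain_error")
  # identity-map allometry
  ident <- allometry("LA", "a_cb", elevation = 1, slope = 1, cf = 1)
  expect_equal(predict(ident, c(0.3, 2)), c(0.3, 2))
})

test_that("interval forms evaluate as specified", {
  a <- qpipe_registry()$qpipe_la_pooled
  pr <- predict_interval(a, 1, warn_extrapolation = FALSE)
  # at x = 1 m2, u = 0: half-width is c0 alone
  expect_equal(pr$delta_pi, 0.77894)
  m <- 2742 # uncorrected prediction at 1 m2
  expect_equal(pr$lower, m * exp(-0.77894))
  expect_equal(pr$upper, m * exp(0.77894))
  expect_equal(pr$point, 1.077 * m)
  expect_true(pr$lower < pr$point && pr$point < pr$upper)

  # ls form: minimised at u = c3, symmetric about it
  dc <- qpipe_registry()$qpipe_lm_DC
  u0 <- -5.206
  d_min <- predict_interval(dc, exp(u0), warn_extrapolation = FALSE)$delta_pi
  d_lo <- predict_interval(dc, exp(u0 - 1), warn_extrapolation = FALSE)$delta_pi
  d_hi <- predict_interval(dc, exp(u0 + 1), warn_extrapolation = FALSE)$delta_pi
  expect_lt(d_min, d_lo)
  expect_equal(d_lo, d_hi, tolerance = 1e-12)
  expect_equal(d_min, 2.004 * 0.3389 * sqrt(1 + 1 / 57))

  # zero-width coefficients collapse the interval (CF-free entry)
  flat <- allometry("LA", "a_cb", 100, 1,
    cf = 1,
    pi = pi_approximation("quadratic", 0, 0, 0)
  )
  pr0 <- predict_interval(flat, 0.5, warn_extrapolation = FALSE)
  expect_equal(pr0$lower, pr0$point)
  expect_equal(pr0$upper, pr0$point)
})

test_that("extrapolation warns but does not fail", {
  a <- qpipe_registry()$qpipe_la_pooled
  expect_warning(predict_interval(a, 5), "calibration range")
  expect_silent(predict_interval(a, 5, warn_extrapolation = FALSE))
})

test_that("per-tree estimation selects pooled LA and per-PFT LM entries", {
  t_ec <- make_tree(pft = "EC")
  t_db <- make_tree(pft = "DB", tree_id = "t2")
  trees <- rbind(t_ec, t_db)
  la <- estimate_trees(trees, "LA")
  expect_equal(la$point[1], la$point[2]) # pooled: PFT ignored
  lm_ <- estimate_trees(trees, "LM")
  expect_gt(lm_$point[1], lm_$point[2]) # EC elevation 854.4 vs DB 180.3

  # direct evaluation chain oracle
  acb_est <- 0.04 * 7 / 13.7
  expect_equal(la$x[1], acb_est)
  expect_equal(la$point[1], 1.077 * 2742 * acb_est^0.955)

  bad <- make_tree()
  bad$pft <- "EB"
  reg_no_eb <- qpipe_registry()[c("qpipe_lm_EC", "qpipe_lm_DB")]
  class(reg_no_eb) <- "qpipe_registry"
  expect_error(
    estimate_trees(bad, "LM", registry = reg_no_eb),
    "EC",
    class = "qpipe_registry_error"
  )
})

test_that("fit_allometry recovers a noiseless power law exactly", {
  set.seed(31)
  n <- 40
  a_bh <- exp(runif(n, log(1e-3), log(0.3)))
  h <- runif(n, 5, 30)
  cb <- 1.3 + runif(n, 0.1, 0.8) * (h - 1.3)
  trees <- tibble::tibble(
    species = sample(c("a", "b"), n, TRUE), pft = "EB",
    a_bh = a_bh, height = h, crown_base_height = cb
  )
  acbe <- add_crown_metrics(trees)$a_cb_est
  trees$leaf_area <- 500 * acbe^1.2
  fit <- suppressWarnings(fit_allometry(trees, "LA", "a_cb_est")) # perfect fit
  expect_equal(fit$slope, 1.2, tolerance = 1e-8)
  expect_equal(fit$elevation, 500, tolerance = 1e-6)
  expect_equal(fit$cf, 1, tolerance = 1e-10)
})

test_that("quadratic interval approximation tracks pointwise intervals within 1%", {
  trees <- simulate_trees(n_trees = 400, n_species = 20, seed = 14)
  fit <- fit_allometry(trees, "LA", "a_cb_est")
  m1 <- attr(fit, "fit")
  expect_equal(m1$method, "random_intercept")
  lx <- log(add_crown_metrics(trees)$a_cb_est)
  mid <- quantile(lx, c(0.05, 0.95))
  u <- seq(mid[1], mid[2], length.out = 50)
  exact <- qnorm(0.975) * sqrt(
    m1$residual_sd^2 + m1$species_sd^2 + m1$intercept_se^2 + u^2 * m1$slope_se^2
  )
  approx <- delta_pi(fit$pi, u)
  expect_lt(max(abs(approx - exact) / exact), 0.01)
})

test_that("fitted intervals cover ~95% of held-out draws from the model", {
  trees <- simulate_trees(n_trees = 400, n_species = 20, seed = 15)
  fit <- fit_allometry(trees, "LA", "a_cb_est")
  m1 <- attr(fit, "fit")
  set.seed(16)
  n_new <- 2000
  lx <- log(add_crown_metrics(trees)$a_cb_est)
  u <- runif(n_new, quantile(lx, 0.02), quantile(lx, 0.98))
  sd_new <- sqrt(m1$residual_sd^2 + m1$species_sd^2) # new species draw
  y <- m1$intercept + m1$slope * u + rnorm(n_new, 0, sd_new)
  pr <- predict_interval(fit, exp(u), warn_extrapolation = FALSE)
  covered <- mean(exp(y) >= pr$lower & exp(y) <= pr$upper)
  expect_gt(covered, 0.92)
  expect_lt(covered, 0.98)
})

test_that("parameter recovery: fitted CIs cover generating slope and elevation", {
  hits_slope <- 0
  hits_elev <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    d <- make_loglog(400, 1.1, 800, 0.3, seed = 5000 + r)
    fit <- fit_ols(d, x, y)
    ci_s <- fit$slope + c(-1, 1) * qt(0.975, fit$df_residual) * fit$slope_se
    ci_e <- fit$intercept + c(-1, 1) * qt(0.975, fit$df_residual) * fit$intercept_se
    hits_slope <- hits_slope + (1.1 >= ci_s[1] && 1.1 <= ci_s[2])
    hits_elev <- hits_elev + (log(800) >= ci_e[1] && log(800) <= ci_e[2])
  }
  expect_gte(hits_slope / n_rep, 0.9)
  expect_gte(hits_elev / n_rep, 0.9)
})

test_that("registry YAML round-trips through read/write", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  write_registry(qpipe_registry(), tmp)
  back <- read_registry(tmp)
  expect_equal(tidy(back), tidy(qpipe_registry()))
  # shipped file carries the same constants as the built-in registry
  shipped <- system.file("extdata", "global_allometries.yml", package = "qpipe")
  expect_equal(tidy(read_registry(shipped)), tidy(qpipe_registry()))
})
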