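test_that("a single tree's stand estimate is the tree's triple over the area", {
  tree <- make_tree()
  a <- make_flat_pi_allometry(delta = 0.5)
  per <- predict_interval(a, add_crown_metrics(tree)$a_cb_est,
    warn_extrapolation = FALSE
  )
  est <- estimate_stand(tree, area = 100, source = a)
  expect_equal(est$point, per$point / 100)
  expect_equal(est$lower, per$lower / 100, tolerance = 1e-10)
  expect_equal(est$upper, per$upper / 100, tolerance = 1e-10)
})

test_that("n identical trees give the sqrt(n) closed form under quadrature", {
  n <- 16
  trees <- do.call(rbind, lapply(1:n, function(i) make_tree(tree_id = as.character(i))))
  a <- make_flat_pi_allometry(delta = 0.5)
  one <- predict_interval(a, add_crown_metrics(make_tree())$a_cb_est,
    warn_extrapolation = FALSE
  )
  est <- estimate_stand(trees, area = 100, source = a, propagate = "quadrature")
  expect_equal(est$point, n * one$point / 100)
  expect_equal(est$point - est$lower, sqrt(n) * (one$point - one$lower) / 100)
  expect_equal(est$upper - est$point, sqrt(n) * (one$upper - one$point) / 100)
})

test_that("zero-width per-tree intervals collapse the stand bounds", {
  trees <- simulate_trees(n_trees = 10, seed = 5)
  flat <- allometry("LA", "a_cb_est", 2000, 1,
    cf = 1,
    pi = pi_approximation("quadratic", 0, 0, 0), range = c(1e-6, 10)
  )
  for (rule in c("lognormal", "quadrature", "log_quadrature")) {
    est <- estimate_stand(trees, 50, source = flat, propagate = rule)
    expect_equal(est$lower, est$point)
    expect_equal(est$upper, est$point)
  }
})

test_that("propagated half-width is sub-additive in the per-tree half-widths", {
  trees <- simulate_trees(n_trees = 25, seed = 6)
  est <- estimate_stand(trees, area = 200, propagate = "quadrature")
  per <- est$per_tree
  expect_lte(est$point - est$lower, sum(per$point - per$lower) / 200)
  expect_lte(est$upper - est$point, sum(per$upper - per$point) / 200)
})

test_that("LAI points recombine exactly across sub-stands", {
  trees <- simulate_trees(n_trees = 30, seed = 7)
  full <- estimate_stand(trees, area = 300)
  half1 <- estimate_stand(trees[1:15, ], area = 150)
  half2 <- estimate_stand(trees[16:30, ], area = 150)
  expect_equal(full$point, (half1$point * 150 + half2$point * 150) / 300)
})

test_that("lognormal propagation matches a Monte-Carlo oracle within 5%", {
  trees <- simulate_trees(n_trees = 30, seed = 42)
  a <- make_flat_pi_allometry(delta = 0.6)
  est <- estimate_stand(trees, area = 400, source = a, propagate = "lognormal")
  per <- est$per_tree
  # oracle: draw each tree from its ln-scale predictive distribution
  sigma <- log(per$upper / per$lower) / (2 * qnorm(0.975))
  mu <- log(per$point) - sigma^2 / 2 # point is the CF-corrected mean
  set.seed(1234)
  n_draw <- 50000
  draws <- matrix(
    rlnorm(n_draw * nrow(per), rep(mu, n_draw), rep(sigma, n_draw)),
    nrow = nrow(per)
  )
  totals <- colSums(draws) / 400
  q <- quantile(totals, c(0.025, 0.975))
  hw_lo_mc <- est$point - q[[1]]
  hw_up_mc <- q[[2]] - est$point
  expect_lt(abs((est$point - est$lower) - hw_lo_mc) / hw_lo_mc, 0.05)
  expect_lt(abs((est$upper - est$point) - hw_up_mc) / hw_up_mc, 0.05)
})

test_that("method comparison reproduces identical rows for identical sources", {
  trees <- simulate_trees(n_trees = 20, seed = 8)
  a <- make_flat_pi_allometry()
  out <- compare_methods(trees, 100, list(m1 = a, m2 = a))
  expect_equal(out$point[1], out$point[2])
  expect_equal(out$lower[1], out$lower[2])
  expect_true(all(attr(out, "overlap")$overlap))
})

test_that("paraboloid stands equate pipe and qPipe; tapered (X<2) stands diverge", {
  mk <- function(taper_sdlog, taper_meanlog) {
    simulate_trees(
      n_trees = 80, seed = 10, residual_sdlog = 0, species_sdlog = 0,
      taper_meanlog = taper_meanlog, taper_sdlog = taper_sdlog
    )
  }
  a_pipe <- make_flat_pi_allometry(delta = 0.3, predictor = "a_cb")
  a_qpipe <- make_flat_pi_allometry(delta = 0.3, predictor = "a_cb_est")
  # exact paraboloids: A_CB_Est = A_CB, methods agree tree by tree
  tr2 <- mk(0, log(2))
  out <- compare_methods(tr2, 500, list(
    pipe = list(source = a_pipe, predictor = "a_cb"),
    qpipe = list(source = a_qpipe, predictor = "a_cb_est")
  ))
  expect_equal(out$point[1], out$point[2], tolerance = 1e-12)
  # strongly tapered stems (X mostly < 2): qPipe overestimates the stand
  tr1 <- mk(0.1, log(1.4))
  out1 <- compare_methods(tr1, 500, list(
    pipe = list(source = a_pipe, predictor = "a_cb"),
    qpipe = list(source = a_qpipe, predictor = "a_cb_est")
  ))
  expect_gt(out1$point[out1$method == "qpipe"], out1$point[out1$method == "pipe"])
})

test_that("dead and zero-crown trees are excluded with a message", {
  trees <- simulate_trees(n_trees = 10, seed = 9)
  trees$dead <- c(TRUE, rep(FALSE, 9))
  expect_message(
    est <- estimate_stand(trees, 100),
    "excluded 1 dead"
  )
  expect_equal(est$n_trees, 9)
})

test_that("stand report writes one delimited row per estimate", {
  trees <- simulate_trees(n_trees = 10, seed = 12)
  est <- estimate_stand(trees, 100)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_stand_report(est, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_equal(back$point, est$point)
  expect_error(estimate_stand(trees, -5), class = "qpipe_domain_error")
})
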