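test_that("diameter/area conversion is exact and round-trips", {
  expect_equal(area_from_diameter(2 / sqrt(pi)), 1.0)
  expect_equal(area_from_diameter(0.1), pi * 0.01 / 4)
  expect_equal(area_from_diameter(diameter_from_area(0.04)), 0.04)
  expect_error(area_from_diameter(0), class = "qpipe_domain_error")
  expect_error(diameter_from_area(-1), class = "qpipe_domain_error")
})

test_that("crown ratio follows the crown-length / stem-length definition", {
  expect_equal(crown_ratio(15, 8), 7 / 13.7)
  expect_equal(crown_ratio(15, 1.3), 1) # crown down to breast height
  expect_error(crown_ratio(15, 15), class = "qpipe_domain_error") # no crown
  expect_error(crown_ratio(1.3, 1.3), class = "qpipe_domain_error")
  expect_error(crown_ratio(15, 1.0), class = "qpipe_domain_error") # below 1.3
})

test_that("the qPipe estimate is A_BH x crown ratio, never above A_BH", {
  expect_equal(estimate_acb(0.04, 15, 8), 0.04 * 7 / 13.7)
  expect_equal(estimate_acb(0.04, 15, 1.3), 0.04)
  # exact paraboloid (X = 2): estimate equals the true crown-base area
  l <- 0.37
  a_bh <- 0.05
  expect_equal(estimate_acb(a_bh, 20, 20 - l * (20 - 1.3)),
    a_bh * taper_relative_area(l, 2),
    tolerance = 1e-12
  )
  set.seed(7)
  h <- runif(200, 2, 40)
  cb <- 1.3 + runif(200) * (h - 1.3) * 0.999
  a <- runif(200, 1e-4, 0.5)
  expect_true(all(estimate_acb(a, h, cb) <= a + 1e-15))
})

test_that("taper profile matches L^(2/X) and is monotone in l", {
  expect_equal(taper_relative_area(1, 0.7), 1)
  expect_equal(taper_relative_area(0.5, 1), 0.25)
  expect_equal(taper_relative_area(0.512, 3), 0.64)
  expect_equal(taper_relative_area(0.5, 2), 0.5)
  for (x in c(0.5, 1, 2, 3, 7)) {
    l <- seq(0.01, 1, length.out = 50)
    expect_true(all(diff(taper_relative_area(l, x)) > 0))
  }
  expect_error(taper_relative_area(0, 2), class = "qpipe_domain_error")
  expect_error(taper_relative_area(1.01, 2), class = "qpipe_domain_error")
})

test_that("qPipe relative error is l^(1-2/X), crossing 1 exactly at X = 2", {
  expect_equal(qpipe_relative_error(0.3, 2), 1.0)
  expect_equal(qpipe_relative_error(0.5, 1), 2.0) # cone: overestimate
  expect_equal(qpipe_relative_error(0.512, 3), 0.8) # cubic: underestimate
  expect_equal(qpipe_relative_error(1, 7.3), 1.0) # degenerate but valid
  # monotone decreasing in X at fixed l < 1
  xs <- seq(0.5, 5, by = 0.1)
  for (l in c(0.2, 0.5, 0.9)) {
    err <- qpipe_relative_error(l, xs)
    expect_true(all(diff(err) < 0))
    expect_true(all(err[xs < 2] > 1))
    expect_true(all(err[xs > 2] < 1))
  }
})

test_that("taper exponent inversion round-trips with the taper profile", {
  expect_equal(taper_exponent_from_observation(0.5, 0.5), 2)
  expect_equal(taper_exponent_from_observation(0.5, 0.25), 1)
  expect_equal(
    taper_exponent_from_observation(0.3, taper_relative_area(0.3, 2.7)), 2.7
  )
  expect_error(taper_exponent_from_observation(1, 0.5), class = "qpipe_domain_error")
  expect_error(taper_exponent_from_observation(0.5, 1), class = "qpipe_domain_error")
})

test_that("log relative errors cancel for X symmetric about 2 on the 2/X scale", {
  l <- 0.4
  delta <- seq(0.05, 0.6, by = 0.05)
  x <- 2 / c(1 + delta, 1 - delta) # symmetric pairs in 2/X
  expect_equal(mean(log(qpipe_relative_error(l, x))), 0, tolerance = 1e-12)
})

test_that("tree table validation enforces the record invariants", {
  expect_silent(as_tree_tbl(make_tree()))
  expect_error(as_tree_tbl(make_tree(height = 1.3)), class = "qpipe_record_error")
  expect_error(as_tree_tbl(make_tree(crown_base_height = 15)), class = "qpipe_record_error")
  expect_error(as_tree_tbl(make_tree(crown_base_height = 1.0)), class = "qpipe_record_error")
  expect_error(as_tree_tbl(make_tree(pft = "XX")), class = "qpipe_record_error")
  expect_error(as_tree_tbl(make_tree(leaf_area = -1)), class = "qpipe_record_error")
  expect_error(
    as_tree_tbl(make_tree()[, setdiff(names(make_tree()), "height")]),
    class = "qpipe_schema_error"
  )
  # dbh accepted in place of a_bh
  t2 <- as_tree_tbl(tibble::tibble(
    species = "x", pft = "DB", dbh = 0.2, height = 10, crown_base_height = 4
  ))
  expect_equal(t2$a_bh, pi * 0.04 / 4)
})

test_that("add_crown_metrics appends ratio and qPipe area", {
  tr <- add_crown_metrics(make_tree())
  expect_equal(tr$crown_ratio, 7 / 13.7)
  expect_equal(tr$a_cb_est, 0.04 * 7 / 13.7)
})

test_that("taper_diagnose recovers the drawn exponents from simulated trees", {
  trees <- simulate_trees(n_trees = 60, seed = 11)
  d <- taper_diagnose(trees)
  expect_gt(nrow(d), 50)
  expect_equal(d$taper_x, trees$taper_x[match(d$tree_id, trees$tree_id)],
    tolerance = 1e-10
  )
  expect_equal(d$rel_error,
    qpipe_relative_error(d$rel_crown_length, d$taper_x),
    tolerance = 1e-12
  )
})
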