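#' Standardized major axis (Model II) regression on log-log data
#'
#' Fits an SMA line per group to natural-log transformed allometric data.
#' SMA is the symmetric line-fitting method appropriate for *estimating* an
#' allometric slope (residuals in both variables); use the Model I fitters
#' ([fit_ols()], [fit_random_intercept()]) for *prediction*.
#'
#' Per group the SMA slope is sign(r)·sd(y)/sd(x) and the elevation is the
#' back-transformed intercept, i.e. the response value at a predictor of
#' 1 m². Slope confidence limits follow the standard SMA construction
#' b·(sqrt(B+1) ± sqrt(B)) with B = F(1-alpha; 1, n-2)·(1-r²)/(n-2). With
#' more than one group, a likelihood-ratio test of a common slope is run
#' (the statistic -sum (n_i - 2.5)·ln(1 - r_i²) of the correlation between
#' residual and fitted-axis scores, minimised over the candidate common
#' slope, compared to chi-square on groups - 1 df), and when slopes are
#' homogeneous, elevations are compared pairwise by Wald tests at the common
#' slope with Sidak-corrected p-values.
#'
#' The robust variant downweights points by Huber weights on the
#' standardized bivariate distance from the (iteratively re-estimated)
#' centroid, so the means and variances entering the slope formula are
#' outlier-resistant; iteration stops at a 1e-8 relative change or 50
#' iterations.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted or strings) of the ln-scale predictor
#'   and response.
#' @param group Optional grouping column (e.g. PFT).
#' @param robust Use Huber-downweighted moments (default FALSE). Groups with
#'   fewer than 5 points fall back to the standard fit with a warning.
#' @param alpha Confidence level complement for intervals and tests
#'   (default 0.05).
#' @return An object of class `qpipe_sma` with `tidy()`, `glance()` and
#'   `autoplot()` methods. `$groups` holds per-group estimates, `$common_slope`
#'   the likelihood-ratio test, `$pairwise` the Sidak-corrected elevation
#'   comparisons.
#' @examples
#' d <- data.frame(x = log(c(1, 2, 4, 8)), y = 2 * log(c(1, 2, 4, 8)) + log(2))
#' fit <- fit_sma(d, x, y)
#' tidy(fit)
#' @export
fit_sma <- function(data, x, y, group = NULL, robust = FALSE, alpha = 0.05) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  gq <- rlang::enquo(group)
  g_name <- if (rlang::quo_is_null(gq)) NULL else rlang::as_name(gq)

  d <- tibble::tibble(
    x = data[[x_name]],
    y = data[[y_name]],
    group = if (is.null(g_name)) "all" else as.character(data[[g_name]])
  )
  d <- d[complete.cases(d), ]
  counts <- table(d$group)
  if (any(counts < 3)) {
    abort("each group needs at least 3 complete observations.",
      class = "qpipe_degenerate_error"
    )
  }

  groups <- sort(unique(d$group))
  per_group <- purrr::map(groups, function(g) {
    di <- d[d$group == g, ]
    sma_core(di$x, di$y, robust = robust, alpha = alpha, label = g)
  })
  group_tbl <- purrr::list_rbind(purrr::map(per_group, "row"))
  group_tbl$group <- groups

  common <- NULL
  pairwise <- NULL
  if (length(groups) > 1) {
    common <- sma_common_slope_test(d, weights_of = per_group, groups = groups)
    pairwise <- sma_pairwise_elevations(d, per_group, groups,
      common_slope = common$common_slope, alpha = alpha
    )
  }

  structure(
    list(
      groups = group_tbl[, c(
        "group", "n", "slope", "slope_lo", "slope_hi",
        "elevation", "elevation_lo", "elevation_hi", "intercept", "r2"
      )],
      common_slope = common,
      pairwise = pairwise,
      alpha = alpha,
      robust = robust,
      x = x_name, y = y_name, group_var = g_name,
      data = d
    ),
    class = "qpipe_sma"
  )
}

# Single-group SMA on ln-scale data; returns the estimates row plus the
# Huber weights (reused by the grouped tests).
sma_core <- function(x, y, robust = FALSE, alpha = 0.05, label = NULL) {
  n <- length(x)
  if (robust && n < 5) {
    warn(sprintf(
      "robust SMA needs >= 5 points (group '%s' has %d); using the standard fit.",
      label %||% "", n
    ))
    robust <- FALSE
  }
  w <- w2 <- rep(1, n)
  if (robust) {
    # Huber M-estimation of the bivariate location/scatter entering the
    # slope formula: location weights min(1, k/d), squared for the second
    # moments; the scatter consistency constant cancels in slope and r.
    k <- sqrt(qchisq(0.95, df = 2))
    mx <- median(x)
    my <- median(y)
    sx <- max(stats::mad(x), .Machine$double.eps)
    sy <- max(stats::mad(y), .Machine$double.eps)
    for (iter in seq_len(50)) {
      di <- sqrt(((x - mx) / sx)^2 + ((y - my) / sy)^2)
      w <- pmin(1, k / pmax(di, .Machine$double.eps))
      w2 <- w^2
      mx_new <- sum(w * x) / sum(w)
      my_new <- sum(w * y) / sum(w)
      sx_new <- sqrt(sum(w2 * (x - mx_new)^2) / sum(w2))
      sy_new <- sqrt(sum(w2 * (y - my_new)^2) / sum(w2))
      if (sx_new == 0 || sy_new == 0) break
      delta <- max(abs(c(mx_new - mx, my_new - my, sx_new - sx, sy_new - sy)))
      mx <- mx_new
      my <- my_new
      sx <- sx_new
      sy <- sy_new
      if (delta < 1e-8) break
    }
  }
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxx <- sum(w2 * (x - mx)^2) / sum(w2)
  syy <- sum(w2 * (y - my)^2) / sum(w2)
  sxy <- sum(w2 * (x - mx) * (y - my)) / sum(w2)
  if (sxx <= 0 || syy <= 0) {
    abort(sprintf("zero variance in group '%s'; SMA undefined.", label %||% ""),
      class = "qpipe_degenerate_error"
    )
  }
  r <- sxy / sqrt(sxx * syy)
  b <- sign2(r) * sqrt(syy / sxx)
  a <- my - b * mx
  r2 <- min(r^2, 1)

  B <- qf(1 - alpha, 1, n - 2) * (1 - r2) / (n - 2)
  slope_lo <- b * (sqrt(B + 1) - sqrt(B))
  slope_hi <- b * (sqrt(B + 1) + sqrt(B))
  if (b < 0) {
    tmp <- slope_lo
    slope_lo <- slope_hi
    slope_hi <- tmp
  }

  res <- y - a - b * x
  varres <- sum(w2 * res^2) / sum(w2) * n / max(n - 2, 1)
  var_b <- b^2 * (1 - r2) / (n - 2)
  se_a <- sqrt(varres / n + mx^2 * var_b)
  tq <- qt(1 - alpha / 2, n - 2)

  list(
    row = tibble::tibble(
      group = label %||% "all", n = n,
      slope = b, slope_lo = slope_lo, slope_hi = slope_hi,
      elevation = exp(a),
      elevation_lo = exp(a - tq * se_a), elevation_hi = exp(a + tq * se_a),
      intercept = a, r2 = r2
    ),
    weights = w, mx = mx, my = my, sxx = sxx, syy = syy, sxy = sxy,
    varres = varres, se_a = se_a, n = n
  )
}

sign2 <- function(r) if (r < 0) -1 else 1

# Likelihood-ratio test of a common SMA slope across groups: the statistic
# -sum (n_i - 2.5) log(1 - cor(y - b x, y + b x)^2), minimised over b,
# is chi-square on (groups - 1) df under slope homogeneity.
sma_common_slope_test <- function(d, weights_of, groups) {
  stat_of <- function(b) {
    s <- 0
    for (i in seq_along(groups)) {
      di <- d[d$group == groups[i], ]
      u <- di$y - b * di$x
      v <- di$y + b * di$x
      # (near-)zero residual variance: the group lies exactly on slope b,
      # which is no evidence against a common slope
      tol <- 1e-10 * (sd(di$y) + abs(b) * sd(di$x))
      if (sd(u) <= tol || sd(v) <= tol) next
      r2 <- cor(u, v)^2
      s <- s - (nrow(di) - 2.5) * log(max(1 - r2, .Machine$double.eps))
    }
    s
  }
  slopes <- purrr::map_dbl(weights_of, ~ .x$row$slope)
  lo <- min(abs(slopes)) / 4
  hi <- max(abs(slopes)) * 4
  sgn <- sign2(median(slopes))
  opt <- optimize(function(b) stat_of(sgn * b), interval = c(lo, hi), tol = 1e-9)
  # degenerate (noise-free) groups make the objective discontinuous at the
  # group slopes; evaluate those candidates explicitly as well
  cand_b <- c(sgn * opt$minimum, slopes)
  cand_s <- vapply(cand_b, stat_of, numeric(1))
  best <- which.min(cand_s)
  df <- length(groups) - 1
  list(
    common_slope = cand_b[best],
    statistic = cand_s[best],
    df = df,
    p_value = 1 - pchisq(cand_s[best], df)
  )
}

# Wald comparison of group elevations at the common slope, Sidak-adjusted.
sma_pairwise_elevations <- function(d, per_group, groups, common_slope, alpha) {
  g <- length(groups)
  n_tot <- nrow(d)
  # pooled within-group correlation for the shared-slope variance term
  pooled_r2 <- {
    sxx <- syy <- sxy <- 0
    for (pg in per_group) {
      sxx <- sxx + pg$sxx * pg$n
      syy <- syy + pg$syy * pg$n
      sxy <- sxy + pg$sxy * pg$n
    }
    min((sxy / sqrt(sxx * syy))^2, 1)
  }
  var_b <- common_slope^2 * (1 - pooled_r2) / max(n_tot - 2 * g, 1)
  est <- purrr::map_dbl(per_group, function(pg) pg$my - common_slope * pg$mx)
  se2 <- purrr::map_dbl(per_group, function(pg) {
    res <- d$y[d$group == pg$row$group] - est[match(pg$row$group, groups)] -
      common_slope * d$x[d$group == pg$row$group]
    varres <- sum(res^2) / max(pg$n - 2, 1)
    varres / pg$n + pg$mx^2 * var_b
  })
  pairs <- utils::combn(seq_len(g), 2)
  m <- ncol(pairs)
  out <- purrr::map(seq_len(m), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    z <- (est[i] - est[j]) / sqrt(se2[i] + se2[j])
    p <- 2 * (1 - pnorm(abs(z)))
    tibble::tibble(
      group1 = groups[i], group2 = groups[j],
      statistic = z, p_value = p,
      p_sidak = 1 - (1 - p)^m
    )
  })
  out <- purrr::list_rbind(out)
  out$significant <- out$p_sidak < alpha
  out
}

#' @export
print.qpipe_sma <- function(x, ...) {
  cat(sprintf(
    "SMA (Model II) fit of %s ~ %s%s%s\n", x$y, x$x,
    if (!is.null(x$group_var)) paste0(" by ", x$group_var) else "",
    if (x$robust) " [robust]" else ""
  ))
  print(x$groups, ...)
  if (!is.null(x$common_slope)) {
    cat(sprintf(
      "Common slope %.4f; LR = %.3f on %d df, p = %.4g\n",
      x$common_slope$common_slope, x$common_slope$statistic,
      x$common_slope$df, x$common_slope$p_value
    ))
  }
  invisible(x)
}

#' @rdname fit_sma
#' @param x A `qpipe_sma` object.
#' @param ... Unused.
#' @method tidy qpipe_sma
#' @export
tidy.qpipe_sma <- function(x, ...) x$groups

#' @rdname fit_sma
#' @method glance qpipe_sma
#' @export
glance.qpipe_sma <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    n = sum(x$groups$n),
    robust = x$robust,
    common_slope = if (is.null(x$common_slope)) NA_real_ else x$common_slope$common_slope,
    common_slope_stat = if (is.null(x$common_slope)) NA_real_ else x$common_slope$statistic,
    common_slope_p = if (is.null(x$common_slope)) NA_real_ else x$common_slope$p_value
  )
}
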