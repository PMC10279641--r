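#' Power-law allometry objects
#'
#' A `qpipe_allometry` is the prediction equation Y = CF x Elevation x
#' X^Slope on arithmetic scales, where X is a crown-base stem area (measured
#' A_CB or the qPipe estimate A_CB_Est, m²), Y is tree leaf area (m²) or
#' leaf dry mass (kg), Elevation is the response at X = 1 m², and CF is the
#' lognormal back-transformation bias correction. It optionally carries a
#' 95% prediction-interval approximation (see Details) and a soft predictor
#' range outside which predictions warn.
#'
#' Two interval forms are supported, both on the ln scale with u = ln(X):
#' the `quadratic` form dPI(u) = c0 + c1 u + c2 u², used for the mixed-model
#' allometries, and the `ls` form dPI(u) = c0 c1 sqrt(1 + 1/c2 +
#' (u - c3)²/c4) — the exact ordinary-least-squares prediction interval with
#' c0 the t quantile, c1 the residual SE, c2 = n, c3 the mean and c4 the sum
#' of squares of u in the calibration data. Bounds are exp(ln Y_uncorrected
#' ± dPI); by default the CF-corrected point estimate is reported alongside
#' bounds centred on the uncorrected (median-scale) prediction, the
#' regression's natural scale — set `cf_in_interval = TRUE` in
#' [predict_interval()] to scale the bounds by CF as well.
#'
#' @param response `"LA"` (leaf area, m²) or `"LM"` (leaf dry mass, kg).
#' @param predictor `"a_cb"` or `"a_cb_est"`.
#' @param elevation Response at predictor = 1 m² (> 0).
#' @param slope Dimensionless log-log slope.
#' @param cf Correction factor (>= 1).
#' @param scope `"pooled"`, `"per-pft"` or `"site-specific"`.
#' @param pft PFT the entry applies to (per-PFT scope only).
#' @param n Calibration sample size.
#' @param pi Optional interval approximation from [pi_approximation()].
#' @param range Soft calibration range of the predictor (m², length 2).
#' @param label Human-readable label.
#' @return A `qpipe_allometry` object.
#' @export
allometry <- function(response, predictor, elevation, slope, cf = 1,
                      scope = "site-specific", pft = NA_character_,
                      n = NA_integer_, pi = NULL, range = c(1e-5, 1),
                      label = NULL) {
  response <- match.arg(response, c("LA", "LM"))
  predictor <- match.arg(predictor, c("a_cb", "a_cb_est"))
  scope <- match.arg(scope, c("pooled", "per-pft", "site-specific"))
  stopifnot(is.finite(elevation), elevation > 0, is.finite(slope), cf >= 1)
  structure(
    list(
      response = response, predictor = predictor, scope = scope, pft = pft,
      elevation = elevation, slope = slope, cf = cf, n = n,
      pi = pi, range = range,
      label = label %||% sprintf("%s ~ %s (%s)", response, predictor, scope)
    ),
    class = "qpipe_allometry"
  )
}

#' @rdname allometry
#' @param form `"quadratic"` or `"ls"`.
#' @param c0,c1,c2,c3,c4 Coefficients; the quadratic form uses c0..c2 only.
#' @param residual_se Residual SE of the approximation fit (stored, unused).
#' @export
pi_approximation <- function(form, c0, c1, c2, c3 = NA_real_, c4 = NA_real_,
                             residual_se = NA_real_) {
  form <- match.arg(form, c("quadratic", "ls"))
  if (form == "ls" && (!is.finite(c3) || !is.finite(c4))) {
    abort("the ls form needs all of c0..c4.", class = "qpipe_config_error")
  }
  structure(
    list(
      form = form, c0 = c0, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
      residual_se = residual_se
    ),
    class = "qpipe_pi"
  )
}

#' @export
print.qpipe_allometry <- function(x, ...) {
  cat(sprintf(
    "%s: Y = %.4g x %.4g x X^%.4g  [%s%s, n = %s]\n",
    x$label, x$cf, x$elevation, x$slope, x$scope,
    if (!is.na(x$pft)) paste0("/", x$pft) else "", x$n
  ))
  invisible(x)
}

#' Predict from a power-law allometry
#'
#' @param object A `qpipe_allometry`.
#' @param x Predictor area(s), m² (> 0).
#' @param ... Unused.
#' @return CF-corrected point prediction(s), response units.
#' @examples
#' reg <- qpipe_registry()
#' predict(reg$qpipe_la_pooled, 1) # CF x Elevation
#' @export
predict.qpipe_allometry <- function(object, x, ...) {
  if (any(!is.finite(x) | x <= 0)) {
    abort("predictor `x` must be strictly positive.", class = "qpipe_domain_error")
  }
  object$cf * object$elevation * x^object$slope
}

# ln-scale interval half-width at u = ln(x)
delta_pi <- function(pi, u) {
  if (is.null(pi)) abort("no prediction-interval approximation attached.", class = "qpipe_config_error")
  d <- if (pi$form == "quadratic") {
    pi$c0 + pi$c1 * u + pi$c2 * u^2
  } else {
    pi$c0 * pi$c1 * sqrt(1 + 1 / pi$c2 + (u - pi$c3)^2 / pi$c4)
  }
  if (any(d < 0)) abort("negative interval half-width; check coefficients.", class = "qpipe_config_error")
  d
}

#' Point prediction with 95% prediction interval
#'
#' @param a A `qpipe_allometry` carrying a PI approximation.
#' @param x Predictor area(s), m².
#' @param cf_in_interval Multiply the bounds by CF too (default FALSE: the
#'   bounds bracket the uncorrected ln-scale prediction, the point estimate
#'   is CF-corrected).
#' @param warn_extrapolation Warn when `x` leaves the calibration range
#'   (default TRUE).
#' @return A tibble with columns `x`, `point`, `lower`, `upper`, `delta_pi`.
#' @export
predict_interval <- function(a, x, cf_in_interval = FALSE, warn_extrapolation = TRUE) {
  if (any(!is.finite(x) | x <= 0)) {
    abort("predictor `x` must be strictly positive.", class = "qpipe_domain_error")
  }
  if (warn_extrapolation && !is.null(a$range) &&
    any(x < a$range[1] | x > a$range[2])) {
    warn(sprintf(
      "%d value(s) outside the calibration range [%.3g, %.3g] m²; extrapolating.",
      sum(x < a$range[1] | x > a$range[2]), a$range[1], a$range[2]
    ))
  }
  u <- log(x)
  mu <- log(a$elevation) + a$slope * u # uncorrected ln-scale prediction
  d <- delta_pi(a$pi, u)
  k <- if (cf_in_interval) a$cf else 1
  tibble::tibble(
    x = x,
    point = a$cf * exp(mu),
    lower = k * exp(mu - d),
    upper = k * exp(mu + d),
    delta_pi = d
  )
}

#' Per-tree leaf area / leaf mass estimates from a registry
#'
#' Computes each tree's qPipe predictor A_CB_Est (or uses the measured
#' A_CB), selects the pooled entry (leaf area) or the tree's PFT entry
#' (leaf mass) from the registry, and returns point estimates with 95%
#' prediction intervals.
#'
#' @param trees A tree tibble.
#' @param response `"LA"` or `"LM"`.
#' @param registry A `qpipe_registry` (default: the shipped global
#'   coefficients, [qpipe_registry()]).
#' @param predictor `"a_cb_est"` (default) or `"a_cb"` (requires measured
#'   crown-base areas).
#' @param warn_extrapolation Passed to [predict_interval()].
#' @return A tibble: `tree_id`, `species`, `pft`, `x` (predictor, m²),
#'   `entry`, `point`, `lower`, `upper`.
#' @examples
#' trees <- tibble::tibble(
#'   species = "Abies", pft = "EC", a_bh = 0.04,
#'   height = 15, crown_base_height = 8
#' )
#' estimate_trees(trees, "LA")
#' @export
estimate_trees <- function(trees, response = c("LA", "LM"),
                           registry = qpipe_registry(),
                           predictor = c("a_cb_est", "a_cb"),
                           warn_extrapolation = FALSE) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  trees <- add_crown_metrics(trees)
  xs <- if (predictor == "a_cb_est") trees$a_cb_est else trees$a_cb
  if (predictor == "a_cb" && any(is.na(xs))) {
    abort(
      paste0(
        "measured a_cb missing for tree(s): ",
        paste(head(trees$tree_id[is.na(xs)], 5), collapse = ", ")
      ),
      class = "qpipe_record_error"
    )
  }

  pick <- function(pft) registry_entry(registry, response, predictor, pft)
  entries <- if (response == "LA") {
    e <- pick(NA)
    rep(list(e), nrow(trees))
  } else {
    purrr::map(trees$pft, pick)
  }
  preds <- purrr::map2(entries, xs, function(e, x) {
    predict_interval(e, x, warn_extrapolation = warn_extrapolation)
  })
  tibble::tibble(
    tree_id = trees$tree_id,
    species = trees$species,
    pft = trees$pft,
    x = xs,
    entry = purrr::map_chr(entries, "label"),
    point = purrr::map_dbl(preds, "point"),
    lower = purrr::map_dbl(preds, "lower"),
    upper = purrr::map_dbl(preds, "upper")
  )
}

#' Fit a site-specific power-law allometry from tree measurements
#'
#' Runs the Model I path: candidate fits (OLS, OLS + PFT, species random
#' intercept, random intercept + PFT) on ln(response) ~ ln(predictor),
#' AIC selection with failed candidates discarded, CF from the winning
#' fit's residual sd, and a 95% prediction-interval approximation. For an
#' OLS winner the exact least-squares interval coefficients are stored (the
#' `ls` form); for a mixed-model winner pointwise intervals (fixed-effect
#' uncertainty + between-species + residual variance, normal quantile) are
#' computed across the observed predictor range and approximated by least
#' squares with the quadratic form.
#'
#' @param trees A tree tibble with the requested response measured.
#' @param response `"LA"` or `"LM"`.
#' @param predictor `"a_cb_est"` or `"a_cb"`.
#' @param scope Stored on the result (default `"site-specific"`).
#' @param try_pft Also try PFT as a fixed effect when several PFTs are
#'   present (default TRUE).
#' @param grubbs Apply iterative Grubbs filtering to the ln-scale response
#'   residuals about a provisional OLS line, per PFT, before fitting
#'   (default FALSE).
#' @param alpha Grubbs significance level.
#' @return A `qpipe_allometry` with the selected `qpipe_model1` fit attached
#'   as attribute `"fit"`.
#' @export
fit_allometry <- function(trees, response = c("LA", "LM"),
                          predictor = c("a_cb_est", "a_cb"),
                          scope = "site-specific", try_pft = TRUE,
                          grubbs = FALSE, alpha = 0.05) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  trees <- add_crown_metrics(trees)
  ycol <- if (response == "LA") "leaf_area" else "leaf_mass"
  xs <- if (predictor == "a_cb_est") trees$a_cb_est else trees$a_cb
  d <- tibble::tibble(
    lx = log(xs), ly = log(trees[[ycol]]),
    species = trees$species, pft = trees$pft
  )
  d <- d[complete.cases(d), ]
  if (nrow(d) < 10) {
    abort(sprintf("need >= 10 trees with %s measured (got %d).", ycol, nrow(d)),
      class = "qpipe_degenerate_error"
    )
  }
  if (grubbs) {
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$pft), function(ii) {
      if (length(ii) < 3) return(ii)
      res <- stats::residuals(lm(ly ~ lx, data = d[ii, ]))
      ii[grubbs_filter(res, alpha = alpha)$kept_indices]
    }))
    d <- d[sort(keep), ]
  }

  try_fit <- function(expr) tryCatch(expr, error = function(e) NULL)
  cands <- list(try_fit(fit_ols(d, lx, ly)))
  if (length(unique(d$species)) > 1) {
    cands <- c(cands, list(try_fit(fit_random_intercept(d, lx, ly, species))))
  }
  if (try_pft && length(unique(d$pft)) > 1) {
    cands <- c(cands, list(try_fit(fit_ols(d, lx, ly, fixed = pft))))
    if (length(unique(d$species)) > 1) {
      cands <- c(cands, list(
        try_fit(fit_random_intercept(d, lx, ly, species, fixed = pft))
      ))
    }
  }
  best <- select_model(cands)

  cf <- correction_factor(best$residual_sd)
  pi <- fit_pi_approximation(best, d$lx)
  out <- allometry(
    response = response, predictor = predictor,
    elevation = exp(best$intercept), slope = best$slope, cf = cf,
    scope = scope,
    pft = if (length(unique(d$pft)) == 1) unique(d$pft) else NA_character_,
    n = best$n, pi = pi, range = range(exp(d$lx)),
    label = sprintf("%s ~ %s (%s, fitted)", response, predictor, scope)
  )
  attr(out, "fit") <- best
  out
}

# Exact OLS interval coefficients, or a least-squares quadratic fit to
# pointwise mixed-model intervals over the observed ln-predictor range.
fit_pi_approximation <- function(fit, lx) {
  n <- fit$n
  if (fit$method == "ols" && is.null(fit$fixed)) {
    return(pi_approximation(
      form = "ls",
      c0 = qt(0.975, fit$df_residual),
      c1 = fit$residual_sd,
      c2 = n,
      c3 = mean(lx),
      c4 = sum((lx - mean(lx))^2)
    ))
  }
  u <- seq(min(lx), max(lx), length.out = 200)
  var_fixed <- fit$intercept_se^2 + u^2 * fit$slope_se^2
  sd_pred <- sqrt(fit$residual_sd^2 + fit$species_sd^2 + var_fixed)
  d <- qnorm(0.975) * sd_pred
  qfit <- lm(d ~ u + I(u^2))
  cf3 <- coef(qfit)
  pi_approximation(
    form = "quadratic", c0 = cf3[[1]], c1 = cf3[[2]], c2 = cf3[[3]],
    residual_se = summary(qfit)$sigma
  )
}
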