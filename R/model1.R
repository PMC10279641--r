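#' Log-transform bias correction factor
#'
#' Back-transforming a ln-scale regression with exp() estimates the median,
#' not the mean, of the response; under lognormal residuals the arithmetic
#' mean is recovered by multiplying by CF = exp(sigma²/2), where sigma is the
#' residual standard deviation of the ln-scale fit.
#'
#' @param residual_sd Residual standard deviation on the natural-log scale
#'   (>= 0).
#' @return Correction factor CF >= 1 (1 when `residual_sd` is 0).
#' @examples
#' correction_factor(0)      # 1
#' correction_factor(0.3855) # ~1.077
#' @export
correction_factor <- function(residual_sd) {
  if (any(!is.finite(residual_sd) | residual_sd < 0)) {
    abort("`residual_sd` must be non-negative.", class = "qpipe_domain_error")
  }
  exp(residual_sd^2 / 2)
}

#' Model I (prediction) fits on log-log allometric data
#'
#' `fit_ols()` fits ordinary least squares of ln(response) on ln(predictor);
#' `fit_random_intercept()` adds a species random intercept (Gaussian mixed
#' model), the structure selected for most of the global leaf-mass and
#' leaf-area allometries. Variance components come from the REML fit while
#' the reported AIC comes from a full maximum-likelihood refit, so AICs are
#' comparable across fixed-effect structures and with `fit_ols()`.
#'
#' Both return a `qpipe_model1` object carrying the ln-scale intercept and
#' slope with standard errors, residual sd, AIC, the bias correction factor
#' CF = exp(sd²/2), and — for the mixed model — the species-intercept
#' standard deviation. [fit_allometry()] wraps these into a power-law
#' prediction equation with intervals.
#'
#' @param data A data frame.
#' @param x,y Ln-scale predictor and response columns (unquoted or strings).
#' @param species Species column for the random intercept.
#' @param fixed Optional extra fixed-effect column (e.g. PFT) entering as a
#'   categorical covariate; used for AIC-based structure comparison.
#' @return A `qpipe_model1` object with `tidy()` and `glance()` methods.
#' @examples
#' d <- data.frame(x = log(1:20), y = 1.2 * log(1:20) + log(500))
#' glance(fit_ols(d, x, y))
#' @export
fit_ols <- function(data, x, y, fixed = NULL) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  fq <- rlang::enquo(fixed)
  f_name <- if (rlang::quo_is_null(fq)) NULL else rlang::as_name(fq)

  d <- model1_frame(data, x_name, y_name, f_name = f_name)
  if (nrow(d) < 3) abort("need at least 3 complete observations.", class = "qpipe_degenerate_error")
  if (var(d$x) == 0) abort("zero predictor variance.", class = "qpipe_degenerate_error")

  form <- if (is.null(f_name)) y ~ x else y ~ x + fixed
  fit <- lm(form, data = d)
  s <- summary(fit)
  sigma <- s$sigma
  est <- coef(s)
  new_model1(
    method = "ols",
    intercept = est["(Intercept)", "Estimate"],
    intercept_se = est["(Intercept)", "Std. Error"],
    slope = est["x", "Estimate"],
    slope_se = est["x", "Std. Error"],
    residual_sd = sigma,
    species_sd = 0,
    aic = AIC(fit),
    n = nrow(d),
    df_residual = fit$df.residual,
    n_parameters = length(coef(fit)) + 1,
    fixed = f_name,
    fit = fit,
    data = d
  )
}

#' @rdname fit_ols
#' @export
fit_random_intercept <- function(data, x, y, species, fixed = NULL) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  sp_name <- rlang::as_name(rlang::enquo(species))
  fq <- rlang::enquo(fixed)
  f_name <- if (rlang::quo_is_null(fq)) NULL else rlang::as_name(fq)

  d <- model1_frame(data, x_name, y_name, sp_name = sp_name, f_name = f_name)
  if (nrow(d) < 3) abort("need at least 3 complete observations.", class = "qpipe_degenerate_error")
  if (length(unique(d$species)) < 2) {
    # no between-species information: the model degenerates to plain OLS
    out <- if (is.null(f_name)) fit_ols(d, x, y) else fit_ols(d, x, y, fixed = "fixed")
    out$method <- "random_intercept"
    return(out)
  }

  form <- if (is.null(f_name)) y ~ x + (1 | species) else y ~ x + fixed + (1 | species)
  reml <- tryCatch(
    lme4::lmer(form, data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) abort(paste0("mixed model failed: ", conditionMessage(e)),
      class = "qpipe_convergence_error"
    )
  )
  ml <- tryCatch(
    lme4::lmer(form, data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) abort(paste0("mixed model (ML refit) failed: ", conditionMessage(e)),
      class = "qpipe_convergence_error"
    )
  )
  msgs <- unlist(reml@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
    abort("mixed model failed to converge.", class = "qpipe_convergence_error")
  }

  vc <- as.data.frame(lme4::VarCorr(reml))
  species_sd <- vc$sdcor[vc$grp == "species"][1]
  sigma <- vc$sdcor[vc$grp == "Residual"][1]
  fe <- lme4::fixef(reml)
  se <- sqrt(diag(as.matrix(vcov(reml))))
  new_model1(
    method = "random_intercept",
    intercept = unname(fe["(Intercept)"]),
    intercept_se = unname(se[1]),
    slope = unname(fe["x"]),
    slope_se = unname(se[2]),
    residual_sd = sigma,
    species_sd = species_sd,
    aic = AIC(ml),
    n = nrow(d),
    df_residual = nrow(d) - length(fe),
    n_parameters = length(fe) + 2,
    fixed = f_name,
    fit = reml,
    data = d
  )
}

model1_frame <- function(data, x_name, y_name, sp_name = NULL, f_name = NULL) {
  d <- tibble::tibble(x = data[[x_name]], y = data[[y_name]])
  if (!is.null(sp_name)) d$species <- as.character(data[[sp_name]])
  if (!is.null(f_name)) d$fixed <- as.character(data[[f_name]])
  d[complete.cases(d), ]
}

new_model1 <- function(...) {
  structure(list(...), class = "qpipe_model1")
}

#' @export
print.qpipe_model1 <- function(x, ...) {
  cat(sprintf(
    "Model I fit (%s): ln(y) = %.4f + %.4f ln(x)%s\n",
    x$method, x$intercept, x$slope,
    if (x$species_sd > 0) sprintf(" + species (sd %.3f)", x$species_sd) else ""
  ))
  cat(sprintf(
    "  residual sd %.4f | CF %.4f | AIC %.2f | n %d\n",
    x$residual_sd, correction_factor(x$residual_sd), x$aic, x$n
  ))
  invisible(x)
}

#' @rdname fit_ols
#' @param x For the tidiers: a `qpipe_model1` object.
#' @param ... Unused.
#' @method tidy qpipe_model1
#' @export
tidy.qpipe_model1 <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @rdname fit_ols
#' @method glance qpipe_model1
#' @export
glance.qpipe_model1 <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    slope = x$slope,
    elevation = exp(x$intercept),
    residual_sd = x$residual_sd,
    species_sd = x$species_sd,
    cf = correction_factor(x$residual_sd),
    aic = x$aic,
    n = x$n
  )
}

#' Select the minimum-AIC model
#'
#' Failed fits (entries that are `NULL` or inherit from `try-error` /
#' condition objects) are dropped before comparison, mirroring the practice
#' of discarding non-converged candidates irrespective of AIC. Ties within
#' 1e-9 go to the candidate with fewer parameters.
#'
#' @param candidates A list of `qpipe_model1` fits (possibly with failures).
#' @return The winning fit.
#' @export
select_model <- function(candidates) {
  ok <- purrr::keep(candidates, ~ inherits(.x, "qpipe_model1"))
  if (length(ok) == 0) abort("no successfully fitted candidate models.", class = "qpipe_domain_error")
  aics <- purrr::map_dbl(ok, "aic")
  npar <- purrr::map_dbl(ok, "n_parameters")
  best <- which(aics <= min(aics) + 1e-9)
  ok[[best[which.min(npar[best])]]]
}

#' Iterative Grubbs outlier filtering
#'
#' Repeatedly applies the two-sided Grubbs test: the most extreme value is
#' removed whenever G = max|v - mean| / sd exceeds the critical value
#' ((n-1)/sqrt(n))·sqrt(t² / (n-2+t²)) with t the (1 - alpha/(2n)) quantile
#' of the t distribution on n-2 df, until no outlier remains or fewer than 3
#' values are left. Ties break on first occurrence, so the result is
#' deterministic in input order.
#'
#' @param values Numeric vector (residual-like quantities), n >= 3.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list of class `qpipe_grubbs`: `kept_indices`,
#'   `removed_indices` (in removal order), `statistics` (G at each
#'   iteration), `alpha`.
#' @examples
#' grubbs_filter(c(1, 1, 1, 1, 10))$removed_indices  # 5
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  if (length(values) < 3) abort("need at least 3 values.", class = "qpipe_domain_error")
  if (any(!is.finite(values))) abort("`values` must be finite.", class = "qpipe_domain_error")
  idx <- seq_along(values)
  removed <- integer(0)
  stats <- numeric(0)
  repeat {
    v <- values[idx]
    n <- length(v)
    if (n < 3) break
    s <- sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    i_max <- which.max(dev) # first occurrence on ties
    G <- dev[i_max] / s
    stats <- c(stats, G)
    if (G > grubbs_critical(n, alpha)) {
      removed <- c(removed, idx[i_max])
      idx <- idx[-i_max]
    } else {
      break
    }
  }
  structure(
    list(
      kept_indices = idx, removed_indices = removed,
      statistics = stats, alpha = alpha
    ),
    class = "qpipe_grubbs"
  )
}

#' @rdname grubbs_filter
#' @param n Sample size.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}
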