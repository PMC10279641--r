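#' Plot an SMA fit
#'
#' Scatter of the ln-scale data with the fitted SMA line per group, drawn
#' over each group's own predictor range.
#'
#' @param object A `qpipe_sma` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qpipe_sma
#' @export
autoplot.qpipe_sma <- function(object, ...) {
  d <- object$data
  ranges <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(xmin = min(.data$x), xmax = max(.data$x))
  r <- dplyr::left_join(object$groups, ranges, by = "group")
  ends <- as.vector(rbind(r$xmin, r$xmax))
  lines <- tibble::tibble(
    group = rep(r$group, each = 2),
    x = ends,
    y = rep(r$intercept, each = 2) + rep(r$slope, each = 2) * ends
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = lines, linewidth = 0.8) +
    ggplot2::labs(
      x = paste0("ln ", object$x), y = paste0("ln ", object$y),
      colour = object$group_var %||% NULL,
      title = "SMA (Model II) allometry"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a power-law allometry with its 95% prediction band
#'
#' @param object A `qpipe_allometry` with a PI approximation.
#' @param xlim Predictor range (m²); defaults to the entry's calibration
#'   range.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot on log-log axes.
#' @method autoplot qpipe_allometry
#' @export
autoplot.qpipe_allometry <- function(object, xlim = NULL, n_grid = 200, ...) {
  xlim <- xlim %||% object$range
  xs <- exp(seq(log(xlim[1]), log(xlim[2]), length.out = n_grid))
  band <- predict_interval(object, xs, warn_extrapolation = FALSE)
  ggplot2::ggplot(band, ggplot2::aes(.data$x, .data$point)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.7
    ) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sprintf("%s (m²)", toupper(object$predictor)),
      y = sprintf("%s (%s)", object$response, if (object$response == "LA") "m²" else "kg"),
      title = object$label,
      subtitle = sprintf(
        "Y = %.3f x %.4g x X^%.3f, 95%% prediction band",
        object$cf, object$elevation, object$slope
      )
    ) +
    ggplot2::theme_minimal()
}

#' Taper-error diagnostic plot
#'
#' Trees placed against the reference stem-taper curves (cone X = 1,
#' paraboloid X = 2, cubic X = 3) on the relative crown length / relative
#' area plane; points above the paraboloid line are overestimated by the
#' qPipe assumption, points below underestimated.
#'
#' @param trees A tree tibble with measured crown-base areas, or the output
#'   of [taper_diagnose()].
#' @return A ggplot.
#' @export
plot_taper_error <- function(trees) {
  diag <- if (all(c("rel_crown_length", "rel_area") %in% names(trees))) {
    trees
  } else {
    taper_diagnose(trees)
  }
  l_grid <- seq(0.01, 1, length.out = 200)
  curves <- purrr::list_rbind(purrr::map(c(1, 2, 3), function(xv) {
    tibble::tibble(
      l = l_grid, a = taper_relative_area(l_grid, xv),
      curve = sprintf("X = %d", xv)
    )
  }))
  ggplot2::ggplot(diag, ggplot2::aes(.data$rel_crown_length, .data$rel_area)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$l, .data$a, linetype = .data$curve),
      colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rel_error > 1), alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "overestimated", `FALSE` = "underestimated"),
      name = "qPipe A_CB"
    ) +
    ggplot2::labs(
      x = "relative crown length l", y = expression(A[CB] / A[BH]),
      title = "Stem taper vs the paraboloid assumption"
    ) +
    ggplot2::theme_minimal()
}

#' Plot stand estimates with 95% bounds
#'
#' @param object A `qpipe_stand` or the tibble from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qpipe_stand
#' @export
autoplot.qpipe_stand <- function(object, ...) {
  tbl <- tidy(object)
  tbl$method <- object$source
  plot_stand_tbl(tbl)
}

plot_stand_tbl <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$method, .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(
      x = NULL,
      y = if (all(tbl$quantity == "LAI")) "LAI (m²/m²)" else "leaf biomass (kg/m²)",
      title = "Stand estimate with propagated 95% bounds"
    ) +
    ggplot2::theme_minimal()
}
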