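#' Convert stem diameter to cross-sectional area
#'
#' Areas are the canonical internal size representation: diameters read from
#' inventories are converted once at ingest via these helpers.
#'
#' @param d Stem diameter in m (vectorised).
#' @return Cross-sectional area in m².
#' @examples
#' area_from_diameter(0.1)            # 0.00785 m²
#' diameter_from_area(area_from_diameter(0.3))
#' @export
area_from_diameter <- function(d) {
  if (any(!is.finite(d) | d <= 0)) {
    abort("`d` must be strictly positive and finite.", class = "qpipe_domain_error")
  }
  pi * d^2 / 4
}

#' @rdname area_from_diameter
#' @param a Cross-sectional area in m² (vectorised).
#' @export
diameter_from_area <- function(a) {
  if (any(!is.finite(a) | a <= 0)) {
    abort("`a` must be strictly positive and finite.", class = "qpipe_domain_error")
  }
  2 * sqrt(a / pi)
}

#' Crown ratio and the qPipe crown-base area estimate
#'
#' The crown ratio R_CROWN is the crown length L_C = H - crown-base height
#' divided by the stem length above breast height, H - 1.3 m. Under the
#' assumption that the stem between treetop and breast height is a paraboloid
#' of revolution with apex at the treetop, the stem cross-sectional area at
#' the crown base is A_BH x R_CROWN; this product is the qPipe estimator
#' A_CB_Est, computable entirely from the ground.
#'
#' @param height Total tree height H, m. Must exceed 1.3 m.
#' @param crown_base_height Height of the crown base, m, in [1.3, height).
#' @return `crown_ratio()`: dimensionless ratio in (0, 1].
#' @examples
#' crown_ratio(15, 8)                # 7 / 13.7
#' estimate_acb(0.04, 15, 8)         # m²
#' @export
crown_ratio <- function(height, crown_base_height) {
  if (any(!is.finite(height) | height <= BREAST_HEIGHT)) {
    abort("`height` must exceed breast height (1.3 m).", class = "qpipe_domain_error")
  }
  bad <- !is.finite(crown_base_height) |
    crown_base_height < BREAST_HEIGHT | crown_base_height >= height
  if (any(bad)) {
    abort(
      "`crown_base_height` must lie in [1.3, height); a crown base at the treetop means no crown.",
      class = "qpipe_domain_error"
    )
  }
  (height - crown_base_height) / (height - BREAST_HEIGHT)
}

#' @rdname crown_ratio
#' @param a_bh Stem cross-sectional area at breast height, m².
#' @return `estimate_acb()`: estimated crown-base area A_CB_Est, m²;
#'   never exceeds `a_bh`.
#' @export
estimate_acb <- function(a_bh, height, crown_base_height) {
  if (any(!is.finite(a_bh) | a_bh <= 0)) {
    abort("`a_bh` must be strictly positive.", class = "qpipe_domain_error")
  }
  a_bh * crown_ratio(height, crown_base_height)
}

#' Relative stem-taper profile
#'
#' The stem between breast height and treetop is described on relative scales
#' by A = L^(2/X), where L is the distance from the treetop (L = 1 at breast
#' height), A the cross-sectional area relative to the breast-height area,
#' and X the taper exponent: X = 1 is a cone, X = 2 a paraboloid of
#' revolution (the qPipe assumption), X = 3 a cubic solid of revolution.
#'
#' @param l Relative distance from the treetop, in (0, 1].
#' @param x Taper exponent X > 0.
#' @return Relative cross-sectional area in (0, 1].
#' @examples
#' taper_relative_area(0.5, 1)   # cone: 0.25
#' taper_relative_area(0.5, 2)   # paraboloid: 0.5
#' @export
taper_relative_area <- function(l, x) {
  if (any(!is.finite(l) | l <= 0 | l > 1)) {
    abort("`l` must lie in (0, 1].", class = "qpipe_domain_error")
  }
  if (any(!is.finite(x) | x <= 0)) {
    abort("taper exponent `x` must be > 0.", class = "qpipe_domain_error")
  }
  l^(2 / x)
}

#' Relative error of the qPipe crown-base area estimate
#'
#' For a stem with true taper exponent X, the qPipe estimator (which assumes
#' X = 2) yields A_CB_Est / A_CB = l^(1 - 2/X) at relative crown length l.
#' The ratio exceeds 1 (overestimate) for X < 2, equals 1 at X = 2, and is
#' below 1 (underestimate) for X > 2.
#'
#' @param l Relative crown length, in (0, 1]. At l = 1 the ratio is exactly 1
#'   for any X (crown base at breast height).
#' @param x True taper exponent X > 0.
#' @return Ratio A_CB_Est / A_CB.
#' @export
qpipe_relative_error <- function(l, x) {
  if (any(!is.finite(l) | l <= 0 | l > 1)) {
    abort("`l` must lie in (0, 1].", class = "qpipe_domain_error")
  }
  if (any(!is.finite(x) | x <= 0)) {
    abort("taper exponent `x` must be > 0.", class = "qpipe_domain_error")
  }
  l^(1 - 2 / x)
}

#' Taper exponent implied by an observed relative area
#'
#' Inverts A = L^(2/X): a tree observed at relative crown length `l` with
#' relative crown-base area `a` = A_CB / A_BH lies on the taper curve with
#' X = 2 ln(l) / ln(a). Used to place field trees against the cone /
#' paraboloid / cubic reference curves.
#'
#' @param l Relative crown length, in (0, 1) strictly.
#' @param a Relative crown-base area A_CB / A_BH, in (0, 1) strictly.
#' @return Taper exponent X > 0.
#' @export
taper_exponent_from_observation <- function(l, a) {
  if (any(!is.finite(l) | l <= 0 | l >= 1)) {
    abort("`l` must lie strictly inside (0, 1); X is undefined at l = 1.",
      class = "qpipe_domain_error"
    )
  }
  if (any(!is.finite(a) | a <= 0 | a >= 1)) {
    abort("`a` must lie strictly inside (0, 1); X is undefined at a = 1.",
      class = "qpipe_domain_error"
    )
  }
  2 * log(l) / log(a)
}

#' Per-tree taper diagnostics for an inventory
#'
#' For trees carrying a measured crown-base area, computes the relative crown
#' length, the implied taper exponent X, and the relative error of the qPipe
#' estimate, one row per usable tree.
#'
#' @param trees A tree tibble (see [as_tree_tbl()]).
#' @return A tibble with columns `tree_id`, `species`, `pft`,
#'   `rel_crown_length`, `rel_area`, `taper_x`, `rel_error`.
#' @export
taper_diagnose <- function(trees) {
  trees <- as_tree_tbl(trees)
  usable <- trees |>
    dplyr::filter(!is.na(.data$a_cb)) |>
    dplyr::mutate(
      rel_crown_length = crown_ratio(.data$height, .data$crown_base_height),
      rel_area = .data$a_cb / .data$a_bh
    ) |>
    dplyr::filter(.data$rel_crown_length < 1, .data$rel_area < 1, .data$rel_area > 0)
  dropped <- sum(!is.na(trees$a_cb)) - nrow(usable)
  if (dropped > 0) {
    inform(sprintf("taper_diagnose: %d tree(s) on the domain boundary dropped.", dropped))
  }
  usable |>
    dplyr::mutate(
      taper_x = taper_exponent_from_observation(.data$rel_crown_length, .data$rel_area),
      rel_error = qpipe_relative_error(.data$rel_crown_length, .data$taper_x)
    ) |>
    dplyr::select(
      "tree_id", "species", "pft",
      "rel_crown_length", "rel_area", "taper_x", "rel_error"
    )
}
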