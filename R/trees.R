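#' Canonical tree inventory tibble
#'
#' All higher-level functions operate on a "tree tibble": one row per tree
#' with columns
#' \describe{
#'   \item{tree_id}{unique identifier (character)}
#'   \item{species}{species label}
#'   \item{pft}{plant functional type: one of EC, DC, EB, DB (evergreen /
#'     deciduous crossed with conifer / broadleaf)}
#'   \item{a_bh}{stem cross-sectional area at breast height (1.3 m), m²}
#'   \item{height}{total tree height, m (> 1.3)}
#'   \item{crown_base_height}{height of the crown base, m, in [1.3, height)}
#'   \item{a_cb}{optional measured crown-base cross-sectional area, m² (NA if
#'     not climbed)}
#'   \item{leaf_area}{optional one-sided (projected for conifers) leaf area,
#'     m²}
#'   \item{leaf_mass}{optional leaf dry mass, kg}
#' }
#' `as_tree_tbl()` validates these invariants and fails with the offending
#' tree ids; a `dbh` column (m) is accepted in place of `a_bh` and converted.
#'
#' @param x A data frame with the columns above.
#' @return A tibble with the canonical columns, invariants checked.
#' @export
as_tree_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"a_bh" %in% names(x) && "dbh" %in% names(x)) {
    x$a_bh <- area_from_diameter(x$dbh)
  }
  required <- c("species", "pft", "a_bh", "height", "crown_base_height")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("tree table lacks required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "qpipe_schema_error"
    )
  }
  if (!"tree_id" %in% names(x)) x$tree_id <- as.character(seq_len(nrow(x)))
  x$tree_id <- as.character(x$tree_id)
  for (opt in c("a_cb", "leaf_area", "leaf_mass")) {
    if (!opt %in% names(x)) x[[opt]] <- NA_real_
  }
  x$pft <- as.character(x$pft)

  bad_pft <- !x$pft %in% PFT_LEVELS
  bad_height <- !is.finite(x$height) | x$height <= BREAST_HEIGHT
  bad_cb <- !is.finite(x$crown_base_height) |
    x$crown_base_height < BREAST_HEIGHT | x$crown_base_height >= x$height
  bad_pos <- !is.finite(x$a_bh) | x$a_bh <= 0
  for (col in c("a_cb", "leaf_area", "leaf_mass")) {
    bad_pos <- bad_pos | (!is.na(x[[col]]) & x[[col]] <= 0)
  }
  bad <- bad_pft | bad_height | bad_cb | bad_pos
  if (any(bad)) {
    abort(
      paste0(
        "invalid tree record(s): ",
        paste(utils::head(x$tree_id[bad], 5), collapse = ", "),
        if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else "",
        ". Required: pft in {EC, DC, EB, DB}; height > 1.3 m; ",
        "1.3 <= crown_base_height < height; areas/masses > 0."
      ),
      class = "qpipe_record_error"
    )
  }
  cols <- c(
    "tree_id", "species", "pft", "a_bh", "height", "crown_base_height",
    "a_cb", "leaf_area", "leaf_mass"
  )
  x[, c(cols, setdiff(names(x), c(cols, "dbh")))]
}

#' Add crown ratio and qPipe crown-base area columns
#'
#' Convenience verb: appends `crown_ratio` and `a_cb_est` (the qPipe
#' estimate, m²) to a tree tibble.
#'
#' @param trees A tree tibble (see [as_tree_tbl()]).
#' @return The tibble with two extra columns.
#' @examples
#' trees <- tibble::tibble(
#'   species = "Abies", pft = "EC", a_bh = 0.04,
#'   height = 15, crown_base_height = 8
#' )
#' add_crown_metrics(trees)
#' @export
add_crown_metrics <- function(trees) {
  trees <- as_tree_tbl(trees)
  trees |>
    dplyr::mutate(
      crown_ratio = crown_ratio(.data$height, .data$crown_base_height),
      a_cb_est = .data$a_bh * .data$crown_ratio
    )
}
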