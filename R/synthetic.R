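#' Seeded synthetic tree generator
#'
#' Generates multi-species, multi-PFT tree inventories with known ground
#' truth, emulating the structure the allometric analyses assume: a
#' power-law leaf-area relation against the true crown-base area with
#' lognormal residuals and ln-scale Gaussian species intercept offsets;
#' per-tree stem-taper exponents X scattered around the paraboloid value 2
#' so the qPipe estimate errs by l^(1 - 2/X); and a tree-level LMA
#' increasing with height, LMA = base_lma x (height / href)^gamma, which
#' makes leaf-mass slopes exceed leaf-area slopes whenever gamma > 0.
#'
#' Distribution choices (heights lognormal about an allometric
#' diameter-height curve, crown ratios Beta, X lognormal around 2) are for
#' positivity and realistic skew; all are overridable. One global seed
#' drives a per-tree counter-based stream, so any subset of trees is
#' reproducible independently of the rest.
#'
#' @param n_trees Number of trees.
#' @param n_species Number of species, allocated round-robin across `pfts`.
#' @param pfts PFTs to include.
#' @param dbh_meanlog,dbh_sdlog Lognormal DBH (m) parameters.
#' @param height_coef,height_exp,height_sdlog Height model
#'   H = 1.3 + coef x dbh^exp x lognormal noise (m).
#' @param crown_shape1,crown_shape2 Beta parameters of the crown ratio.
#' @param taper_meanlog,taper_sdlog Lognormal taper exponent X (default
#'   centred on 2, the paraboloid).
#' @param la_elevation,la_slope True leaf-area allometry vs the true
#'   crown-base area (m² at 1 m²; dimensionless).
#' @param residual_sdlog Ln-scale residual sd of leaf area.
#' @param species_sdlog Ln-scale sd of species intercept offsets.
#' @param base_lma LMA (kg/m²) of a reference-height tree.
#' @param lma_href Reference height (m) for the LMA gradient.
#' @param lma_gamma LMA-height exponent gamma >= 0 (0 = constant LMA).
#' @param seed Integer seed; required for reproducibility.
#' @return A tree tibble with extra ground-truth columns (`crown_ratio_true`,
#'   `taper_x`, `species_offset`, `lma`) and the full configuration in
#'   `attr(, "config")`. Measured `a_cb` is the true crown-base area from the
#'   drawn taper curve, `leaf_area`/`leaf_mass` the true responses.
#' @examples
#' trees <- simulate_trees(n_trees = 50, seed = 1)
#' all(trees$a_cb <= trees$a_bh)
#' @export
simulate_trees <- function(n_trees = 500, n_species = 20,
                           pfts = c("EC", "DC", "EB", "DB"),
                           dbh_meanlog = log(0.12), dbh_sdlog = 0.6,
                           height_coef = 25, height_exp = 0.65,
                           height_sdlog = 0.10,
                           crown_shape1 = 5, crown_shape2 = 3,
                           taper_meanlog = log(2), taper_sdlog = 0.15,
                           la_elevation = 2400, la_slope = 1.0,
                           residual_sdlog = 0.30, species_sdlog = 0.30,
                           base_lma = 0.10, lma_href = 10, lma_gamma = 0.25,
                           seed = NULL) {
  cfg <- list(
    n_trees = n_trees, n_species = n_species, pfts = pfts,
    dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
    height_coef = height_coef, height_exp = height_exp,
    height_sdlog = height_sdlog,
    crown_shape1 = crown_shape1, crown_shape2 = crown_shape2,
    taper_meanlog = taper_meanlog, taper_sdlog = taper_sdlog,
    la_elevation = la_elevation, la_slope = la_slope,
    residual_sdlog = residual_sdlog, species_sdlog = species_sdlog,
    base_lma = base_lma, lma_href = lma_href, lma_gamma = lma_gamma,
    seed = seed
  )
  validate_sim_config(cfg)

  species_ids <- seq_len(n_species)
  species_pft <- pfts[(species_ids - 1) %% length(pfts) + 1]
  species_offset <- vapply(species_ids, function(s) {
    with_stream_seed(seed, 10^6 + s, rnorm(1, 0, species_sdlog))
  }, numeric(1))

  rows <- purrr::map(seq_len(n_trees), function(i) {
    draws <- with_stream_seed(seed, i, {
      list(
        sp = sample.int(n_species, 1),
        dbh = rlnorm(1, dbh_meanlog, dbh_sdlog),
        h_noise = rlnorm(1, 0, height_sdlog),
        cr = rbeta(1, crown_shape1, crown_shape2),
        x = rlnorm(1, taper_meanlog, taper_sdlog),
        la_noise = rlnorm(1, 0, residual_sdlog)
      )
    })
    sp <- draws$sp
    dbh <- draws$dbh
    height <- BREAST_HEIGHT + height_coef * dbh^height_exp * draws$h_noise
    cr <- min(max(draws$cr, 0.02), 0.98)
    a_bh <- area_from_diameter(dbh)
    a_cb <- a_bh * taper_relative_area(cr, draws$x)
    la <- la_elevation * a_cb^la_slope * exp(species_offset[sp]) * draws$la_noise
    lma <- base_lma * (height / lma_href)^lma_gamma
    tibble::tibble(
      tree_id = as.character(i),
      species = sprintf("sp%02d", sp),
      pft = species_pft[sp],
      a_bh = a_bh,
      height = height,
      crown_base_height = height - cr * (height - BREAST_HEIGHT),
      a_cb = a_cb,
      leaf_area = la,
      leaf_mass = lma * la,
      crown_ratio_true = cr,
      taper_x = draws$x,
      species_offset = species_offset[sp],
      lma = lma
    )
  })
  out <- as_tree_tbl(purrr::list_rbind(rows))
  attr(out, "config") <- cfg
  out
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (is.null(seed) || !is.finite(seed)) {
      abort("a finite integer `seed` is required.", class = "qpipe_config_error")
    }
    if (n_trees < 1 || n_species < 1) {
      abort("`n_trees` and `n_species` must be >= 1.", class = "qpipe_config_error")
    }
    if (any(c(dbh_sdlog, height_sdlog, taper_sdlog, residual_sdlog, species_sdlog) < 0)) {
      abort("all sd parameters must be >= 0.", class = "qpipe_config_error")
    }
    if (lma_gamma < 0) abort("`lma_gamma` must be >= 0.", class = "qpipe_config_error")
    if (any(!pfts %in% PFT_LEVELS)) {
      abort("`pfts` must be drawn from EC, DC, EB, DB.", class = "qpipe_config_error")
    }
    if (height_coef <= 0 || base_lma <= 0 || la_elevation <= 0 || lma_href <= 0) {
      abort("scale parameters must be > 0.", class = "qpipe_config_error")
    }
  })
  invisible(cfg)
}

# Counter-based substream: a deterministic 31-bit seed per (seed, counter)
# pair, restoring the caller's RNG state afterwards.
with_stream_seed <- function(seed, counter, expr) {
  sub <- (as.double(seed) * 48271 + as.double(counter) * 2654435761) %% 2147483647
  sub <- as.integer(sub) + 1L
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub)
  force(expr)
}

#' Simulate a stand
#'
#' Wraps [simulate_trees()] with a ground area so the result can go
#' straight into [estimate_stand()]. The true LAI (sum of generated leaf
#' areas over area) is attached for coverage checks.
#'
#' @param ... Passed to [simulate_trees()].
#' @param area Ground area, m² (> 0).
#' @return A list with elements `trees`, `area`, `true_lai`,
#'   `true_biomass`.
#' @export
simulate_stand <- function(..., area) {
  if (!is.finite(area) || area <= 0) {
    abort("`area` must be > 0 m².", class = "qpipe_config_error")
  }
  trees <- simulate_trees(...)
  list(
    trees = trees,
    area = area,
    true_lai = sum(trees$leaf_area) / area,
    true_biomass = sum(trees$leaf_mass) / area
  )
}
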