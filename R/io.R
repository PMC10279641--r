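#' Column map for reading tree inventories
#'
#' Inventories come from many sources with their own headers and units; a
#' column map declares which source column holds each canonical field and
#' what unit it uses. At least `species`, one breast-height size (`dbh` or
#' `a_bh`), `height` and `crown_base_height` must be mapped; `pft` may
#' instead be derived from mapped `leaf_habit` (evergreen/deciduous) and
#' `leaf_form` (broadleaf/conifer) columns.
#'
#' @param species,height,crown_base_height Required source column names.
#' @param pft Source column holding EC/DC/EB/DB labels, or NULL to derive.
#' @param leaf_habit,leaf_form Columns for deriving the PFT when `pft` is
#'   unmapped (values starting with e/d and b/c respectively,
#'   case-insensitive).
#' @param dbh,a_bh Breast-height size column (exactly one required).
#' @param d_cb,a_cb Optional measured crown-base size column.
#' @param leaf_area,leaf_mass Optional leaf measurement columns.
#' @param monocot Optional logical/0-1 flag column marking monocots (palms)
#'   for exclusion.
#' @param tree_id Optional identifier column.
#' @param units Named list overriding default units: lengths `"m"` or
#'   `"cm"`, areas `"m2"` or `"cm2"`, mass `"kg"` or `"g"`. Defaults: m, m²,
#'   kg everywhere.
#' @return A `qpipe_column_map`.
#' @export
qpipe_column_map <- function(species = "species",
                             height = "height",
                             crown_base_height = "crown_base_height",
                             pft = "pft",
                             leaf_habit = NULL, leaf_form = NULL,
                             dbh = NULL, a_bh = "a_bh",
                             d_cb = NULL, a_cb = "a_cb",
                             leaf_area = "leaf_area", leaf_mass = "leaf_mass",
                             monocot = NULL, tree_id = "tree_id",
                             units = list()) {
  map <- list(
    species = species, height = height, crown_base_height = crown_base_height,
    pft = pft, leaf_habit = leaf_habit, leaf_form = leaf_form,
    dbh = dbh, a_bh = a_bh, d_cb = d_cb, a_cb = a_cb,
    leaf_area = leaf_area, leaf_mass = leaf_mass,
    monocot = monocot, tree_id = tree_id
  )
  if (is.null(map$dbh) && is.null(map$a_bh)) {
    abort("map one breast-height size column (`dbh` or `a_bh`).", class = "qpipe_config_error")
  }
  if (is.null(map$pft) && (is.null(map$leaf_habit) || is.null(map$leaf_form))) {
    abort("map `pft`, or both `leaf_habit` and `leaf_form`.", class = "qpipe_config_error")
  }
  defaults <- list(
    dbh = "m", a_bh = "m2", height = "m", crown_base_height = "m",
    d_cb = "m", a_cb = "m2", leaf_area = "m2", leaf_mass = "kg"
  )
  structure(
    list(map = map, units = utils::modifyList(defaults, units)),
    class = "qpipe_column_map"
  )
}

#' @rdname qpipe_column_map
#' @param path YAML file with top-level `columns` and optional `units`
#'   maps.
#' @export
read_column_map <- function(path) {
  raw <- yaml::read_yaml(path)
  cols <- raw$columns %||% raw
  args <- cols[!purrr::map_lgl(cols, is.null)]
  args$units <- raw$units %||% list()
  # unmapped optional columns must be explicit NULLs, not defaults
  for (opt in c("pft", "a_bh", "a_cb", "leaf_area", "leaf_mass", "tree_id")) {
    if (!opt %in% names(cols)) args[[opt]] <- NULL
  }
  defaults <- list(pft = NULL, a_bh = NULL, a_cb = NULL,
    leaf_area = NULL, leaf_mass = NULL, tree_id = NULL)
  do.call(qpipe_column_map, utils::modifyList(defaults, args))
}

unit_factor <- function(unit, kind) {
  ok <- switch(kind,
    length = c(m = 1, cm = 0.01),
    area = c(m2 = 1, cm2 = 1e-4),
    mass = c(kg = 1, g = 1e-3)
  )
  if (!unit %in% names(ok)) {
    abort(sprintf("unsupported %s unit '%s' (use %s).", kind, unit,
      paste(names(ok), collapse = "/")), class = "qpipe_config_error")
  }
  unname(ok[unit])
}

#' Read and filter a tree inventory file
#'
#' Reads delimited text (delimiter auto-detected among comma, tab and
#' semicolon unless given), applies the column map with unit normalisation,
#' and enforces the inclusion rules: tree height strictly greater than
#' 1.3 m; crown-base height between 1.3 m and the tree height (exclusive at
#' the top — a crown base at the treetop means no crown); a positive
#' breast-height size; at least one of leaf area / leaf mass recorded when
#' `require_leaf = TRUE`; and no monocot flag. Removed rows are tallied per
#' rule (each row counted under the first rule it fails).
#'
#' @param path Inventory file.
#' @param map A [qpipe_column_map()]; default assumes canonical headers.
#' @param delim Field delimiter; NULL (default) auto-detects.
#' @param require_leaf Drop trees with neither leaf area nor leaf mass
#'   (default TRUE, the calibration-data rule; set FALSE for prediction
#'   inventories).
#' @param monocot_species Character vector of species labels to exclude as
#'   monocots, in addition to any mapped flag column.
#' @return A tree tibble; the filter tally is attached as attribute
#'   `"filter_report"` and retrievable with [filter_report()].
#' @export
read_inventory <- function(path, map = qpipe_column_map(), delim = NULL,
                           require_leaf = TRUE, monocot_species = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "qpipe_io_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- c(",", "\t", ";")[which.max(c(
      lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
      lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
      lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
    ))]
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, na = c("", "NA", "na", "NaN")
  )
  m <- map$map
  required <- c("species", "height", "crown_base_height")
  if (!is.null(m$pft)) required <- c(required, "pft") else required <- c(required, "leaf_habit", "leaf_form")
  required <- c(required, if (!is.null(m$a_bh) && is.null(m$dbh)) "a_bh" else "dbh")
  for (field in required) {
    col <- m[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(sprintf("required column '%s' (canonical field '%s') not in file.",
        col %||% "<unmapped>", field), class = "qpipe_schema_error")
    }
  }

  num_field <- function(field, kind) {
    col <- m[[field]]
    if (is.null(col) || !col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("unparseable numeric in column '%s', data row %d ('%s').",
        col, bad[1], v[bad[1]]), class = "qpipe_parse_error")
    }
    parsed * unit_factor(map$units[[field]], kind)
  }

  d <- tibble::tibble(
    tree_id = if (!is.null(m$tree_id) && m$tree_id %in% names(raw)) {
      as.character(raw[[m$tree_id]])
    } else {
      as.character(seq_len(nrow(raw)))
    },
    species = as.character(raw[[m$species]]),
    height = num_field("height", "length"),
    crown_base_height = num_field("crown_base_height", "length")
  )
  d$a_bh <- if (!is.null(m$a_bh) && m$a_bh %in% names(raw)) {
    num_field("a_bh", "area")
  } else {
    area_from_diameter_safe(num_field("dbh", "length"))
  }
  d$a_cb <- if (!is.null(m$a_cb) && m$a_cb %in% names(raw)) {
    num_field("a_cb", "area")
  } else if (!is.null(m$d_cb)) {
    area_from_diameter_safe(num_field("d_cb", "length"))
  } else {
    NA_real_
  }
  d$leaf_area <- num_field("leaf_area", "area")
  d$leaf_mass <- num_field("leaf_mass", "mass")
  d$pft <- if (!is.null(m$pft)) {
    toupper(as.character(raw[[m$pft]]))
  } else {
    habit <- substr(tolower(as.character(raw[[m$leaf_habit]])), 1, 1)
    form <- substr(tolower(as.character(raw[[m$leaf_form]])), 1, 1)
    paste0(toupper(habit), ifelse(form == "b", "B", ifelse(form == "c", "C", "?")))
  }
  is_monocot <- rep(FALSE, nrow(d))
  if (!is.null(m$monocot) && m$monocot %in% names(raw)) {
    flag <- tolower(as.character(raw[[m$monocot]]))
    is_monocot <- flag %in% c("true", "t", "1", "yes", "y")
  }
  if (!is.null(monocot_species)) {
    is_monocot <- is_monocot | d$species %in% monocot_species
  }

  rules <- list(
    monocot = is_monocot,
    height_not_above_breast = !is.finite(d$height) | d$height <= BREAST_HEIGHT,
    crown_base_out_of_range = !is.finite(d$crown_base_height) |
      d$crown_base_height < BREAST_HEIGHT | d$crown_base_height >= d$height,
    missing_breast_height_size = !is.finite(d$a_bh) | d$a_bh <= 0,
    no_leaf_measure = if (require_leaf) is.na(d$leaf_area) & is.na(d$leaf_mass) else rep(FALSE, nrow(d)),
    invalid_pft = !d$pft %in% PFT_LEVELS
  )
  removed_by <- rep(NA_character_, nrow(d))
  for (rule in names(rules)) {
    hit <- rules[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  kept <- d[is.na(removed_by), ]
  report <- list(
    rules = tibble::tibble(
      rule = names(rules),
      removed = vapply(names(rules), function(r) sum(removed_by == r, na.rm = TRUE), integer(1), USE.NAMES = FALSE)
    ),
    input = nrow(d),
    retained = nrow(kept),
    retained_by_pft = dplyr::count(kept, .data$pft, name = "n"),
    retained_by_species = dplyr::count(kept, .data$species, name = "n")
  )
  out <- if (nrow(kept) > 0) as_tree_tbl(kept) else kept
  attr(out, "filter_report") <- report
  out
}

area_from_diameter_safe <- function(d) {
  ifelse(is.finite(d) & d > 0, pi * d^2 / 4, NA_real_)
}

#' @rdname read_inventory
#' @param trees A tree tibble returned by [read_inventory()].
#' @export
filter_report <- function(trees) {
  rep <- attr(trees, "filter_report")
  if (is.null(rep)) abort("no filter report attached.", class = "qpipe_domain_error")
  rep
}

#' Write a tree inventory (and optional ground-truth sidecar)
#'
#' Writes the canonical columns as delimited text readable by
#' [read_inventory()] with the default column map. For simulated data the
#' generator configuration can be written alongside as a YAML sidecar.
#'
#' @param trees A tree tibble.
#' @param path Output file; `.csv` writes comma-separated, otherwise tab.
#' @param truth_path Optional sidecar path for the `attr(trees, "config")`
#'   ground truth.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(trees, path, truth_path = NULL) {
  cfg <- attr(trees, "config")
  trees <- as_tree_tbl(trees)
  attr(trees, "config") <- cfg
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(trees, path)
  } else {
    readr::write_tsv(trees, path)
  }
  if (!is.null(truth_path)) {
    cfg <- attr(trees, "config")
    if (is.null(cfg)) {
      warn("no ground-truth config attached; sidecar not written.")
    } else {
      yaml::write_yaml(cfg, truth_path)
    }
  }
  invisible(path)
}
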