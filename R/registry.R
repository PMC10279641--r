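#' The shipped registry of global qPipe / pipe allometric coefficients
#'
#' Population-level prediction equations established on a compiled global
#' dataset of 962 trees (159 species, four PFTs) spanning tropical to boreal
#' forests: pooled leaf-area allometries for the pipe (measured A_CB) and
#' qPipe (A_CB_Est) predictors, and per-PFT qPipe leaf-mass allometries,
#' each with its 95% prediction-interval approximation. Leaf area was
#' pooled across PFTs (PFT was not selected as a predictor in Model I
#' regression); leaf mass separates by PFT.
#'
#' The same constants ship as a human-editable YAML file
#' (`system.file("extdata", "global_allometries.yml", package = "qpipe")`),
#' the format accepted by [read_registry()] for site-specific equations.
#'
#' @return A `qpipe_registry`: a named list of [allometry()] entries with
#'   keys `pipe_la_pooled`, `qpipe_la_pooled`, `qpipe_lm_EC`, `qpipe_lm_DC`,
#'   `qpipe_lm_EB`, `qpipe_lm_DB`.
#' @examples
#' tidy(qpipe_registry())
#' @export
qpipe_registry <- function() {
  entries <- list(
    pipe_la_pooled = allometry(
      response = "LA", predictor = "a_cb", scope = "pooled",
      elevation = 2370, slope = 0.940, cf = 1.065, n = 768L,
      pi = pi_approximation("quadratic", 0.71655, 0.00590, 0.00052,
        residual_se = 0.00002
      ),
      range = c(1e-5, 1), label = "global pipe LA (pooled PFTs)"
    ),
    qpipe_la_pooled = allometry(
      response = "LA", predictor = "a_cb_est", scope = "pooled",
      elevation = 2742, slope = 0.955, cf = 1.077, n = 768L,
      pi = pi_approximation("quadratic", 0.77894, 0.00622, 0.00054,
        residual_se = 0.00002
      ),
      range = c(1e-5, 1), label = "global qPipe LA (pooled PFTs)"
    ),
    qpipe_lm_EC = allometry(
      response = "LM", predictor = "a_cb_est", scope = "per-pft", pft = "EC",
      elevation = 854.4, slope = 1.078, cf = 1.023, n = 221L,
      pi = pi_approximation("quadratic", 0.48920, 0.01772, 0.00181,
        residual_se = 0.00002
      ),
      range = c(1e-5, 1), label = "global qPipe LM (EC)"
    ),
    qpipe_lm_DC = allometry(
      response = "LM", predictor = "a_cb_est", scope = "per-pft", pft = "DC",
      elevation = 571.4, slope = 1.172, cf = 1.059, n = 57L,
      pi = pi_approximation("ls",
        c0 = 2.004, c1 = 0.3389, c2 = 57, c3 = -5.206, c4 = 62.89
      ),
      range = c(1e-5, 1), label = "global qPipe LM (DC)"
    ),
    qpipe_lm_EB = allometry(
      response = "LM", predictor = "a_cb_est", scope = "per-pft", pft = "EB",
      elevation = 293.8, slope = 0.973, cf = 1.073, n = 447L,
      pi = pi_approximation("quadratic", 0.78223, 0.01286, 0.00112,
        residual_se = 0.00007
      ),
      range = c(1e-5, 1), label = "global qPipe LM (EB)"
    ),
    qpipe_lm_DB = allometry(
      response = "LM", predictor = "a_cb_est", scope = "per-pft", pft = "DB",
      elevation = 180.3, slope = 1.017, cf = 1.073, n = 227L,
      pi = pi_approximation("quadratic", 0.81205, 0.01924, 0.00159,
        residual_se = 0.00007
      ),
      range = c(1e-5, 1), label = "global qPipe LM (DB)"
    )
  )
  structure(entries, class = "qpipe_registry")
}

registry_entry <- function(registry, response, predictor, pft = NA) {
  cand <- purrr::keep(registry, function(e) {
    e$response == response && e$predictor == predictor
  })
  per_pft <- purrr::keep(cand, function(e) {
    e$scope == "per-pft" && !is.na(pft) && identical(e$pft, pft)
  })
  hit <- if (length(per_pft) > 0) per_pft else purrr::keep(cand, ~ .x$scope != "per-pft")
  if (length(hit) == 0) {
    valid <- unique(stats::na.omit(purrr::map_chr(registry, "pft")))
    abort(
      sprintf(
        "no registry entry for %s ~ %s%s; PFTs available: %s.",
        response, predictor,
        if (!is.na(pft)) paste0(" (pft ", pft, ")") else "",
        paste(valid, collapse = ", ")
      ),
      class = "qpipe_registry_error"
    )
  }
  hit[[1]]
}

#' @export
print.qpipe_registry <- function(x, ...) {
  cat(sprintf("qpipe registry: %d allometries\n", length(x)))
  for (e in x) print(e)
  invisible(x)
}

#' @rdname qpipe_registry
#' @param x A `qpipe_registry`.
#' @param ... Unused.
#' @method tidy qpipe_registry
#' @export
tidy.qpipe_registry <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x, function(e, key) {
    tibble::tibble(
      key = key, label = e$label, response = e$response,
      predictor = e$predictor, scope = e$scope, pft = e$pft,
      elevation = e$elevation, slope = e$slope, cf = e$cf, n = e$n,
      pi_form = if (is.null(e$pi)) NA_character_ else e$pi$form,
      c0 = e$pi$c0 %||% NA_real_, c1 = e$pi$c1 %||% NA_real_,
      c2 = e$pi$c2 %||% NA_real_, c3 = e$pi$c3 %||% NA_real_,
      c4 = e$pi$c4 %||% NA_real_
    )
  }))
}

#' Read or write a registry as YAML
#'
#' Site-specific allometries can be supplied in the same file format as the
#' shipped global registry: a top-level `allometries` map keyed by entry
#' name, each with `response`, `predictor`, `scope`, optional `pft`,
#' `elevation`, `slope`, `cf`, `n`, optional `range` and an optional `pi`
#' block (`form`, `c0`..`c4`).
#'
#' @param path File path.
#' @return `read_registry()`: a `qpipe_registry`.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$allometries)) {
    abort("registry file lacks a top-level `allometries` map.", class = "qpipe_config_error")
  }
  entries <- purrr::map(raw$allometries, function(e) {
    pi <- if (!is.null(e$pi)) {
      pi_approximation(
        form = e$pi$form, c0 = e$pi$c0, c1 = e$pi$c1, c2 = e$pi$c2,
        c3 = e$pi$c3 %||% NA_real_, c4 = e$pi$c4 %||% NA_real_,
        residual_se = e$pi$residual_se %||% NA_real_
      )
    }
    allometry(
      response = e$response, predictor = e$predictor,
      elevation = e$elevation, slope = e$slope, cf = e$cf %||% 1,
      scope = e$scope %||% "site-specific", pft = e$pft %||% NA_character_,
      n = e$n %||% NA_integer_, pi = pi,
      range = unlist(e$range) %||% c(1e-5, 1), label = e$label %||% NULL
    )
  })
  structure(entries, class = "qpipe_registry")
}

#' @rdname read_registry
#' @param registry A `qpipe_registry`.
#' @export
write_registry <- function(registry, path) {
  as_list <- purrr::map(registry, function(e) {
    out <- list(
      label = e$label, response = e$response, predictor = e$predictor,
      scope = e$scope, elevation = e$elevation, slope = e$slope,
      cf = e$cf, n = e$n, range = as.numeric(e$range)
    )
    if (!is.na(e$pft)) out$pft <- e$pft
    if (!is.null(e$pi)) {
      pi <- e$pi
      out$pi <- Filter(
        function(v) !is.null(v) && !all(is.na(v)),
        list(
          form = pi$form, c0 = pi$c0, c1 = pi$c1, c2 = pi$c2,
          c3 = pi$c3, c4 = pi$c4, residual_se = pi$residual_se
        )
      )
    }
    out
  })
  yaml::write_yaml(list(allometries = as_list), path)
  invisible(path)
}
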