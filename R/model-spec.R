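#' Specify an SCR model
#'
#' A model specification names the terms entering each submodel's linear
#' predictor: density (log link, per-km^2 intensity), baseline encounter rate
#' `lambda0` (log link) and half-normal scale `sigma` (log link).  The sex
#' mixture proportion `psi` (logit link) is always part of the model because
#' detected individuals' sexes are observed.  Allowed terms follow the study
#' design: `session` and `forest` on density; `session`, `effort`, `road`,
#' `sex`, `forest` on detection; `sex` on sigma.  `effort` is a mandatory
#' design covariate on detection, and `sex` must enter detection and sigma
#' jointly or not at all (scale and baseline rate trade off, so a sex effect
#' is only interpretable on both).
#'
#' @param density,detection,sigma One-sided formulas (or character vectors)
#'   of term names.
#' @return An object of class `scr_model_spec`.
#' @examples
#' scr_model_spec(~ session + forest, ~ session + effort + sex, ~ sex)
#' @export
scr_model_spec <- function(density = ~session, detection = ~ session + effort,
                           sigma = ~1) {
  parse_terms <- function(x) {
    if (inherits(x, "formula")) return(all.vars(x))
    as.character(x)
  }
  d <- parse_terms(density)
  p <- parse_terms(detection)
  s <- parse_terms(sigma)
  if (!all(d %in% c("session", "forest"))) {
    abort("density terms must be a subset of {session, forest}",
          class = "foxscr_error_spec")
  }
  if (!all(p %in% c("session", "effort", "road", "sex", "forest"))) {
    abort("detection terms must be a subset of {session, effort, road, sex, forest}",
          class = "foxscr_error_spec")
  }
  if (!all(s %in% "sex")) {
    abort("sigma terms must be a subset of {sex}", class = "foxscr_error_spec")
  }
  if (!"effort" %in% p) {
    abort("`effort` is a study-design covariate and must be included on detection",
          class = "foxscr_error_spec")
  }
  if (("sex" %in% p) != ("sex" %in% s)) {
    abort("`sex` must appear on detection and sigma jointly or not at all",
          class = "foxscr_error_spec")
  }
  order_terms <- function(x, ref) ref[ref %in% x]
  d <- order_terms(d, c("session", "forest"))
  p <- order_terms(p, c("session", "effort", "road", "sex", "forest"))
  s <- order_terms(s, "sex")
  structure(
    list(density = d, detection = p, sigma = s,
         label = spec_label(d, p, s)),
    class = "scr_model_spec"
  )
}

spec_label <- function(d, p, s) {
  fmt <- function(x) if (length(x) == 0) "1" else paste(x, collapse = "+")
  sprintf("D~%s p0~%s sigma~%s", fmt(d), fmt(p), fmt(s))
}

#' @export
print.scr_model_spec <- function(x, ...) {
  cat("<scr_model_spec>", x$label, "\n")
  invisible(x)
}

has_sex <- function(spec) "sex" %in% spec$detection

#' Candidate model set over the design covariates
#'
#' Builds the 16 extensions of the base design model (session effects on
#' density and detection, search effort on detection) formed by all
#' combinations of four optional components: forest on density, road on
#' detection, forest on detection, and sex jointly on detection and sigma.
#'
#' @param base The base [scr_model_spec()]; must include `session` on density
#'   and detection and `effort` on detection.
#' @return A named list of 16 `scr_model_spec` objects.
#' @export
candidate_set <- function(base = scr_model_spec()) {
  if (!"session" %in% base$density || !"session" %in% base$detection ||
      !"effort" %in% base$detection) {
    abort("the base model must include session on D and p0 and effort on p0",
          class = "foxscr_error_spec")
  }
  grid <- expand.grid(
    forest_d = c(FALSE, TRUE), road_p = c(FALSE, TRUE),
    forest_p = c(FALSE, TRUE), sex = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE
  )
  specs <- purrr::pmap(grid, function(forest_d, road_p, forest_p, sex) {
    scr_model_spec(
      density = c(base$density, if (forest_d) "forest"),
      detection = c(base$detection, if (road_p) "road",
                    if (forest_p) "forest", if (sex) "sex"),
      sigma = c(base$sigma, if (sex) "sex")
    )
  })
  names(specs) <- purrr::map_chr(specs, "label")
  specs
}

# Parameter layout (names and block membership) for a spec with S sessions.
param_layout <- function(spec, session_labels) {
  S <- length(session_labels)
  d_names <- if ("session" %in% spec$density && S > 1) {
    paste0("D.", session_labels)
  } else "D.(Intercept)"
  if ("forest" %in% spec$density) d_names <- c(d_names, "D.forest")
  p_names <- if ("session" %in% spec$detection && S > 1) {
    paste0("p0.", session_labels)
  } else "p0.(Intercept)"
  p_names <- c(p_names,
               "p0.effort",
               if ("road" %in% spec$detection) "p0.road",
               if ("forest" %in% spec$detection) "p0.forest",
               if ("sex" %in% spec$detection) "p0.sexM")
  s_names <- c("logsigma.(Intercept)",
               if ("sex" %in% spec$sigma) "logsigma.sexM")
  list(
    names = c(d_names, p_names, s_names, "psi.logitM"),
    d = d_names, p = p_names, s = s_names, psi = "psi.logitM"
  )
}
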