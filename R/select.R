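#' Fit a set of candidate models
#'
#' Fits each specification in turn.  With `warm_start = TRUE` the first
#' (base) model's estimates seed the remaining fits (shared parameters are
#' copied by name, new parameters start at zero), which speeds up screening
#' without changing any optimum.
#'
#' @inheritParams fit_scr
#' @param specs Named list of [scr_model_spec()] objects, e.g. from
#'   [candidate_set()].
#' @param warm_start Seed each fit from the first fit's estimates.
#' @param hessian Compute covariance matrices for every candidate (slow); the
#'   retained model can be refitted with `hessian = TRUE` afterwards.
#' @return A named list of `scr_fit` objects.
#' @export
fit_candidates <- function(encounters, state, detectors,
                           specs = candidate_set(), warm_start = TRUE,
                           hessian = FALSE, standardize = TRUE,
                           control = list()) {
  encounters <- as_encounters(encounters)
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  base_coef <- NULL
  for (i in seq_along(specs)) {
    start <- NULL
    if (warm_start && !is.null(base_coef)) {
      template <- scr_params(specs[[i]], purrr::map_chr(encounters, "session"))
      shared <- intersect(names(template), names(base_coef))
      template[shared] <- base_coef[shared]
      start <- template
    }
    fits[[i]] <- tryCatch(
      fit_scr(encounters, state, detectors, specs[[i]], start = start,
              hessian = hessian, standardize = standardize, control = control),
      foxscr_error_convergence = function(e) {
        warn(sprintf("model '%s' failed to fit: %s", names(specs)[i],
                     conditionMessage(e)))
        NULL
      }
    )
    if (i == 1 && !is.null(fits[[1]])) base_coef <- fits[[1]]$coefficients
  }
  fits[!purrr::map_lgl(fits, is.null)]
}

#' AIC model-selection table
#'
#' Ranks fitted candidate models by AIC, mirroring the usual comparison-table
#' layout: submodel formulas, parameter count, AIC and the difference to the
#' best model.  Non-converged fits are excluded with a warning; ties are
#' broken by fewer parameters, then by model label.
#'
#' @param fits List of `scr_fit` objects (e.g. from [fit_candidates()]).
#' @return A tibble of class `scr_model_table` with columns `model`,
#'   `density`, `detection`, `sigma`, `n_params`, `logLik`, `AIC`, `dAIC`.
#' @export
model_table <- function(fits) {
  ok <- purrr::map_lgl(fits, "converged")
  if (any(!ok)) {
    warn(sprintf("excluding %d non-converged model(s) from the table", sum(!ok)))
  }
  fits <- fits[ok]
  if (length(fits) == 0) {
    abort("no converged fits to tabulate", class = "foxscr_error_convergence")
  }
  fmt <- function(x) if (length(x) == 0) "~1" else paste(x, collapse = " + ")
  out <- purrr::map_dfr(fits, function(f) {
    tibble(
      model = f$spec$label,
      density = fmt(f$spec$density),
      detection = fmt(f$spec$detection),
      sigma = fmt(f$spec$sigma),
      n_params = f$n_params,
      logLik = f$loglik,
      AIC = f$aic
    )
  }) |>
    dplyr::arrange(.data$AIC, .data$n_params, .data$model) |>
    dplyr::mutate(dAIC = .data$AIC - min(.data$AIC))
  class(out) <- c("scr_model_table", class(out))
  out
}

#' Retained (minimum-AIC) model
#'
#' @param fits List of `scr_fit` objects.
#' @return The single `scr_fit` with the lowest AIC among converged fits.
#' @export
retained_model <- function(fits) {
  tab <- model_table(fits)
  labels <- purrr::map_chr(fits, function(f) f$spec$label)
  fits[[which(labels == tab$model[1])[1]]]
}
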