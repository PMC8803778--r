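#' Home-range area from the half-normal scale parameter
#'
#' Under the bivariate-normal space-use model implied by the half-normal
#' encounter function, the circular area containing a given fraction of an
#' individual's utilization distribution is `pi * sigma^2 * q`, where `q` is
#' the chi-square quantile with 2 degrees of freedom at that fraction
#' (`q = 5.99` at 95%).
#'
#' @param sigma Half-normal scale(s) in km, non-negative.
#' @param quantile Utilization fraction in (0, 1); default 0.95.
#' @return Area(s) in km^2.
#' @examples
#' home_range_area(1.63)  # ~50 km^2
#' @export
home_range_area <- function(sigma, quantile = 0.95) {
  if (any(quantile <= 0) || any(quantile >= 1)) {
    abort("`quantile` must be in (0, 1)", class = "foxscr_error_domain")
  }
  if (any(sigma < 0)) {
    abort("`sigma` must be non-negative", class = "foxscr_error_domain")
  }
  pi * sigma^2 * qchisq(quantile, df = 2)
}

#' Sex-specific space-use scale and home-range areas from a fit
#'
#' Back-transforms the log-sigma coefficients to sigma with Wald intervals on
#' the log scale, then maps sigma and its interval bounds through
#' [home_range_area()].
#'
#' @param fit An [fit_scr()] result (with a covariance matrix).
#' @param level Confidence level.
#' @param quantile Utilization fraction for the home-range area.
#' @return A tibble with columns `sex`, `sigma`, `sigma_low`, `sigma_high`,
#'   `area`, `area_low`, `area_high`.
#' @export
home_ranges <- function(fit, level = 0.95, quantile = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  g0 <- fit$coefficients[["logsigma.(Intercept)"]]
  with_sex <- "logsigma.sexM" %in% names(fit$coefficients)
  vc <- fit$vcov
  var_of <- function(w) {
    if (is.null(vc)) return(NA_real_)
    idx <- names(fit$coefficients) %in% names(w)
    wv <- setNames(numeric(sum(idx)), names(fit$coefficients)[idx])
    wv[names(w)] <- w
    as.numeric(t(wv) %*% vc[idx, idx, drop = FALSE] %*% wv)
  }
  rows <- if (with_sex) {
    gM <- fit$coefficients[["logsigma.sexM"]]
    list(
      list(sex = "F", est = g0, var = var_of(c("logsigma.(Intercept)" = 1))),
      list(sex = "M", est = g0 + gM,
           var = var_of(c("logsigma.(Intercept)" = 1, "logsigma.sexM" = 1)))
    )
  } else {
    list(list(sex = "all", est = g0, var = var_of(c("logsigma.(Intercept)" = 1))))
  }
  purrr::map_dfr(rows, function(r) {
    se <- sqrt(r$var)
    s <- exp(r$est)
    lo <- exp(r$est - z * se)
    hi <- exp(r$est + z * se)
    tibble(
      sex = r$sex, sigma = s, sigma_low = lo, sigma_high = hi,
      area = home_range_area(s, quantile),
      area_low = home_range_area(lo, quantile),
      area_high = home_range_area(hi, quantile)
    )
  })
}

# Fitted per-cell density (individuals / km^2) for one session.
predict_mu <- function(fit, state, session) {
  d_names <- fit$layout$d
  int_name <- if (length(fit$session_labels) > 1 &&
                  any(d_names == paste0("D.", session))) {
    paste0("D.", session)
  } else "D.(Intercept)"
  if (!int_name %in% d_names) {
    abort(sprintf("session '%s' is not part of this fit", session),
          class = "foxscr_error_config")
  }
  eta <- rep(fit$coefficients[[int_name]], nrow(state))
  for (tm in names(fit$state_scalers)) {
    col <- DENSITY_COLS[[tm]]
    z <- apply_scaler(state[[col]], fit$state_scalers[[tm]])
    eta <- eta + fit$coefficients[[paste0("D.", tm)]] * z
  }
  exp(eta)
}

new_density_surface <- function(state, density, kind, session) {
  a <- attr(state, "cell_area")
  out <- tibble(
    cell = state$cell, x = state$x, y = state$y,
    density = density, expected_n = density * a
  )
  attr(out, "kind") <- kind
  attr(out, "session") <- session
  attr(out, "cell_area") <- a
  attr(out, "resolution") <- attr(state, "resolution")
  attr(out, "extent") <- attr(state, "extent")
  class(out) <- c("scr_density_surface", class(out))
  out
}

#' Expected density surface from a fitted model
#'
#' Per-cell fitted AC intensity `mu_hat(g)` (individuals per km^2) for one
#' session.  Summing `expected_n = mu_hat * a` over a region gives the
#' expected abundance in that region.
#'
#' @param fit An [fit_scr()] result.
#' @param state The state space the model was fitted on.
#' @param session Session label (defaults to the first).
#' @return A tibble of class `scr_density_surface` with columns `cell`, `x`,
#'   `y`, `density`, `expected_n`.
#' @export
expected_density <- function(fit, state, session = fit$session_labels[1]) {
  new_density_surface(state, predict_mu(fit, state, session),
                      kind = "expected", session = session)
}

#' Realized density surface from a fitted model
#'
#' Per-cell expected number of activity centres given the observed data: the
#' sum of each detected individual's posterior AC distribution (Bayes' rule
#' over the state space) plus the expected contribution of undetected
#' individuals, `sum_c psi_c * mu(g) * a * (1 - p.(g, c))`.  The surface
#' totals `n_detected + expected undetected`.
#'
#' @inheritParams expected_density
#' @param encounters The encounter data used in fitting.
#' @param detectors The detector grid used in fitting.
#' @return A tibble of class `scr_density_surface` (density in
#'   individuals / km^2).
#' @export
realized_density <- function(fit, encounters, state, detectors,
                             session = fit$session_labels[1]) {
  ctx <- build_fit_context(as_encounters(encounters), state, detectors,
                           fit$spec, fit$standardize,
                           det_scalers = fit$det_scalers,
                           state_scalers = fit$state_scalers)
  s <- purrr::detect(ctx$sessions, function(x) x$session == session)
  if (is.null(s)) {
    abort(sprintf("session '%s' not found in encounter data", session),
          class = "foxscr_error_config")
  }
  par <- check_params(fit$coefficients, ctx$layout)
  pc <- session_param_pieces(par, ctx, s)
  post <- scr_session_posterior_core(
    s$D2, pc$log_mu_a, pc$log_lam0, pc$sigma, pc$log_psi,
    s$YD2, s$sex_code, pc$sex_specific
  )
  n <- s$n
  realized_n <- if (n > 0) rowSums(post[, seq_len(n), drop = FALSE]) else
    numeric(nrow(post))
  realized_n <- realized_n + post[, n + 1]
  new_density_surface(state, realized_n / ctx$cell_area,
                      kind = "realized", session = session)
}

#' Abundance in a region
#'
#' Sums expected activity-centre counts over the cells of a region.  For a
#' fitted model a Wald interval is added by the delta method on the log scale.
#'
#' @param x An `scr_density_surface` or an `scr_fit`.
#' @param ... Passed to methods.
#' @return A one-row tibble (`session`, `estimate`, plus `lower`/`upper` and
#'   `area_km2` for fits).
#' @export
abundance <- function(x, ...) UseMethod("abundance")

# Cells with centres inside a rectangular region (inclusive bounds).
region_cells <- function(state_xy, region) {
  if (is.null(region)) return(rep(TRUE, nrow(state_xy)))
  region <- as_extent(region)
  ok <- in_extent(state_xy$x, state_xy$y, region)
  if (!any(ok)) {
    abort("the region contains no state-space cells", class = "foxscr_error_config")
  }
  ok
}

#' @rdname abundance
#' @param region Rectangular region `c(x_min, x_max, y_min, y_max)` in km, or
#'   `NULL` for the whole surface.
#' @export
abundance.scr_density_surface <- function(x, region = NULL, ...) {
  keep <- region_cells(x, region)
  tibble(
    session = attr(x, "session") %||% NA_character_,
    estimate = sum(x$expected_n[keep])
  )
}

#' @rdname abundance
#' @param state State space used in fitting.
#' @param session Session label.
#' @param level Confidence level for the delta-method interval.
#' @export
abundance.scr_fit <- function(x, state, region = NULL,
                              session = x$session_labels[1], level = 0.95,
                              ...) {
  keep <- region_cells(state, region)
  a <- attr(state, "cell_area")
  log_N_of <- function(par) {
    f <- x
    f$coefficients <- setNames(par, names(x$coefficients))
    log(sum(predict_mu(f, state, session)[keep]) * a)
  }
  est <- exp(log_N_of(x$coefficients))
  lower <- upper <- NA_real_
  if (!is.null(x$vcov)) {
    g <- num_grad(log_N_of, x$coefficients)
    se <- sqrt(max(as.numeric(t(g) %*% x$vcov %*% g), 0))
    z <- qnorm(1 - (1 - level) / 2)
    lower <- est * exp(-z * se)
    upper <- est * exp(z * se)
  }
  tibble(session = session, estimate = est, lower = lower, upper = upper,
         area_km2 = sum(keep) * a)
}

#' Per-session sampling summary
#'
#' Summarises an NGS sample table the way field-survey reports tabulate it:
#' sample totals, species-confirmed and successfully genotyped counts,
#' identified individuals by sex, and the mean (2 decimals) and range of
#' samples per identified individual.
#'
#' @param samples Tibble with columns `session`, `sample_id`, and
#'   `individual_id` (`NA` when not genotyped); optionally logical
#'   `confirmed`, `genotyped` and a per-individual `sex`.
#' @return A tibble with one row per session.
#' @export
summarize_samples <- function(samples) {
  if (!"session" %in% names(samples)) samples$session <- "s1"
  if (!"genotyped" %in% names(samples)) {
    samples$genotyped <- !is.na(samples$individual_id)
  }
  if (!"confirmed" %in% names(samples)) samples$confirmed <- TRUE
  samples |>
    dplyr::group_by(.data$session) |>
    dplyr::group_modify(function(g, key) {
      gt <- g[g$genotyped & !is.na(g$individual_id), ]
      per_ind <- if (nrow(gt) > 0) table(gt$individual_id) else integer()
      ind_sex <- if ("sex" %in% names(gt) && nrow(gt) > 0) {
        tapply(gt$sex, gt$individual_id, function(s) s[1])
      } else character()
      tibble(
        n_samples = nrow(g),
        n_confirmed = sum(g$confirmed, na.rm = TRUE),
        n_genotyped = nrow(gt),
        n_individuals = length(per_ind),
        n_females = sum(ind_sex == "F", na.rm = TRUE),
        n_males = sum(ind_sex == "M", na.rm = TRUE),
        mean_samples = if (length(per_ind) > 0) {
          round_half_up(nrow(gt) / length(per_ind), 2)
        } else NA_real_,
        min_samples = if (length(per_ind) > 0) min(per_ind) else NA_integer_,
        max_samples = if (length(per_ind) > 0) max(per_ind) else NA_integer_
      )
    }) |>
    dplyr::ungroup()
}
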