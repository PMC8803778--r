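#' Fit an SCR model by maximum likelihood
#'
#' Maximises the multi-session marginal log-likelihood with BFGS.  Covariates
#' are z-scored internally (means and SDs are stored so predictions are on the
#' raw scale).  Standard errors come from the inverse observed information
#' (numerical Hessian at the optimum); Wald 95% intervals are formed on the
#' link scale and back-transformed where needed.
#'
#' @param encounters An `scr_encounters` object (or a single `scr_session`).
#' @param state State space from [build_state_space()].
#' @param detectors Detector grid (or per-session list) with the covariates
#'   the specification requires.
#' @param spec An [scr_model_spec()].
#' @param start Optional named start vector (see [scr_params()]); by default a
#'   data-driven start is used.
#' @param hessian Compute the Hessian / covariance matrix (skip for speed in
#'   candidate screening).
#' @param standardize z-score covariates before fitting.
#' @param control List: `maxit` (default 500), `reltol` (default 1e-10),
#'   `grad_tol` (gradient-norm threshold for the convergence flag, default
#'   0.1).
#' @return An object of class `scr_fit`.
#' @export
fit_scr <- function(encounters, state, detectors, spec = scr_model_spec(),
                    start = NULL, hessian = TRUE, standardize = TRUE,
                    control = list()) {
  ctx <- build_fit_context(as_encounters(encounters), state, detectors, spec,
                           standardize)
  maxit <- control$maxit %||% 500
  reltol <- control$reltol %||% 1e-10
  grad_tol <- control$grad_tol %||% 0.1

  nll <- function(par) {
    v <- -loglik_context(setNames(par, ctx$layout$names), ctx)
    if (!is.finite(v)) 1e10 else v
  }

  if (is.null(start)) {
    start <- default_start(ctx)
  } else {
    start <- check_params(start, ctx$layout)
  }
  if (nll(start) >= 1e10) {
    start <- fallback_start(ctx)
    if (nll(start) >= 1e10) {
      abort("log-likelihood is non-finite at both the default and fallback starts",
            class = "foxscr_error_convergence")
    }
  }

  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  par <- setNames(opt$par, ctx$layout$names)
  grad <- num_grad(nll, par)
  grad_max <- max(abs(grad))

  vc <- NULL
  if (hessian) {
    H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) dimnames(vc) <- list(names(par), names(par))
    }
  }
  converged <- opt$convergence == 0 && is.finite(opt$value) &&
    grad_max < grad_tol
  if (!converged) {
    warn(sprintf("fit did not converge (optim code %d, max |gradient| %.3g)",
                 opt$convergence, grad_max))
  }

  loglik <- -opt$value
  k <- length(par)
  structure(
    list(
      spec = spec,
      coefficients = par,
      loglik = loglik,
      n_params = k,
      aic = scr_aic(loglik, k),
      vcov = vc,
      converged = converged,
      grad_max = grad_max,
      optim = opt[c("convergence", "counts")],
      layout = ctx$layout,
      session_labels = ctx$session_labels,
      n_detected = purrr::map_int(ctx$sessions, "n"),
      det_scalers = ctx$det_scalers,
      state_scalers = ctx$state_scalers,
      standardize = ctx$standardize,
      cell_area = ctx$cell_area,
      start = start
    ),
    class = "scr_fit"
  )
}

scr_aic <- function(loglik, n_params) 2 * n_params - 2 * loglik

# Data-driven default start: density intercept at the naive detected density,
# sigma at an eighth of the largest grid span, baseline rate spreading the
# mean per-individual count over the effective number of exposed detectors,
# slopes at zero, psi at the observed sex ratio.
default_start <- function(ctx) {
  layout <- ctx$layout
  par <- setNames(numeric(length(layout$names)), layout$names)
  n_det <- sum(purrr::map_int(ctx$sessions, "n"))
  area <- nrow(ctx$state) * ctx$cell_area
  span <- max(extent_width(attr(ctx$state, "extent")),
              extent_height(attr(ctx$state, "extent")))
  sigma0 <- span / 8
  total_counts <- sum(purrr::map_dbl(ctx$sessions, function(s) sum(s$Y)))
  eff_detectors <- 2 * pi * sigma0^2 / ctx$cell_area
  lam0_start <- max(total_counts, 1) / max(n_det, 1) / eff_detectors
  d_int <- grep("^D\\.(?!forest$)", layout$d, perl = TRUE, value = TRUE)
  par[d_int] <- log(max(n_det, 1) / area)
  p_int <- layout$p[!layout$p %in% c("p0.effort", "p0.road", "p0.forest", "p0.sexM")]
  par[p_int] <- log(lam0_start)
  par["logsigma.(Intercept)"] <- log(sigma0)
  n_male <- sum(purrr::map_dbl(ctx$sessions, function(s) sum(s$sex_code)))
  prop_m <- min(max(n_male / max(n_det, 1), 0.05), 0.95)
  par["psi.logitM"] <- qlogis(prop_m)
  par
}

fallback_start <- function(ctx) {
  layout <- ctx$layout
  par <- setNames(numeric(length(layout$names)), layout$names)
  d_int <- grep("^D\\.(?!forest$)", layout$d, perl = TRUE, value = TRUE)
  par[d_int] <- log(0.05)
  p_int <- layout$p[!layout$p %in% c("p0.effort", "p0.road", "p0.forest", "p0.sexM")]
  par[p_int] <- log(0.05)
  par["logsigma.(Intercept)"] <- 0
  par
}

# Central-difference gradient; adequate for convergence checks and the delta
# method on smooth likelihoods.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    step <- h * max(1, abs(x[i]))
    xp[i] <- x[i] + step
    xm[i] <- x[i] - step
    (f(xp) - f(xm)) / (2 * step)
  }, numeric(1))
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("<scr_fit>", x$spec$label, "\n")
  cat(sprintf("  sessions: %s; detected: %s\n",
              paste(x$session_labels, collapse = ", "),
              paste(x$n_detected, collapse = ", ")))
  cat(sprintf("  logLik %.3f | %d parameters | AIC %.2f | %s\n",
              x$loglik, x$n_params, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.scr_fit <- function(object, ...) object$coefficients

#' @export
logLik.scr_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
vcov.scr_fit <- function(object, ...) object$vcov

#' Tidy an SCR fit
#'
#' @param x An [fit_scr()] result.
#' @param conf.int,conf.level Wald interval on the link scale.
#' @param ... Unused.
#' @return A tibble with columns `submodel`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (link scale).
#' @exportS3Method generics::tidy
tidy.scr_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, x$n_params)
  out <- tibble(
    submodel = sub("\\..*$", "", names(x$coefficients)),
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se)
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at an SCR fit
#'
#' @param x An [fit_scr()] result.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `n_params`, `n_sessions`,
#'   `n_detected`, `converged`.
#' @exportS3Method generics::glance
glance.scr_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$aic, n_params = x$n_params,
    n_sessions = length(x$session_labels), n_detected = sum(x$n_detected),
    converged = x$converged
  )
}
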