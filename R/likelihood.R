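#' Half-normal encounter rate
#'
#' Expected Poisson encounter count at a detector a given distance from an
#' individual's activity centre: `lambda = lambda0 * exp(-d^2 / (2 sigma^2))`.
#'
#' @param distance Distance(s) in km, non-negative.
#' @param lambda0 Baseline encounter rate(s) at distance zero, non-negative.
#' @param sigma Half-normal scale in km, positive.
#' @return Expected encounter count(s).
#' @examples
#' encounter_rate(2 * 1.6, 1, 1.6)  # exp(-2)
#' @export
encounter_rate <- function(distance, lambda0, sigma) {
  if (any(sigma <= 0)) {
    abort("`sigma` must be positive", class = "foxscr_error_domain")
  }
  if (any(distance < 0)) {
    abort("`distance` must be non-negative", class = "foxscr_error_domain")
  }
  if (any(lambda0 < 0)) {
    abort("`lambda0` must be non-negative", class = "foxscr_error_domain")
  }
  lambda0 * exp(-distance^2 / (2 * sigma^2))
}

#' Probability of being detected at least once
#'
#' Under independent Poisson counts across detectors, an individual with
#' activity centre at distances `distances` from the detectors is detected at
#' least once with probability `1 - exp(-sum_j lambda_j)`.
#'
#' @param distances Vector of AC-detector distances in km.
#' @param lambda0 Baseline rate, scalar or per-detector vector.
#' @param sigma Half-normal scale in km.
#' @return A probability.
#' @examples
#' detection_prob_any(0, log(2), 1)  # 0.5
#' @export
detection_prob_any <- function(distances, lambda0, sigma) {
  1 - exp(-sum(encounter_rate(distances, lambda0, sigma)))
}

# Map model terms to covariate column names.
DETECTION_COLS <- c(effort = "effort_km", road = "road_km", forest = "forest_prop")
DENSITY_COLS <- c(forest = "forest")

as_encounters <- function(x) {
  if (inherits(x, "scr_encounters")) return(x)
  if (inherits(x, "scr_session")) return(new_scr_encounters(list(x)))
  abort("expected an scr_encounters or scr_session object",
        class = "foxscr_error_input")
}

# Assemble everything the likelihood needs: distance matrices, design
# matrices (z-scored covariates), precomputed count cross-products, and the
# parameter layout.
build_fit_context <- function(encounters, state, detectors, spec,
                              standardize = TRUE, det_scalers = NULL,
                              state_scalers = NULL) {
  fixed_det_scalers <- det_scalers
  fixed_state_scalers <- state_scalers
  encounters <- as_encounters(encounters)
  session_labels <- purrr::map_chr(encounters, "session")
  S <- length(session_labels)
  det_list <- if (inherits(detectors, "scr_detectors")) {
    rep(list(detectors), S)
  } else if (is.list(detectors)) {
    if (length(detectors) != S) {
      abort("detector list length must match the number of sessions",
            class = "foxscr_error_config")
    }
    detectors
  } else {
    abort("`detectors` must be a detector grid or a per-session list",
          class = "foxscr_error_config")
  }

  # Covariate scalers: detectors pooled across sessions; state over cells.
  p_terms <- setdiff(spec$detection, c("session", "sex"))
  det_scalers <- list()
  for (tm in p_terms) {
    col <- DETECTION_COLS[[tm]]
    vals <- unlist(purrr::map(det_list, function(d) {
      if (!col %in% names(d)) {
        abort(sprintf("detector covariate '%s' required by the model is missing", col),
              class = "foxscr_error_config")
      }
      d[[col]]
    }))
    det_scalers[[tm]] <- if (!is.null(fixed_det_scalers)) {
      fixed_det_scalers[[tm]]
    } else if (standardize) make_scaler(vals) else list(mean = 0, sd = 1)
  }
  d_terms <- setdiff(spec$density, "session")
  state_scalers <- list()
  for (tm in d_terms) {
    col <- DENSITY_COLS[[tm]]
    if (!col %in% names(state)) {
      abort(sprintf("state-space covariate '%s' required by the model is missing", col),
            class = "foxscr_error_config")
    }
    state_scalers[[tm]] <- if (!is.null(fixed_state_scalers)) {
      fixed_state_scalers[[tm]]
    } else if (standardize) make_scaler(state[[col]]) else list(mean = 0, sd = 1)
  }

  layout <- param_layout(spec, session_labels)
  a <- attr(state, "cell_area")
  G <- nrow(state)

  make_Xd <- function(s_idx) {
    cols <- list()
    if ("session" %in% spec$density && S > 1) {
      for (k in seq_len(S)) cols[[k]] <- rep(as.numeric(k == s_idx), G)
    } else {
      cols[[1]] <- rep(1, G)
    }
    for (tm in d_terms) {
      cols[[length(cols) + 1]] <-
        apply_scaler(state[[DENSITY_COLS[[tm]]]], state_scalers[[tm]])
    }
    do.call(cbind, cols)
  }
  make_Xp <- function(s_idx, dets) {
    J <- nrow(dets)
    cols <- list()
    if ("session" %in% spec$detection && S > 1) {
      for (k in seq_len(S)) cols[[k]] <- rep(as.numeric(k == s_idx), J)
    } else {
      cols[[1]] <- rep(1, J)
    }
    for (tm in p_terms) {
      cols[[length(cols) + 1]] <-
        apply_scaler(dets[[DETECTION_COLS[[tm]]]], det_scalers[[tm]])
    }
    do.call(cbind, cols)
  }

  sess <- purrr::imap(encounters, function(rec, nm) {
    s_idx <- match(rec$session, session_labels)
    dets <- det_list[[s_idx]]
    J <- nrow(dets)
    Y <- rec$counts
    if (ncol(Y) != J) {
      abort("encounter matrix columns do not match the detector grid",
            class = "foxscr_error_config")
    }
    D2 <- outer(dets$x, state$x, "-")^2 + outer(dets$y, state$y, "-")^2
    storage.mode(Y) <- "double"
    list(
      session = rec$session,
      n = nrow(Y),
      Y = Y,
      sex_code = as.integer(rec$sex == "M"),
      D2 = D2,
      YD2 = Y %*% D2,
      logyfact = as.numeric(rowSums(lgamma(Y + 1))),
      Xd = make_Xd(s_idx),
      Xp = make_Xp(s_idx, dets),
      detectors = dets
    )
  })

  list(
    spec = spec, layout = layout, sessions = sess,
    session_labels = session_labels, state = state, cell_area = a,
    det_scalers = det_scalers, state_scalers = state_scalers,
    standardize = standardize
  )
}

# Per-session parameter pieces on the natural scales used by the C++ core.
session_param_pieces <- function(par, ctx, s) {
  layout <- ctx$layout
  spec <- ctx$spec
  bd <- par[layout$d]
  p_design <- setdiff(layout$p, "p0.sexM")
  ap <- par[p_design]
  log_mu_a <- as.numeric(s$Xd %*% bd) + log(ctx$cell_area)
  base <- as.numeric(s$Xp %*% ap)
  sexM_off <- if ("p0.sexM" %in% layout$p) par[["p0.sexM"]] else 0
  log_lam0 <- cbind(base, base + sexM_off)
  g0 <- par[["logsigma.(Intercept)"]]
  gM <- if ("logsigma.sexM" %in% layout$s) par[["logsigma.sexM"]] else 0
  sigma <- exp(c(g0, g0 + gM))
  psiM <- plogis(par[["psi.logitM"]])
  log_psi <- log(c(1 - psiM, psiM))
  list(log_mu_a = log_mu_a, log_lam0 = log_lam0, sigma = sigma,
       log_psi = log_psi, sex_specific = has_sex(spec))
}

loglik_context <- function(par, ctx) {
  total <- 0
  for (s in ctx$sessions) {
    pc <- session_param_pieces(par, ctx, s)
    Ylogl0 <- s$Y %*% pc$log_lam0
    total <- total + scr_session_loglik_core(
      s$D2, pc$log_mu_a, pc$log_lam0, pc$sigma, pc$log_psi,
      s$YD2, Ylogl0, s$sex_code, s$logyfact, pc$sex_specific
    )
  }
  total
}

check_params <- function(params, layout) {
  if (is.null(names(params)) || !setequal(names(params), layout$names)) {
    abort(sprintf("params must be a named vector with names {%s}",
                  paste(layout$names, collapse = ", ")),
          class = "foxscr_error_spec")
  }
  params[layout$names]
}

#' Template parameter vector for a model specification
#'
#' Returns a zero-filled named parameter vector in the layout used by
#' [session_loglik()], [multisession_loglik()] and [fit_scr()]: density
#' coefficients (`D.*`, log scale), detection coefficients (`p0.*`, log
#' scale), log-sigma coefficients and the logit male proportion.
#'
#' @param spec An [scr_model_spec()].
#' @param sessions Character vector of session labels.
#' @return A named numeric vector of zeros.
#' @export
scr_params <- function(spec, sessions = "s1") {
  layout <- param_layout(spec, sessions)
  setNames(numeric(length(layout$names)), layout$names)
}

#' Session log-likelihood of the SCR model
#'
#' The Poisson point-process marginal likelihood of one session's encounter
#' data: each detected individual contributes its sex-mixture weight times the
#' sum over state-space cells of the AC-intensity-weighted Poisson likelihood
#' of its detector counts, and the term `-Lambda_bar` accounts for the
#' expected number of individuals that were never detected.  With no detected
#' individuals the log-likelihood is `-Lambda_bar`.
#'
#' @param data One session of encounter data (an `scr_session` or a
#'   single-session `scr_encounters`).
#' @param state State space from [build_state_space()].
#' @param detectors Detector grid with required covariates.
#' @param spec An [scr_model_spec()].
#' @param params Named parameter vector (see [scr_params()]).
#' @param standardize z-score covariates (must match how `params` are scaled).
#' @return The log-likelihood (scalar).
#' @export
session_loglik <- function(data, state, detectors, spec, params,
                           standardize = TRUE) {
  enc <- as_encounters(data)
  if (length(enc) != 1) {
    abort("`session_loglik()` expects exactly one session; use multisession_loglik()",
          class = "foxscr_error_input")
  }
  ctx <- build_fit_context(enc, state, detectors, spec, standardize)
  par <- check_params(params, ctx$layout)
  loglik_context(par, ctx)
}

#' Multi-session log-likelihood
#'
#' Sum of independent session log-likelihoods with parameters shared or
#' session-specific according to the model specification (session terms give
#' each session its own intercept; slopes are shared).
#'
#' @param encounters An `scr_encounters` object (one or more sessions).
#' @inheritParams session_loglik
#' @return The total log-likelihood (scalar).
#' @export
multisession_loglik <- function(encounters, state, detectors, spec, params,
                                standardize = TRUE) {
  ctx <- build_fit_context(as_encounters(encounters), state, detectors, spec,
                           standardize)
  par <- check_params(params, ctx$layout)
  loglik_context(par, ctx)
}
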