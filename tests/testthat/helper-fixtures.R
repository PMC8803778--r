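# Shared fixtures, built in code.  Toy instances are small enough for the
# enumeration oracle; the "small scenario" is a fast end-to-end simulation
# reused across test files (memoised within the session).

# A toy likelihood instance: <= 9 state cells (3 x 3 grid of 1 km cells),
# <= 3 detectors on a line inside the state space, random counts and sexes.
toy_instance <- function(seed, n_detectors = 3, n_ind = 3) {
  withr::with_seed(seed, {
    st <- build_state_space(c(0, 3, 0, 3), resolution = 1, buffer_km = 0)
    det <- build_detector_grid(c(0, n_detectors, 1, 2), 1)
    det$effort_km <- round(runif(n_detectors, 0.2, 2), 2)
    sex <- sample(c("F", "M"), n_ind, replace = TRUE)
    counts <- matrix(rpois(n_ind * n_detectors, 0.8), n_ind, n_detectors)
    for (i in seq_len(n_ind)) {
      if (sum(counts[i, ]) == 0) counts[i, sample.int(n_detectors, 1)] <- 1L
    }
    if (n_ind > 0) rownames(counts) <- sprintf("ind_%02d", seq_len(n_ind))
  })
  enc <- if (n_ind > 0) {
    foxscr:::new_scr_encounters(list(
      foxscr:::new_scr_session(counts,
                               stats::setNames(sex, rownames(counts)), "s1")
    ))
  } else {
    foxscr:::new_scr_encounters(list(
      structure(list(counts = matrix(0L, 0, n_detectors), sex = character(),
                     session = "s1", truth = NULL), class = "scr_session")
    ))
  }
  list(state = st, detectors = det, enc = enc, counts = counts, sex = sex)
}

# Natural-scale oracle inputs for a toy instance and parameter vector
# (raw-covariate parameterisation, i.e. standardize = FALSE).
toy_oracle_inputs <- function(inst, par, spec) {
  det <- inst$detectors
  st <- inst$state
  base <- par[["p0.(Intercept)"]] + par[["p0.effort"]] * det$effort_km
  sexM <- if ("p0.sexM" %in% names(par)) par[["p0.sexM"]] else 0
  lam0 <- cbind(exp(base), exp(base + sexM))
  g0 <- par[["logsigma.(Intercept)"]]
  gM <- if ("logsigma.sexM" %in% names(par)) par[["logsigma.sexM"]] else 0
  sigma <- c(F = exp(g0), M = exp(g0 + gM))
  mu <- rep(exp(par[["D.(Intercept)"]]), nrow(st))
  dist <- sqrt(outer(det$x, st$x, "-")^2 + outer(det$y, st$y, "-")^2)
  list(mu = mu, cell_area = attr(st, "cell_area"), lam0 = lam0,
       sigma = sigma, psi_male = plogis(par[["psi.logitM"]]), dist = dist)
}

# A small but realistic end-to-end scenario: 6 x 6 km searched area, 1 km
# detector cells, 1 km state-space cells with a 2 km buffer, sex-structured
# detection.  Memoised so several test files can reuse the same fit.
small_scenario <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    extent <- c(0, 6, 0, 6)
    land <- make_landscape(extent, resolution = 0.5, forest_smoothness = 1.5,
                           n_roads = 2, n_tracks = 5, seed = 101)
    det <- add_detector_covariates(build_detector_grid(extent, 1), land)
    st <- build_state_space(extent, resolution = 1, buffer_km = 2,
                            covariates = list(forest = smooth_forest(land$forest, 1)))
    pop <- simulate_population(st, c("(Intercept)" = log(0.6), forest = 0.5),
                               psi_male = 0.5, seed = 102)
    enc <- simulate_detections(
      pop, det, c("(Intercept)" = log(0.35), effort_km = 0.3, sexM = 0.2),
      sigma_by_sex = c(F = 0.8, M = 1.0), seed = 103
    )
    spec <- scr_model_spec(~session, ~ session + effort + sex, ~sex)
    fit <- suppressWarnings(fit_scr(enc, st, det, spec))
    cache <<- list(landscape = land, detectors = det, state = st, pop = pop,
                   enc = enc, spec = spec, fit = fit)
    cache
  }
})

# Construct a minimal scr_fit by hand (for arithmetic-only checks where no
# optimisation is involved).
manual_fit <- function(coefficients, spec, session_labels = "s1",
                       cell_area = 0.25, vcov = NULL,
                       state_scalers = list(), det_scalers = list()) {
  structure(
    list(
      spec = spec, coefficients = coefficients,
      loglik = NA_real_, n_params = length(coefficients),
      aic = NA_real_, vcov = vcov, converged = TRUE,
      layout = foxscr:::param_layout(spec, session_labels),
      session_labels = session_labels,
      n_detected = NA_integer_, det_scalers = det_scalers,
      state_scalers = state_scalers, standardize = FALSE,
      cell_area = cell_area
    ),
    class = "scr_fit"
  )
}

# Replicate-genotype table built from per-marker call triplets.
reps_table <- function(sample_id, marker_calls) {
  purrr::imap_dfr(marker_calls, function(calls, m) {
    tibble::tibble(
      sample_id = sample_id,
      marker = sprintf("m%02d", m),
      replicate = 1:3,
      allele1 = vapply(calls, `[`, numeric(1), 1),
      allele2 = vapply(calls, `[`, numeric(1), 2)
    )
  })
}

unanimous_het <- list(c(1, 2), c(1, 2), c(1, 2))

# Random but reproducible parameter vectors for toy likelihood instances.
random_toy_params <- function(spec, seed) {
  withr::with_seed(seed, {
    par <- scr_params(spec)
    par["D.(Intercept)"] <- runif(1, -1.5, 0)
    par["p0.(Intercept)"] <- runif(1, -1.5, 0)
    par["p0.effort"] <- runif(1, -0.5, 0.5)
    par["logsigma.(Intercept)"] <- runif(1, -0.5, 0.5)
    if ("p0.sexM" %in% names(par)) par["p0.sexM"] <- runif(1, -0.5, 0.5)
    if ("logsigma.sexM" %in% names(par)) par["logsigma.sexM"] <- runif(1, -0.3, 0.3)
    par["psi.logitM"] <- runif(1, -1, 1)
  })
  par
}
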