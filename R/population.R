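#' Simulate a population of activity centres
#'
#' Draws a realization of the inhomogeneous Poisson point process the density
#' submodel assumes: the expected activity-centre (AC) count in state-space
#' cell `g` is `mu(g) * a = exp(b0 + sum_k b_k X_k(g)) * a`, the number of
#' individuals is Poisson with mean `Lambda = sum_g mu(g) * a`, each AC falls
#' in a cell with probability proportional to `mu(g) * a` and uniformly within
#' it, and sex is Bernoulli(`psi_male`).
#'
#' @param state An [build_state_space()] result carrying the density
#'   covariates named in `beta_d`.
#' @param beta_d Named coefficient vector on the log-density (per km^2) scale;
#'   must contain `"(Intercept)"`, other names must match covariate columns of
#'   `state`.
#' @param psi_male Proportion male in `[0, 1]`.
#' @param seed Integer seed (required).
#' @param session Session label attached to the population.
#' @param standardize Should covariates be z-scored over state-space cells
#'   before applying `beta_d`?  Matches the standardization used when fitting,
#'   so simulated and estimated coefficients are on the same scale.
#' @return A tibble of class `scr_population` with columns `individual`, `x`,
#'   `y`, `sex`, and attributes `Lambda`, `session`, `beta_d`, `psi_male`.
#' @export
simulate_population <- function(state, beta_d, psi_male = 0.5, seed,
                                session = "s1", standardize = TRUE) {
  seed <- check_seed(seed)
  if (psi_male < 0 || psi_male > 1) {
    abort("`psi_male` must be in [0, 1]", class = "foxscr_error_domain")
  }
  covs <- setdiff(names(beta_d), "(Intercept)")
  if (!"(Intercept)" %in% names(beta_d)) {
    abort("`beta_d` must contain an \"(Intercept)\" term",
          class = "foxscr_error_spec")
  }
  missing_covs <- setdiff(covs, names(state))
  if (length(missing_covs) > 0) {
    abort(sprintf("unknown density covariate(s): %s",
                  paste(missing_covs, collapse = ", ")),
          class = "foxscr_error_spec")
  }
  a <- attr(state, "cell_area")
  res <- attr(state, "resolution")
  eta <- rep(beta_d[["(Intercept)"]], nrow(state))
  for (nm in covs) {
    x <- state[[nm]]
    if (standardize) x <- apply_scaler(x, make_scaler(x))
    eta <- eta + beta_d[[nm]] * x
  }
  mu_a <- exp(eta) * a
  Lambda <- sum(mu_a)

  withr::with_seed(seed, {
    n <- rpois(1, Lambda)
    if (n > 0) {
      cells <- sample.int(nrow(state), n, replace = TRUE, prob = mu_a)
      x <- state$x[cells] + runif(n, -res / 2, res / 2)
      y <- state$y[cells] + runif(n, -res / 2, res / 2)
      sex <- ifelse(runif(n) < psi_male, "M", "F")
    } else {
      x <- y <- double()
      sex <- character()
    }
  })

  out <- tibble(
    individual = sprintf("ind_%04d", seq_len(n)),
    x = x, y = y, sex = sex
  )
  attr(out, "Lambda") <- Lambda
  attr(out, "session") <- session
  attr(out, "beta_d") <- beta_d
  attr(out, "psi_male") <- psi_male
  class(out) <- c("scr_population", class(out))
  out
}

#' Simulate detector-level encounter counts
#'
#' Generates the Poisson count data the SCR likelihood models: individual `i`
#' with activity centre `s_i` produces
#' `y_ij ~ Poisson(lambda0_j(sex_i) * exp(-d(s_i, j)^2 / (2 sigma_sex^2)))`
#' detections at detector `j`, where
#' `log lambda0_j = a0 + sum_k a_k Z_k(j) (+ a_sexM)`.
#' Individuals never detected are excluded from the returned encounter data
#' but kept in the truth record for recovery checks.
#'
#' @param pop An [simulate_population()] result.
#' @param detectors Detector grid with the covariates named in `lambda0_link`.
#' @param lambda0_link Named coefficients on the log baseline encounter rate:
#'   `"(Intercept)"` plus optionally detector covariate names (`effort_km`,
#'   `road_km`, `forest_prop`) and `"sexM"`.
#' @param sigma_by_sex Half-normal scale in km, named `c(F = , M = )`; a
#'   single unnamed value is used for both sexes.
#' @param seed Integer seed (required).
#' @param standardize z-score detector covariates before applying
#'   `lambda0_link` (matches fitting).
#' @return An `scr_encounters` object with one session; the session record
#'   carries a `truth` list (full population, undetected individuals and the
#'   generating parameters).
#' @export
simulate_detections <- function(pop, detectors, lambda0_link,
                                sigma_by_sex = c(F = 1.6, M = 2.0), seed,
                                standardize = TRUE) {
  seed <- check_seed(seed)
  if (length(sigma_by_sex) == 1) {
    sigma_by_sex <- c(F = unname(sigma_by_sex), M = unname(sigma_by_sex))
  }
  if (any(sigma_by_sex <= 0)) {
    abort("`sigma_by_sex` must be positive", class = "foxscr_error_domain")
  }
  covs <- setdiff(names(lambda0_link), c("(Intercept)", "sexM"))
  if (!"(Intercept)" %in% names(lambda0_link)) {
    abort("`lambda0_link` must contain an \"(Intercept)\" term",
          class = "foxscr_error_spec")
  }
  missing_covs <- setdiff(covs, names(detectors))
  if (length(missing_covs) > 0) {
    abort(sprintf("unknown detector covariate(s): %s",
                  paste(missing_covs, collapse = ", ")),
          class = "foxscr_error_spec")
  }

  J <- nrow(detectors)
  n <- nrow(pop)
  log_lam0 <- rep(lambda0_link[["(Intercept)"]], J)
  for (nm in covs) {
    z <- detectors[[nm]]
    if (standardize) z <- apply_scaler(z, make_scaler(z))
    log_lam0 <- log_lam0 + lambda0_link[[nm]] * z
  }
  beta_sexM <- if ("sexM" %in% names(lambda0_link)) lambda0_link[["sexM"]] else 0

  session <- attr(pop, "session") %||% "s1"
  if (n == 0) {
    counts <- matrix(0L, 0, J)
    rec <- structure(list(counts = counts, sex = character(), session = session,
                          truth = list(population = pop,
                                       undetected = pop)),
                     class = "scr_session")
    return(new_scr_encounters(list(rec)))
  }

  d2 <- outer(pop$x, detectors$x, "-")^2 + outer(pop$y, detectors$y, "-")^2
  sig <- sigma_by_sex[pop$sex]
  lam <- exp(matrix(log_lam0, n, J, byrow = TRUE) +
               (pop$sex == "M") * beta_sexM - d2 / (2 * sig^2))
  withr::with_seed(seed, {
    y <- matrix(rpois(n * J, lam), n, J)
  })
  detected <- rowSums(y) > 0
  counts <- y[detected, , drop = FALSE]
  rownames(counts) <- pop$individual[detected]
  truth <- list(
    population = pop,
    undetected = pop[!detected, ],
    lambda0_link = lambda0_link,
    sigma_by_sex = sigma_by_sex
  )
  rec <- new_scr_session(counts, setNames(pop$sex[detected],
                                          pop$individual[detected]),
                         session = session, truth = truth)
  new_scr_encounters(list(rec))
}

#' Expand encounter counts into per-sample field records
#'
#' Converts detector-level counts into a sample table resembling raw NGS field
#' records: one row per sample with coordinates drawn uniformly within the
#' detector cell, a collection date in the winter field season and a sample
#' type (scat / urine / hair).
#'
#' @param encounters An `scr_encounters` object.
#' @param detectors The detector grid used for simulation.
#' @param seed Integer seed (required).
#' @param year First session's calendar year (subsequent sessions increment).
#' @return A tibble with columns `sample_id`, `session`, `individual_id`,
#'   `sex`, `x_km`, `y_km`, `date`, `type`.
#' @export
detections_to_samples <- function(encounters, detectors, seed, year = 2017) {
  seed <- check_seed(seed)
  cell_side <- attr(detectors, "cell_side")
  type_probs <- c(scat = 0.40, urine = 0.57, hair = 0.03)
  withr::with_seed(seed, {
    purrr::imap_dfr(encounters, function(s, idx) {
      i_sess <- match(s$session, names(encounters))
      tb <- as_tibble(new_scr_encounters(list(s)))
      if (nrow(tb) == 0) return(tb)
      tb <- tidyr::uncount(tb, weights = .data$n)
      m <- nrow(tb)
      dates <- seq(as.Date(sprintf("%d-02-01", year + i_sess - 1)),
                   as.Date(sprintf("%d-03-31", year + i_sess - 1)), by = "day")
      tibble(
        sample_id = sprintf("%s_smp_%04d", s$session, seq_len(m)),
        session = tb$session,
        individual_id = tb$individual_id,
        sex = tb$sex,
        x_km = detectors$x[tb$detector] + runif(m, -cell_side / 2, cell_side / 2),
        y_km = detectors$y[tb$detector] + runif(m, -cell_side / 2, cell_side / 2),
        date = sample(dates, m, replace = TRUE),
        type = sample(names(type_probs), m, replace = TRUE, prob = type_probs)
      )
    })
  })
}
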