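test_that("the half-normal encounter rate has its closed-form landmarks", {
  expect_equal(encounter_rate(0, 0.7, 1.6), 0.7)
  expect_equal(encounter_rate(1.6 * sqrt(2 * log(2)), 0.7, 1.6), 0.35)
  expect_equal(encounter_rate(2 * 1.6, 1, 1.6), exp(-2))
  expect_error(encounter_rate(1, 1, 0), class = "foxscr_error_domain")
  expect_error(encounter_rate(-1, 1, 1), class = "foxscr_error_domain")
})

test_that("detection probability integrates hazards across detectors", {
  expect_equal(detection_prob_any(c(1, 2), 0, 1), 0)
  expect_equal(detection_prob_any(0, log(2), 1), 0.5)
  # two detectors with rate 0.3 each
  expect_equal(detection_prob_any(c(0, 0), 0.3, 1), 1 - exp(-0.6))
})


test_that("session_loglik matches brute-force enumeration over cells and sexes", {
  spec_sex <- scr_model_spec(~session, ~ session + effort + sex, ~sex)
  spec_plain <- scr_model_spec(~session, ~ session + effort, ~1)
  cases <- tidyr::expand_grid(seed = 1:3, n_det = c(1, 3), n_ind = c(1, 3),
                              sexed = c(TRUE, FALSE))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    inst <- toy_instance(100 + cs$seed * 7 + cs$n_det + cs$n_ind,
                         n_detectors = cs$n_det, n_ind = cs$n_ind)
    spec <- if (cs$sexed) spec_sex else spec_plain
    par <- random_toy_params(spec, 200 + k)
    ll <- session_loglik(inst$enc, inst$state, inst$detectors, spec, par,
                         standardize = FALSE)
    o <- toy_oracle_inputs(inst, par, spec)
    ll_oracle <- oracle_session_loglik(inst$counts, inst$sex, o$mu,
                                       o$cell_area, o$lam0, o$sigma,
                                       o$psi_male, o$dist)
    expect_equal(ll, ll_oracle, tolerance = 1e-10)
  }
})

test_that("a single-cell single-detector instance matches the hand formula", {
  st <- build_state_space(c(0, 1, 0, 1), 1, buffer_km = 0)
  det <- build_detector_grid(c(0, 1, 0, 1), 1)
  det$effort_km <- 1
  spec <- scr_model_spec(~session, ~ session + effort, ~1)
  y <- 3L
  enc <- make_encounters(
    tibble::tibble(session = "s1", individual_id = "a", sex = "M",
                   detector = 1L, n = y),
    det
  )
  par <- scr_params(spec)
  par["D.(Intercept)"] <- log(0.8)
  par["p0.(Intercept)"] <- log(0.9)
  par["psi.logitM"] <- 0.4

  mu_a <- 0.8  # cell area 1
  lam <- 0.9   # AC and detector share the cell centre: distance 0
  psi_m <- plogis(0.4)
  hand <- log(psi_m) + log(mu_a) + y * log(lam) - lam - log(factorial(y)) -
    mu_a * (1 - exp(-lam))
  expect_equal(
    session_loglik(enc, st, det, spec, par, standardize = FALSE),
    hand, tolerance = 1e-12
  )

  # raising the count changes log L by the Poisson log-pmf ratio
  enc4 <- make_encounters(
    tibble::tibble(session = "s1", individual_id = "a", sex = "M",
                   detector = 1L, n = y + 1L),
    det
  )
  delta <- session_loglik(enc4, st, det, spec, par, standardize = FALSE) -
    session_loglik(enc, st, det, spec, par, standardize = FALSE)
  expect_equal(delta, dpois(y + 1L, lam, log = TRUE) - dpois(y, lam, log = TRUE),
               tolerance = 1e-12)
})

test_that("empty encounter data gives -Lambda_bar and impossible data -Inf", {
  inst <- toy_instance(301, n_detectors = 2, n_ind = 0)
  spec <- scr_model_spec(~session, ~ session + effort, ~1)
  par <- random_toy_params(spec, 302)
  ll <- session_loglik(inst$enc, inst$state, inst$detectors, spec, par,
                       standardize = FALSE)
  o <- toy_oracle_inputs(inst, par, spec)
  ll_oracle <- oracle_session_loglik(matrix(0, 0, 2), character(), o$mu,
                                     o$cell_area, o$lam0, o$sigma,
                                     o$psi_male, o$dist)
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
  expect_lt(ll, 0)

  # detections with a vanishing baseline rate are impossible
  inst2 <- toy_instance(303, n_detectors = 2, n_ind = 2)
  par2 <- par
  par2["p0.(Intercept)"] <- -60
  expect_lt(
    session_loglik(inst2$enc, inst2$state, inst2$detectors, spec, par2,
                   standardize = FALSE),
    -100
  )
})

test_that("log-likelihood is invariant to individual and detector ordering", {
  inst <- toy_instance(311, n_detectors = 3, n_ind = 3)
  spec <- scr_model_spec(~session, ~ session + effort + sex, ~sex)
  par <- random_toy_params(spec, 312)
  ll <- session_loglik(inst$enc, inst$state, inst$detectors, spec, par,
                       standardize = FALSE)

  # permute individuals
  perm_i <- c(3, 1, 2)
  enc_i <- foxscr:::new_scr_encounters(list(foxscr:::new_scr_session(
    inst$counts[perm_i, , drop = FALSE],
    stats::setNames(inst$sex[perm_i], rownames(inst$counts)[perm_i]), "s1"
  )))
  expect_equal(
    session_loglik(enc_i, inst$state, inst$detectors, spec, par,
                   standardize = FALSE),
    ll, tolerance = 1e-12
  )

  # permute detectors (rows of the grid and columns of the counts together)
  perm_j <- c(2, 3, 1)
  det_j <- inst$detectors[perm_j, ]
  enc_j <- foxscr:::new_scr_encounters(list(foxscr:::new_scr_session(
    inst$counts[, perm_j, drop = FALSE],
    stats::setNames(inst$sex, rownames(inst$counts)), "s1"
  )))
  expect_equal(
    session_loglik(enc_j, inst$state, det_j, spec, par, standardize = FALSE),
    ll, tolerance = 1e-12
  )
})

test_that("the likelihood depends on the state space only through its measure", {
  # splitting every cell into two half-area cells at the same centre leaves
  # log L unchanged
  inst <- toy_instance(321, n_detectors = 3, n_ind = 3)
  spec <- scr_model_spec(~session, ~ session + effort, ~1)
  par <- random_toy_params(spec, 322)
  ll <- session_loglik(inst$enc, inst$state, inst$detectors, spec, par,
                       standardize = FALSE)
  st2 <- inst$state[rep(seq_len(nrow(inst$state)), each = 2), ]
  attr(st2, "cell_area") <- attr(inst$state, "cell_area") / 2
  attr(st2, "resolution") <- attr(inst$state, "resolution")
  attr(st2, "extent") <- attr(inst$state, "extent")
  expect_equal(
    session_loglik(inst$enc, st2, inst$detectors, spec, par,
                   standardize = FALSE),
    ll, tolerance = 1e-10
  )
})

test_that("multi-session likelihood sums independent sessions", {
  inst <- toy_instance(331, n_detectors = 3, n_ind = 3)
  spec <- scr_model_spec(~session, ~ session + effort, ~1)
  par1 <- random_toy_params(spec, 332)
  ll1 <- session_loglik(inst$enc, inst$state, inst$detectors, spec, par1,
                        standardize = FALSE)

  # one session: multisession_loglik equals session_loglik
  expect_equal(
    multisession_loglik(inst$enc, inst$state, inst$detectors, spec, par1,
                        standardize = FALSE),
    ll1
  )

  # two identical sessions with shared parameters: twice the value
  rec <- inst$enc[[1]]
  rec2 <- foxscr:::new_scr_session(rec$counts, rec$sex, "s2")
  enc2 <- foxscr:::new_scr_encounters(list(rec, rec2))
  par2 <- scr_params(spec, sessions = c("s1", "s2"))
  par2[c("D.s1", "D.s2")] <- par1[["D.(Intercept)"]]
  par2[c("p0.s1", "p0.s2")] <- par1[["p0.(Intercept)"]]
  par2["p0.effort"] <- par1[["p0.effort"]]
  par2["logsigma.(Intercept)"] <- par1[["logsigma.(Intercept)"]]
  par2["psi.logitM"] <- par1[["psi.logitM"]]
  expect_equal(
    multisession_loglik(enc2, inst$state, inst$detectors, spec, par2,
                        standardize = FALSE),
    2 * ll1, tolerance = 1e-10
  )

  # mismatched detector list
  expect_error(
    multisession_loglik(enc2, inst$state, list(inst$detectors), spec, par2),
    class = "foxscr_error_config"
  )
})
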