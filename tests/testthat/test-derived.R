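test_that("home-range area follows the circular bivariate-normal quantile law", {
  # independent closed form: the 95% radius satisfies r^2 = -2 sigma^2 log(0.05)
  sigma <- c(0.4, 1, 1.63, 2.5)
  expect_equal(home_range_area(sigma), pi * sigma^2 * (-2 * log(0.05)),
               tolerance = 1e-12)
  expect_equal(home_range_area(sigma, 0.5), pi * sigma^2 * (-2 * log(0.5)),
               tolerance = 1e-12)

  # scaling and monotonicity
  expect_equal(home_range_area(2 * 1.3), 4 * home_range_area(1.3))
  expect_true(all(diff(home_range_area(seq(0.1, 3, by = 0.1))) > 0))
  expect_equal(home_range_area(0), 0)

  expect_error(home_range_area(1, quantile = 1), class = "foxscr_error_domain")
  expect_error(home_range_area(-1), class = "foxscr_error_domain")
})

test_that("home ranges from a fit transform sigma's interval bounds", {
  spec <- scr_model_spec(~session, ~ session + effort + sex, ~sex)
  coefs <- c("D.(Intercept)" = log(0.1), "p0.(Intercept)" = log(0.1),
             "p0.effort" = 0, "p0.sexM" = 0,
             "logsigma.(Intercept)" = log(1.63), "logsigma.sexM" = log(2.13 / 1.63),
             "psi.logitM" = 0)
  vc <- diag(1e-4, length(coefs))
  dimnames(vc) <- list(names(coefs), names(coefs))
  fit <- manual_fit(coefs, spec, vcov = vc)
  hr <- home_ranges(fit)
  expect_equal(hr$sex, c("F", "M"))
  expect_equal(hr$sigma, c(1.63, 2.13), tolerance = 1e-10)
  expect_equal(hr$area, home_range_area(hr$sigma))
  expect_equal(hr$area_low, home_range_area(hr$sigma_low))
  expect_equal(hr$area_high, home_range_area(hr$sigma_high))
  expect_true(all(hr$sigma_low < hr$sigma & hr$sigma < hr$sigma_high))
})

test_that("expected density surfaces integrate to regional abundance", {
  st <- build_state_space(c(0, 15, 0, 15), 0.5, buffer_km = 0)
  spec <- scr_model_spec(~session, ~ session + effort, ~1)
  fit <- manual_fit(
    c("D.(Intercept)" = log(0.16), "p0.(Intercept)" = log(0.1),
      "p0.effort" = 0, "logsigma.(Intercept)" = log(1.6), "psi.logitM" = 0),
    spec, cell_area = attr(st, "cell_area")
  )
  surf <- expected_density(fit, st)
  expect_true(all(surf$density >= 0))
  expect_equal(unique(surf$density), 0.16)

  # 0.16 / km^2 over the 225 km^2 study area -> 36 individuals
  expect_equal(abundance(surf)$estimate, 36, tolerance = 1e-12)

  # additivity over disjoint regions
  left <- abundance(surf, region = c(0, 7.5, 0, 15))$estimate
  right <- abundance(surf, region = c(7.6, 15, 0, 15))$estimate
  expect_equal(left + right, 36, tolerance = 1e-12)

  # a vanishing intensity gives a vanishing abundance
  fit0 <- manual_fit(
    c("D.(Intercept)" = -60, "p0.(Intercept)" = log(0.1), "p0.effort" = 0,
      "logsigma.(Intercept)" = 0, "psi.logitM" = 0),
    spec, cell_area = attr(st, "cell_area")
  )
  expect_lt(abundance(expected_density(fit0, st))$estimate, 1e-20)

  expect_error(abundance(surf, region = c(100, 101, 100, 101)),
               class = "foxscr_error_config")
})

test_that("realized density matches enumeration and conserves individuals", {
  inst <- toy_instance(501, n_detectors = 3, n_ind = 3)
  spec <- scr_model_spec(~session, ~ session + effort + sex, ~sex)
  par <- c("D.(Intercept)" = log(0.5), "p0.(Intercept)" = log(0.6),
           "p0.effort" = 0.25, "p0.sexM" = 0.3,
           "logsigma.(Intercept)" = log(0.9), "logsigma.sexM" = log(1.2),
           "psi.logitM" = 0.2)
  fit <- manual_fit(par, spec, cell_area = attr(inst$state, "cell_area"),
                    det_scalers = list(effort = list(mean = 0, sd = 1)))
  surf <- realized_density(fit, inst$enc, inst$state, inst$detectors)

  o <- toy_oracle_inputs(inst, par, spec)
  oracle_n <- oracle_realized_n(inst$counts, inst$sex, o$mu, o$cell_area,
                                o$lam0, o$sigma, o$psi_male, o$dist)
  expect_equal(surf$expected_n, oracle_n, tolerance = 1e-10)

  # total = n detected + expected undetected
  undet <- sum(o$mu * o$cell_area *
                 ((1 - o$psi_male) * exp(-colSums(o$lam0[, 1] * exp(-o$dist^2 / (2 * o$sigma[["F"]]^2)))) +
                    o$psi_male * exp(-colSums(o$lam0[, 2] * exp(-o$dist^2 / (2 * o$sigma[["M"]]^2))))))
  expect_equal(sum(surf$expected_n), nrow(inst$counts) + undet,
               tolerance = 1e-8)

  # with near-certain detection the surface totals the detected count
  par_sure <- par
  par_sure["p0.(Intercept)"] <- log(50)
  fit_sure <- manual_fit(par_sure, spec,
                         cell_area = attr(inst$state, "cell_area"),
                         det_scalers = list(effort = list(mean = 0, sd = 1)))
  surf_sure <- realized_density(fit_sure, inst$enc, inst$state, inst$detectors)
  expect_equal(sum(surf_sure$expected_n), nrow(inst$counts), tolerance = 1e-3)
})

test_that("abundance from a real fit carries a delta-method interval", {
  sc <- small_scenario()
  nhat <- abundance(sc$fit, sc$state,
                    region = attr(sc$state, "searched_extent"))
  expect_true(nhat$lower < nhat$estimate & nhat$estimate < nhat$upper)
  expect_equal(nhat$area_km2, 36)

  # the full state space integrates to the fitted Lambda
  full <- abundance(sc$fit, sc$state)
  surf <- expected_density(sc$fit, sc$state)
  expect_equal(full$estimate, sum(surf$expected_n), tolerance = 1e-10)
})

test_that("sampling summaries reproduce survey-table arithmetic", {
  # 27 individuals, 122 genotyped samples, range 1-17
  counts <- c(17, 1, rep(4, 21), rep(5, 4))
  stopifnot(sum(counts) == 122, length(counts) == 27)
  tbl <- tibble::tibble(
    session = "Lierne 2018",
    sample_id = sprintf("a%03d", 1:158),
    individual_id = c(rep(sprintf("i%02d", seq_along(counts)), counts),
                      rep(NA, 158 - 122)),
    sex = "F",
    confirmed = c(rep(TRUE, 152), rep(FALSE, 6))
  )
  out <- summarize_samples(tbl)
  expect_equal(out$n_samples, 158)
  expect_equal(out$n_confirmed, 152)
  expect_equal(out$n_genotyped, 122)
  expect_equal(out$n_individuals, 27)
  expect_equal(out$mean_samples, 4.52)
  expect_equal(out$min_samples, 1)
  expect_equal(out$max_samples, 17)

  # 43 samples over 25 individuals -> 1.72
  counts2 <- c(rep(1, 13), rep(2, 9), rep(4, 3))
  stopifnot(sum(counts2) == 43, length(counts2) == 25)
  tbl2 <- tibble::tibble(
    session = "Skrim 2017",
    sample_id = sprintf("b%03d", 1:43),
    individual_id = rep(sprintf("j%02d", seq_along(counts2)), counts2),
    sex = rep(c("F", "M"), length.out = 43)
  )
  expect_equal(summarize_samples(tbl2)$mean_samples, 1.72)

  # singletons
  tbl3 <- tibble::tibble(session = "x", sample_id = c("u", "v"),
                         individual_id = c("i1", "i2"), sex = "M")
  out3 <- summarize_samples(tbl3)
  expect_equal(out3$mean_samples, 1)
  expect_equal(c(out3$min_samples, out3$max_samples), c(1, 1))
})
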