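test_that("landscape generation is deterministic and respects the grid geometry", {
  land <- make_landscape(c(0, 15, 0, 15), resolution = 0.5, seed = 11)
  expect_equal(dim(land$forest$values), c(30, 30))  # 900 cells
  expect_true(all(land$forest$values >= 0 & land$forest$values <= 1))

  land2 <- make_landscape(c(0, 15, 0, 15), resolution = 0.5, seed = 11)
  expect_identical(land, land2)
  land3 <- make_landscape(c(0, 15, 0, 15), resolution = 0.5, seed = 12)
  expect_false(identical(land$forest$values, land3$forest$values))

  expect_error(make_landscape(c(0, 15, 0, 15), resolution = 0.4, seed = 1),
               class = "foxscr_error_config")

  flat <- make_landscape(c(0, 6, 0, 6), resolution = 0.5,
                         forest_smoothness = Inf, seed = 1)
  expect_true(all(flat$forest$values == flat$forest$values[1, 1]))
})

test_that("population simulation realizes the inhomogeneous Poisson density model", {
  st <- build_state_space(c(0, 15, 0, 15), resolution = 1, buffer_km = 0)

  # homogeneous intensity 0.1 / km^2 on 225 km^2
  pop <- simulate_population(st, c("(Intercept)" = log(0.1)), seed = 21)
  expect_equal(attr(pop, "Lambda"), 22.5)

  # realized N is unbiased for Lambda (Monte Carlo)
  Ns <- vapply(1:400, function(r) {
    nrow(simulate_population(st, c("(Intercept)" = log(0.1)), seed = 1000 + r))
  }, numeric(1))
  se <- sqrt(22.5 / 400)
  expect_lt(abs(mean(Ns) - 22.5), 3 * se)

  # everyone male at psi_male = 1
  pop_m <- simulate_population(st, c("(Intercept)" = log(0.2)), psi_male = 1,
                               seed = 22)
  expect_true(all(pop_m$sex == "M"))

  expect_error(
    simulate_population(st, c("(Intercept)" = 0, bogus = 1), seed = 1),
    class = "foxscr_error_spec"
  )
})

test_that("a positive forest coefficient concentrates activity centres in forest", {
  land <- make_landscape(c(0, 8, 0, 8), resolution = 1, forest_smoothness = 2,
                         seed = 31)
  st <- build_state_space(c(0, 8, 0, 8), resolution = 1, buffer_km = 0,
                          covariates = list(forest = land$forest))
  q <- stats::quantile(st$forest, c(0.25, 0.75))
  top <- st$forest >= q[2]
  bottom <- st$forest <= q[1]
  cell_of <- function(pop) {
    ix <- pmin(pmax(ceiling(pop$x - 0), 1), 8)
    iy <- pmin(pmax(ceiling(pop$y - 0), 1), 8)
    (iy - 1) * 8 + ix
  }
  counts <- vapply(1:500, function(r) {
    pop <- simulate_population(st, c("(Intercept)" = log(0.4), forest = 1),
                               seed = 5000 + r)
    cells <- cell_of(pop)
    c(top = sum(top[cells]) / sum(top),
      bottom = sum(bottom[cells]) / sum(bottom))
  }, numeric(2))
  expect_gt(mean(counts["top", ]), mean(counts["bottom", ]))
})

test_that("detection counts follow the half-normal Poisson encounter model", {
  det <- build_detector_grid(c(0, 1, 0, 1), 1)  # one detector at (0.5, 0.5)
  det$effort_km <- 1
  make_pop <- function(x, y, sex = "F") {
    pop <- tibble::tibble(individual = "ind_0001", x = x, y = y, sex = sex)
    attr(pop, "session") <- "s1"
    class(pop) <- c("scr_population", class(pop))
    pop
  }

  # vanishing kernel: AC away from the detector is never seen
  enc <- simulate_detections(make_pop(0.9, 0.9), det,
                             c("(Intercept)" = log(5)),
                             sigma_by_sex = 1e-6, seed = 41)
  expect_equal(nrow(enc[[1]]$counts), 0)

  # individual at the detector with lambda0 = 1: P(detected) = 1 - exp(-1)
  detected <- vapply(1:1000, function(r) {
    e <- simulate_detections(make_pop(0.5, 0.5), det, c("(Intercept)" = 0),
                             sigma_by_sex = 1, seed = 2000 + r,
                             standardize = FALSE)
    nrow(e[[1]]$counts) > 0
  }, logical(1))
  p <- 1 - exp(-1)
  expect_lt(abs(mean(detected) - p), 3 * sqrt(p * (1 - p) / 1000))

  expect_error(
    simulate_detections(make_pop(0.5, 0.5), det, c("(Intercept)" = 0),
                        sigma_by_sex = -1, seed = 1),
    class = "foxscr_error_domain"
  )
})

test_that("detected fraction rises with baseline rate and with sigma", {
  sc <- small_scenario()
  pop <- sc$pop
  frac_detected <- function(lam0, sigma) {
    mean(vapply(1:60, function(r) {
      e <- simulate_detections(pop, sc$detectors, c("(Intercept)" = log(lam0)),
                               sigma_by_sex = sigma, seed = 3000 + r)
      nrow(e[[1]]$counts) / nrow(pop)
    }, numeric(1)))
  }
  by_lam <- vapply(c(0.05, 0.2, 0.8), frac_detected, numeric(1), sigma = 1)
  expect_true(all(diff(by_lam) > 0))
  by_sig <- vapply(c(0.4, 0.8, 1.6), function(s) frac_detected(0.2, s),
                   numeric(1))
  expect_true(all(diff(by_sig) > 0))
})

test_that("replicate genotype simulation honours its error model", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    individual_id = rep(c("a", "b", "c"), each = 4)
  )
  reps <- simulate_replicate_genotypes(samples, n_loci = 14,
                                       error_rates = c(dropout = 0,
                                                       false_allele = 0),
                                       seed = 51)
  expect_equal(dplyr::n_distinct(reps$marker), 14)
  expect_equal(nrow(reps), 12 * 14 * 3)
  # no errors: the three replicates are identical within sample and marker
  spread <- reps |>
    dplyr::group_by(sample_id, marker) |>
    dplyr::summarise(k = dplyr::n_distinct(paste(allele1, allele2)),
                     .groups = "drop")
  expect_true(all(spread$k == 1))
  # and identical to the individual's true genotype
  truth <- attr(reps, "truth")
  joined <- reps |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(truth, by = c("individual_id", "marker"),
                     suffix = c("", ".true"))
  expect_true(all(joined$allele1 == joined$allele1.true &
                    joined$allele2 == joined$allele2.true))

  expect_error(
    simulate_replicate_genotypes(samples, error_rates = c(dropout = 0.6,
                                                          false_allele = 0),
                                 seed = 1),
    class = "foxscr_error_domain"
  )
})

test_that("higher dropout lowers the mean quality index", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:200),
    individual_id = sprintf("i%03d", rep(1:50, each = 4))
  )
  mean_qi <- function(dropout) {
    reps <- simulate_replicate_genotypes(
      samples, n_loci = 10,
      error_rates = c(dropout = dropout, false_allele = 0.02), seed = 61
    )
    mean(quality_index(reps)$qi)
  }
  expect_gt(mean_qi(0.05), mean_qi(0.3))
})
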