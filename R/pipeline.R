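#' Pipeline configuration
#'
#' A single self-describing configuration drives the end-to-end pipeline
#' ([run_simulate()], [run_fit_select()], [run_predict()]).  `scr_config()`
#' returns the default configuration with any supplied elements overriding
#' defaults (nested lists are merged); `read_scr_config()` loads overrides
#' from a YAML file.
#'
#' @param ... Named overrides of the default configuration (nested lists
#'   merged element-wise).
#' @return A named list of class `scr_config`.
#' @export
scr_config <- function(...) {
  defaults <- list(
    seed = NULL,
    out_dir = "foxscr_output",
    study = list(
      extent = c(0, 15, 0, 15),
      cell_side = 0.5,
      state_resolution = 0.5,
      buffer_sigma_max = 2.0,
      forest_smooth_radius = 1.0
    ),
    landscape = list(
      resolution = 0.5,
      forest_smoothness = 2,
      n_roads = 3,
      n_tracks = 8
    ),
    sessions = c("s1", "s2"),
    population = list(
      beta_d = list("(Intercept)" = -2.5, forest = 1.0),
      psi_male = 0.5
    ),
    detection = list(
      lambda0_link = list("(Intercept)" = -3.5, effort_km = 0.4, sexM = 0.3),
      sigma_by_sex = list(F = 1.6, M = 2.0)
    ),
    genotyping = list(
      simulate = FALSE,
      n_loci = 14,
      dropout = 0.1,
      false_allele = 0.02,
      qi_threshold = 0.70
    ),
    fit = list(
      candidates = "full",  # or "base": session + effort model only
      hessian_retained = TRUE
    )
  )
  cfg <- merge_config(defaults, list(...))
  class(cfg) <- c("scr_config", "list")
  cfg
}

#' @rdname scr_config
#' @param path YAML file of configuration overrides.
#' @export
read_scr_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(scr_config, overrides)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

config_seed <- function(config) {
  if (is.null(config$seed)) {
    abort("the configuration must set `seed`", class = "foxscr_error_usage")
  }
  check_seed(config$seed)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory '%s' is not empty; use force = TRUE to overwrite",
                  out_dir),
          class = "foxscr_error_usage")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

write_manifest <- function(out_dir, config, stage, files) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("foxscr")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Shared geometry built from a configuration.
config_geometry <- function(config, forest_raster) {
  smoothed <- smooth_forest(forest_raster, config$study$forest_smooth_radius)
  state <- build_state_space(
    config$study$extent,
    resolution = config$study$state_resolution,
    buffer_km = buffer_width(config$study$buffer_sigma_max),
    covariates = list(forest = smoothed)
  )
  list(state = state, smoothed = smoothed)
}

#' Simulate a full synthetic dataset to disk
#'
#' Generates a landscape, detector covariates, per-session populations and
#' encounter data, expands detections into a field-style sample table, and
#' (optionally) replicate genotypes; writes everything under
#' `config$out_dir` together with a truth record and a manifest.
#'
#' @param config An [scr_config()]; `seed` is mandatory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list with the in-memory objects (landscape,
#'   detectors, populations, encounters, samples).
#' @export
run_simulate <- function(config = scr_config(), force = FALSE) {
  seed <- config_seed(config)
  out_dir <- prepare_out_dir(config$out_dir, force)

  land <- make_landscape(
    extent = config$study$extent,
    resolution = config$landscape$resolution,
    forest_smoothness = config$landscape$forest_smoothness,
    n_roads = config$landscape$n_roads,
    n_tracks = config$landscape$n_tracks,
    seed = derive_seed(seed, 1)
  )
  detectors <- build_detector_grid(config$study$extent, config$study$cell_side) |>
    add_detector_covariates(land)
  geom <- config_geometry(config, land$forest)

  beta_d <- unlist(config$population$beta_d)
  lambda0 <- unlist(config$detection$lambda0_link)
  sigma <- unlist(config$detection$sigma_by_sex)

  sessions <- as.character(config$sessions)
  sims <- purrr::imap(setNames(sessions, sessions), function(s, nm) {
    i <- match(s, sessions)
    pop <- simulate_population(geom$state, beta_d,
                               psi_male = config$population$psi_male,
                               seed = derive_seed(seed, 10 + i), session = s)
    enc <- simulate_detections(pop, detectors, lambda0, sigma,
                               seed = derive_seed(seed, 100 + i))
    samples <- detections_to_samples(enc, detectors,
                                     seed = derive_seed(seed, 200 + i))
    list(pop = pop, enc = enc, samples = samples)
  })
  samples <- purrr::map_dfr(sims, "samples")
  encounters <- new_scr_encounters(purrr::map(sims, function(x) x$enc[[1]]))

  readr::write_csv(samples, file.path(out_dir, "samples.csv"))
  readr::write_csv(tibble::as_tibble(detectors), file.path(out_dir, "detectors.csv"))
  write_esri_ascii(land$forest, file.path(out_dir, "forest.asc"))
  write_esri_ascii(geom$smoothed, file.path(out_dir, "forest_smoothed.asc"))

  genotypes <- NULL
  if (isTRUE(config$genotyping$simulate)) {
    genotypes <- simulate_replicate_genotypes(
      samples, n_loci = config$genotyping$n_loci,
      error_rates = c(dropout = config$genotyping$dropout,
                      false_allele = config$genotyping$false_allele),
      seed = derive_seed(seed, 300)
    )
    readr::write_csv(genotypes, file.path(out_dir, "replicate_genotypes.csv"))
  }

  truth <- list(
    sessions = purrr::map(sims, function(x) {
      list(N = nrow(x$pop), n_detected = nrow(x$enc[[1]]$counts),
           Lambda = attr(x$pop, "Lambda"))
    }),
    parameters = list(beta_d = as.list(beta_d), lambda0_link = as.list(lambda0),
                      sigma_by_sex = as.list(sigma),
                      psi_male = config$population$psi_male),
    seed = seed
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- list.files(out_dir)
  write_manifest(out_dir, config, "simulate", files)

  invisible(list(landscape = land, detectors = detectors, state = geom$state,
                 encounters = encounters, samples = samples,
                 genotypes = genotypes, out_dir = out_dir))
}

read_detectors_csv <- function(path, extent, cell_side) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  attr(d, "cell_side") <- cell_side
  attr(d, "extent") <- as_extent(extent)
  class(d) <- c("scr_detectors", class(d))
  d
}

#' Fit and select models on a prepared dataset
#'
#' Reads the sample table, detector covariates and forest raster written by
#' [run_simulate()] (or assembled by hand in the same formats), builds the
#' buffered state space, snaps samples to detectors, fits the candidate set
#' and writes the AIC table and the retained fit.
#'
#' @param config An [scr_config()] whose `out_dir` holds the prepared data.
#' @return Invisibly, a list with `fits`, `table` and `retained`.
#' @export
run_fit_select <- function(config = scr_config()) {
  out_dir <- config$out_dir
  samples <- readr::read_csv(file.path(out_dir, "samples.csv"),
                             show_col_types = FALSE)
  detectors <- read_detectors_csv(file.path(out_dir, "detectors.csv"),
                                  config$study$extent, config$study$cell_side)
  forest <- read_esri_ascii(file.path(out_dir, "forest.asc"))
  geom <- config_geometry(config, forest)

  assignments <- assign_samples(samples, detectors)
  encounters <- make_encounters(assignments, detectors)

  specs <- if (identical(config$fit$candidates, "base")) {
    list(base = scr_model_spec())
  } else {
    candidate_set()
  }
  fits <- fit_candidates(encounters, geom$state, detectors, specs)
  tab <- model_table(fits)
  retained <- retained_model(fits)
  if (isTRUE(config$fit$hessian_retained) && is.null(retained$vcov)) {
    retained <- fit_scr(encounters, geom$state, detectors, retained$spec,
                        start = retained$coefficients, hessian = TRUE)
  }
  readr::write_csv(tibble::as_tibble(tab), file.path(out_dir, "model_table.csv"))
  write_fit_json(retained, file.path(out_dir, "retained_fit.json"))
  write_manifest(out_dir, config, "fit",
                 c("model_table.csv", "retained_fit.json"))
  invisible(list(fits = fits, table = tab, retained = retained,
                 encounters = encounters, state = geom$state,
                 detectors = detectors))
}

#' Predict density, abundance and home ranges from the retained fit
#'
#' Writes, per session, the expected and realized density surfaces (CSV and
#' ESRI ASCII grid), the abundance in the original searched study area with a
#' delta-method interval, and the sex-specific home-range report.
#'
#' @param config An [scr_config()] whose `out_dir` holds the prepared data
#'   and the retained fit.
#' @param fit Optionally, an `scr_fit` to use instead of reading
#'   `retained_fit.json`.
#' @return Invisibly, a list with surfaces, abundance and home ranges.
#' @export
run_predict <- function(config = scr_config(), fit = NULL) {
  out_dir <- config$out_dir
  fit_path <- file.path(out_dir, "retained_fit.json")
  if (is.null(fit)) {
    if (!file.exists(fit_path)) {
      abort("no retained fit found; run run_fit_select() first",
            class = "foxscr_error_usage")
    }
    fit <- read_fit_json(fit_path)
  }
  samples <- readr::read_csv(file.path(out_dir, "samples.csv"),
                             show_col_types = FALSE)
  detectors <- read_detectors_csv(file.path(out_dir, "detectors.csv"),
                                  config$study$extent, config$study$cell_side)
  forest <- read_esri_ascii(file.path(out_dir, "forest.asc"))
  geom <- config_geometry(config, forest)
  encounters <- make_encounters(assign_samples(samples, detectors), detectors)

  surfaces <- purrr::map(setNames(fit$session_labels, fit$session_labels),
                         function(s) {
    exp_surf <- expected_density(fit, geom$state, s)
    real_surf <- realized_density(fit, encounters, geom$state, detectors, s)
    readr::write_csv(tibble::as_tibble(exp_surf),
                     file.path(out_dir, sprintf("expected_density_%s.csv", s)))
    readr::write_csv(tibble::as_tibble(real_surf),
                     file.path(out_dir, sprintf("realized_density_%s.csv", s)))
    write_esri_ascii(surface_to_raster(exp_surf),
                     file.path(out_dir, sprintf("expected_density_%s.asc", s)))
    write_esri_ascii(surface_to_raster(real_surf),
                     file.path(out_dir, sprintf("realized_density_%s.asc", s)))
    list(expected = exp_surf, realized = real_surf)
  })
  nhat <- purrr::map_dfr(fit$session_labels, function(s) {
    abundance(fit, geom$state, region = config$study$extent, session = s)
  })
  hr <- home_ranges(fit)
  readr::write_csv(nhat, file.path(out_dir, "abundance.csv"))
  readr::write_csv(hr, file.path(out_dir, "home_ranges.csv"))
  write_manifest(out_dir, config, "predict",
                 c("abundance.csv", "home_ranges.csv"))
  invisible(list(surfaces = surfaces, abundance = nhat, home_ranges = hr,
                 fit = fit))
}

# Convert a density surface on the state-space lattice back to a raster.
surface_to_raster <- function(surface) {
  res <- attr(surface, "resolution")
  extent <- attr(surface, "extent")
  nx <- round(extent_width(extent) / res)
  ny <- round(extent_height(extent) / res)
  scr_raster(matrix(surface$density, ny, nx, byrow = TRUE), extent)
}

# JSON round-trip of a fitted model (estimates, uncertainty and the scalers
# needed to predict on the raw covariate scale).
write_fit_json <- function(fit, path) {
  payload <- list(
    spec = list(density = fit$spec$density, detection = fit$spec$detection,
                sigma = fit$spec$sigma),
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    loglik = fit$loglik,
    n_params = fit$n_params,
    aic = fit$aic,
    converged = fit$converged,
    session_labels = fit$session_labels,
    n_detected = as.list(setNames(as.integer(fit$n_detected),
                                  fit$session_labels)),
    det_scalers = fit$det_scalers,
    state_scalers = fit$state_scalers,
    standardize = fit$standardize,
    cell_area = fit$cell_area
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- scr_model_spec(p$spec$density, p$spec$detection,
                         if (length(p$spec$sigma) == 0) character() else p$spec$sigma)
  coefs <- unlist(p$coefficients)
  vc <- if (!is.null(p$vcov)) {
    m <- as.matrix(p$vcov)
    dimnames(m) <- list(names(coefs), names(coefs))
    m
  }
  structure(
    list(
      spec = spec, coefficients = coefs, loglik = p$loglik,
      n_params = p$n_params, aic = p$aic, vcov = vc,
      converged = p$converged, layout = param_layout(spec, p$session_labels),
      session_labels = p$session_labels,
      n_detected = unlist(p$n_detected),
      det_scalers = lapply(p$det_scalers, as.list),
      state_scalers = lapply(p$state_scalers, as.list),
      standardize = p$standardize, cell_area = p$cell_area
    ),
    class = "scr_fit"
  )
}
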