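# The simulation experiment behind the parameter-recovery and
# model-selection acceptance checks.  Study conditions: the searched area is
# 15 x 15 km with 500 x 500 m detector cells (900 detectors); density depends
# on smoothed forest cover (coefficient 2 on the z-scored covariate) with the
# intercept set so that about 60 activity centres are expected inside the
# searched 225 km^2; detection is sex-structured (sigma 1.6 km for females,
# 2.0 km for males, a +0.3 male effect on the log baseline rate) with a
# search-effort effect, and the baseline rate gives a few detections per
# detected individual.  The analysis state space uses 1 km cells inside an
# 8 km (4 x sigma_max) buffer; candidate-model screening uses a coarser
# 1.5 km mask for speed.  25 replicates for recovery, the first 5 for the
# 16-model selection, memoised so both acceptance blocks share one run.
recovery_experiment <- local({
  cache <- NULL
  function(n_rep = 25, n_select = 5) {
    if (!is.null(cache)) return(cache)
    extent <- c(0, 15, 0, 15)
    land <- make_landscape(extent, resolution = 0.5, forest_smoothness = 2,
                           n_roads = 3, n_tracks = 8, seed = 424242)
    det <- add_detector_covariates(build_detector_grid(extent, 0.5), land)
    forest_sm <- smooth_forest(land$forest, 1)
    st <- build_state_space(extent, resolution = 1,
                            buffer_km = buffer_width(2.0),
                            covariates = list(forest = forest_sm))
    st_screen <- build_state_space(extent, resolution = 1.5,
                                   buffer_km = buffer_width(2.0),
                                   covariates = list(forest = forest_sm))
    z <- as.numeric(scale(st$forest))
    core <- st$x >= 0 & st$x <= 15 & st$y >= 0 & st$y <= 15
    beta_forest <- 2
    b0 <- log(60 / sum(exp(beta_forest * z[core]) * attr(st, "cell_area")))
    spec_gen <- scr_model_spec(~ session + forest, ~ session + effort + sex,
                               ~sex)
    truth <- c(
      "D.(Intercept)" = b0, "D.forest" = beta_forest,
      "p0.(Intercept)" = log(0.03), "p0.effort" = 0.4, "p0.sexM" = 0.3,
      "logsigma.(Intercept)" = log(1.6), "logsigma.sexM" = log(2.0 / 1.6),
      "psi.logitM" = 0
    )

    reps <- purrr::map(seq_len(n_rep), function(r) {
      pop <- simulate_population(st, c("(Intercept)" = b0, forest = beta_forest),
                                 psi_male = 0.5, seed = 7000 + r)
      enc <- simulate_detections(
        pop, det, c("(Intercept)" = log(0.03), effort_km = 0.4, sexM = 0.3),
        sigma_by_sex = c(F = 1.6, M = 2.0), seed = 8000 + r
      )
      fit <- suppressWarnings(
        fit_scr(enc, st, det, spec_gen, control = list(reltol = 1e-9))
      )
      top_model <- NA_character_
      if (r <= n_select) {
        fits <- suppressWarnings(
          fit_candidates(enc, st_screen, det, candidate_set(),
                         control = list(reltol = 1e-8))
        )
        tab <- suppressWarnings(model_table(fits))
        top_model <- tab$model[1]
        top_dAIC <- tab$dAIC[1]
      } else {
        top_dAIC <- NA_real_
      }
      list(
        coef = coef(fit),
        se = sqrt(pmax(diag(fit$vcov), 0)),
        converged = fit$converged,
        n_detected = nrow(enc[[1]]$counts),
        mean_detections = sum(enc[[1]]$counts) / max(nrow(enc[[1]]$counts), 1),
        top_model = top_model,
        top_dAIC = top_dAIC
      )
    })

    cache <<- list(
      truth = truth,
      spec_gen = spec_gen,
      coef = do.call(rbind, purrr::map(reps, "coef")),
      se = do.call(rbind, purrr::map(reps, "se")),
      converged = purrr::map_lgl(reps, "converged"),
      n_detected = purrr::map_dbl(reps, "n_detected"),
      mean_detections = purrr::map_dbl(reps, "mean_detections"),
      top_models = purrr::map_chr(reps, "top_model"),
      top_dAIC = purrr::map_dbl(reps, "top_dAIC"),
      n_select = n_select
    )
    cache
  }
})
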