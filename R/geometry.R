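#' Build a regular detector grid
#'
#' Detectors are the centres of square grid cells tiling the searched study
#' area; field samples are later snapped to the nearest detector.  Detector
#' indices run west to east, then south to north.
#'
#' @param extent Searched study extent `c(x_min, x_max, y_min, y_max)` in km.
#' @param cell_side Detector cell side in km (default 0.5, i.e. 500 m cells);
#'   must divide both extent side lengths.
#' @return A tibble of class `scr_detectors` with columns `detector`, `x`,
#'   `y` and attributes `cell_side` and `extent`.
#' @examples
#' build_detector_grid(c(0, 15, 0, 15), 0.5)  # 900 detectors
#' @export
build_detector_grid <- function(extent, cell_side = 0.5) {
  extent <- as_extent(extent)
  if (cell_side <= 0) {
    abort("`cell_side` must be positive", class = "foxscr_error_domain")
  }
  if (!divides_evenly(extent_width(extent), cell_side) ||
      !divides_evenly(extent_height(extent), cell_side)) {
    abort("`cell_side` must divide both extent side lengths",
          class = "foxscr_error_config")
  }
  nx <- round(extent_width(extent) / cell_side)
  ny <- round(extent_height(extent) / cell_side)
  xs <- extent[1] + (seq_len(nx) - 0.5) * cell_side
  ys <- extent[3] + (seq_len(ny) - 0.5) * cell_side
  out <- tibble(
    detector = seq_len(nx * ny),
    x = rep(xs, times = ny),
    y = rep(ys, each = nx)
  )
  attr(out, "cell_side") <- cell_side
  attr(out, "extent") <- extent
  class(out) <- c("scr_detectors", class(out))
  out
}

#' Attach per-detector covariates from a landscape
#'
#' Computes the three detector-level covariates used by the detection model:
#' `effort_km` (length of searched routes - roads plus tracks - within the
#' detector cell), `road_km` (road length within the cell) and `forest_prop`
#' (forest cover at the detector cell).
#'
#' @param detectors An [build_detector_grid()] result.
#' @param landscape An [make_landscape()] result (or any list with `forest`,
#'   `roads`, `tracks`).
#' @return `detectors` with covariate columns added.
#' @export
add_detector_covariates <- function(detectors, landscape) {
  cell_side <- attr(detectors, "cell_side")
  extent <- attr(detectors, "extent")
  searched <- dplyr::bind_rows(landscape$roads, landscape$tracks)
  detectors$effort_km <- polyline_cell_lengths(searched, extent, cell_side)
  detectors$road_km <- polyline_cell_lengths(landscape$roads, extent, cell_side)
  detectors$forest_prop <- raster_lookup(landscape$forest, detectors$x, detectors$y)
  detectors
}

#' State-space buffer width from the largest space-use scale
#'
#' The state space must extend far enough beyond the searched area to contain
#' the activity centre of any individual exposed to sampling; the standard
#' rule of thumb is four times the largest estimated half-normal scale.
#'
#' @param sigma_max Largest half-normal scale parameter (km); positive.
#' @return Buffer width in km (`4 * sigma_max`).
#' @examples
#' buffer_width(2)  # 8 km
#' @export
buffer_width <- function(sigma_max) {
  if (!is.numeric(sigma_max) || any(sigma_max <= 0)) {
    abort("`sigma_max` must be positive", class = "foxscr_error_domain")
  }
  4 * sigma_max
}

#' Build a discretized state space around the searched area
#'
#' The state space is the support of possible activity centres: a regular grid
#' covering the searched extent expanded by a buffer on all sides.  Covariate
#' rasters are sampled at cell centres; cells outside raster coverage take the
#' nearest covered cell's value.  The buffer is snapped up to the nearest
#' multiple of `resolution` so the grid tiles exactly.
#'
#' @param searched_extent Searched study extent in km.
#' @param resolution State-space cell side in km (defaults to the 0.5 km
#'   detector cell side).
#' @param buffer_km Buffer width in km (see [buffer_width()]).
#' @param covariates Named list of [scr_raster()] covariate surfaces; each
#'   becomes a column.
#' @return A tibble of class `scr_state` with columns `cell`, `x`, `y` and one
#'   column per covariate, plus attributes `resolution`, `cell_area`,
#'   `buffer_km`, `extent` (buffered) and `searched_extent`.
#' @examples
#' st <- build_state_space(c(0, 15, 0, 15), 0.5, buffer_km = 8)
#' nrow(st)  # 62 * 62 = 3844 cells
#' @export
build_state_space <- function(searched_extent, resolution = 0.5, buffer_km = 0,
                              covariates = list()) {
  searched_extent <- as_extent(searched_extent)
  if (resolution <= 0) {
    abort("`resolution` must be positive", class = "foxscr_error_domain")
  }
  if (buffer_km < 0) {
    abort("`buffer_km` must be non-negative", class = "foxscr_error_domain")
  }
  b <- ceiling(buffer_km / resolution - 1e-9) * resolution
  if (abs(b - buffer_km) > 1e-9) {
    inform(sprintf("buffer snapped up from %.3g to %.3g km to align with the grid",
                   buffer_km, b))
  }
  extent <- as_extent(searched_extent + c(-b, b, -b, b))
  if (!divides_evenly(extent_width(extent), resolution) ||
      !divides_evenly(extent_height(extent), resolution)) {
    abort("`resolution` must divide the buffered extent side lengths",
          class = "foxscr_error_config")
  }
  nx <- round(extent_width(extent) / resolution)
  ny <- round(extent_height(extent) / resolution)
  xs <- extent[1] + (seq_len(nx) - 0.5) * resolution
  ys <- extent[3] + (seq_len(ny) - 0.5) * resolution
  out <- tibble(
    cell = seq_len(nx * ny),
    x = rep(xs, times = ny),
    y = rep(ys, each = nx)
  )
  for (nm in names(covariates)) {
    r <- covariates[[nm]]
    if (!inherits(r, "scr_raster")) {
      abort("each covariate must be an scr_raster", class = "foxscr_error_config")
    }
    overlaps <- r$extent[1] < extent[2] && r$extent[2] > extent[1] &&
      r$extent[3] < extent[4] && r$extent[4] > extent[3]
    if (!overlaps) {
      abort(sprintf("covariate raster '%s' does not overlap the state space", nm),
            class = "foxscr_error_config")
    }
    out[[nm]] <- raster_lookup(r, out$x, out$y)
  }
  attr(out, "resolution") <- resolution
  attr(out, "cell_area") <- resolution^2
  attr(out, "buffer_km") <- b
  attr(out, "extent") <- extent
  attr(out, "searched_extent") <- searched_extent
  class(out) <- c("scr_state", class(out))
  out
}

#' Smooth a forest-cover raster over a circular neighbourhood
#'
#' Density in SCR reflects the placement of whole home ranges, so the density
#' covariate is forest cover averaged over a neighbourhood (default radius
#' 1 km) rather than the raw cell value.  The neighbourhood of a cell is the
#' set of cells whose centres lie within `radius_km` of its centre, inclusive.
#'
#' @param raster An [scr_raster()] of per-cell forest proportion.
#' @param radius_km Neighbourhood radius in km; `0` returns the input.
#' @return An [scr_raster()] of smoothed values.
#' @export
smooth_forest <- function(raster, radius_km = 1) {
  raster_focal_mean(raster, radius_km)
}

#' Assign samples to their nearest detector
#'
#' Reproduces the data-preparation rule for NGS records: samples outside the
#' study extent, or missing coordinates, individual ID or sex, are dropped
#' (with the reason recorded); the remainder are snapped to the nearest
#' detector centre (Euclidean distance, ties broken toward the lowest detector
#' index) and accumulated into per-individual, per-detector counts.
#'
#' @param samples Tibble with columns `sample_id`, `individual_id`, `sex`,
#'   `x_km`, `y_km` and optionally `session` (defaults to `"s1"`).
#' @param detectors An [build_detector_grid()] result.
#' @param study_extent Extent within which samples count as detections;
#'   defaults to the detector grid extent.
#' @return A tibble of class `scr_assignments` with columns `session`,
#'   `individual_id`, `sex`, `detector`, `n`, and attributes `dropped` (a
#'   tibble of `sample_id`, `reason`), `per_sample` (per-sample detector
#'   assignments) and `n_input`/`n_assigned` for conservation checks.
#' @export
assign_samples <- function(samples, detectors, study_extent = NULL) {
  study_extent <- as_extent(study_extent %||% attr(detectors, "extent"))
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample IDs in input", class = "foxscr_error_input")
  }
  if (!"session" %in% names(samples)) samples$session <- "s1"

  reason <- rep(NA_character_, nrow(samples))
  miss_xy <- is.na(samples$x_km) | is.na(samples$y_km)
  miss_id <- is.na(samples$individual_id)
  miss_sex <- is.na(samples$sex)
  reason[miss_sex] <- "missing_sex"
  reason[miss_id] <- "missing_individual"
  reason[miss_xy] <- "missing_coordinates"
  outside <- !miss_xy & !in_extent(samples$x_km, samples$y_km, study_extent)
  reason[is.na(reason) & outside] <- "outside_study_area"

  dropped <- tibble(sample_id = samples$sample_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  kept <- samples[is.na(reason), ]
  if (nrow(dropped) > 0) {
    inform(sprintf("assign_samples: dropped %d of %d samples (%s)",
                   nrow(dropped), nrow(samples),
                   paste(sprintf("%s: %d", names(table(dropped$reason)),
                                 table(dropped$reason)), collapse = ", ")))
  }

  det_idx <- nearest_detector(kept$x_km, kept$y_km, detectors)
  per_sample <- tibble(
    sample_id = kept$sample_id, session = kept$session,
    individual_id = kept$individual_id, sex = kept$sex, detector = det_idx
  )
  out <- per_sample |>
    dplyr::count(.data$session, .data$individual_id, .data$sex, .data$detector,
                 name = "n")
  attr(out, "dropped") <- dropped
  attr(out, "per_sample") <- per_sample
  attr(out, "n_input") <- nrow(samples)
  attr(out, "n_assigned") <- nrow(kept)
  class(out) <- c("scr_assignments", class(out))
  out
}

# Nearest detector on a regular lattice; equidistant points snap to the lower
# detector index (lower column, then lower row).
nearest_detector <- function(x, y, detectors) {
  cell_side <- attr(detectors, "cell_side")
  extent <- attr(detectors, "extent")
  if (is.null(cell_side) || is.null(extent)) {
    # fall back to brute force if grid attributes were stripped
    d2 <- outer(x, detectors$x, "-")^2 + outer(y, detectors$y, "-")^2
    return(detectors$detector[apply(d2, 1, which.min)])
  }
  nx <- round(extent_width(extent) / cell_side)
  ny <- round(extent_height(extent) / cell_side)
  snap_axis <- function(p, p0, n) {
    idx <- (p - p0) / cell_side + 0.5   # fractional centre index
    lo <- floor(idx)
    up <- lo + 1
    pick_lo <- (idx - lo) <= (up - idx) + 1e-12  # tie -> lower index
    out <- ifelse(pick_lo, lo, up)
    pmin(pmax(out, 1), n)
  }
  ix <- snap_axis(x, extent[1], nx)
  iy <- snap_axis(y, extent[3], ny)
  as.integer((iy - 1) * nx + ix)
}

#' Build encounter data from sample assignments
#'
#' Converts long-format detector assignments into the per-session count
#' matrices the likelihood consumes: one row per detected individual, one
#' column per detector.
#'
#' @param assignments An [assign_samples()] result (or a tibble with columns
#'   `session`, `individual_id`, `sex`, `detector`, `n`).
#' @param detectors The detector grid the assignments refer to.
#' @return An object of class `scr_encounters`: a list of session records,
#'   each with elements `counts` (matrix, individuals x detectors), `sex`
#'   (named character vector) and `session`.
#' @export
make_encounters <- function(assignments, detectors) {
  J <- nrow(detectors)
  sessions <- sort(unique(assignments$session))
  recs <- purrr::map(sessions, function(s) {
    a <- assignments[assignments$session == s, ]
    ids <- sort(unique(a$individual_id))
    counts <- matrix(0L, nrow = length(ids), ncol = J,
                     dimnames = list(ids, NULL))
    counts[cbind(match(a$individual_id, ids), a$detector)] <- as.integer(a$n)
    sex <- setNames(a$sex[match(ids, a$individual_id)], ids)
    new_scr_session(counts, sex, session = s)
  })
  new_scr_encounters(recs)
}

new_scr_session <- function(counts, sex, session, truth = NULL) {
  stopifnot(nrow(counts) == length(sex))
  bad <- rowSums(counts) < 1
  if (any(bad)) {
    abort("every detected individual must have at least one detection",
          class = "foxscr_error_input")
  }
  structure(list(counts = counts, sex = unname(sex) |> setNames(rownames(counts)),
                 session = session, truth = truth),
            class = "scr_session")
}

new_scr_encounters <- function(sessions) {
  names(sessions) <- purrr::map_chr(sessions, "session")
  structure(sessions, class = "scr_encounters")
}

#' @export
print.scr_encounters <- function(x, ...) {
  cat("<scr_encounters>\n")
  for (s in x) {
    cat(sprintf("  session %s: %d individuals (%d F / %d M), %d detections\n",
                s$session, nrow(s$counts), sum(s$sex == "F"), sum(s$sex == "M"),
                sum(s$counts)))
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.scr_encounters <- function(x, ...) {
  purrr::map_dfr(x, function(s) {
    idx <- which(s$counts > 0, arr.ind = TRUE)
    tibble(
      session = s$session,
      individual_id = rownames(s$counts)[idx[, 1]],
      sex = unname(s$sex[idx[, 1]]),
      detector = idx[, 2],
      n = s$counts[idx]
    )
  })
}
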