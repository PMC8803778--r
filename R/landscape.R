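#' Generate a synthetic study landscape
#'
#' Builds the landscape layers the sampling design needs: a spatially
#' autocorrelated forest-cover surface (smoothed white noise, min-max rescaled
#' to `[0, 1]`), a set of roads crossing the area, and a set of search tracks
#' (transects) along which sampling effort accrues.  Everything is
#' deterministic given `seed`.
#'
#' @param extent Study extent `c(x_min, x_max, y_min, y_max)` in km.
#' @param resolution Forest raster cell side in km; must divide both extent
#'   side lengths.
#' @param forest_smoothness Correlation length (km) of the forest field: the
#'   radius of the moving-average kernel applied to white noise.  `Inf` gives
#'   a constant surface.
#' @param n_roads Number of road polylines crossing the extent.
#' @param n_tracks Number of additional search-track polylines (roads are also
#'   searched, so total effort comes from roads plus tracks).
#' @param seed Integer seed (required).
#' @return An object of class `scr_landscape`: a list with elements `forest`
#'   (an [scr_raster()]), `roads` and `tracks` (tibbles of polyline vertices
#'   with columns `line_id`, `x`, `y`), `extent` and `resolution`.
#' @examples
#' land <- make_landscape(c(0, 15, 0, 15), resolution = 0.5, seed = 1)
#' range(land$forest$values)
#' @export
make_landscape <- function(extent = c(0, 15, 0, 15), resolution = 0.5,
                           forest_smoothness = 2, n_roads = 3, n_tracks = 8,
                           seed) {
  extent <- as_extent(extent)
  seed <- check_seed(seed)
  if (!divides_evenly(extent_width(extent), resolution) ||
      !divides_evenly(extent_height(extent), resolution)) {
    abort("`resolution` must divide both extent side lengths",
          class = "foxscr_error_config")
  }
  nx <- round(extent_width(extent) / resolution)
  ny <- round(extent_height(extent) / resolution)

  withr::with_seed(seed, {
    if (is.infinite(forest_smoothness)) {
      forest <- scr_raster(matrix(0.5, ny, nx), extent)
    } else {
      noise <- scr_raster(matrix(rnorm(nx * ny), ny, nx), extent)
      sm <- raster_focal_mean(noise, forest_smoothness)
      v <- sm$values
      rng <- range(v)
      if (diff(rng) < 1e-12) {
        v[] <- 0.5
      } else {
        v <- (v - rng[1]) / diff(rng)
      }
      forest <- scr_raster(v, extent)
    }
    roads <- random_polylines(n_roads, extent, prefix = "road")
    tracks <- random_polylines(n_tracks, extent, prefix = "track")
  })

  structure(
    list(forest = forest, roads = roads, tracks = tracks,
         extent = extent, resolution = resolution),
    class = "scr_landscape"
  )
}

#' @export
print.scr_landscape <- function(x, ...) {
  cat(sprintf(
    "<scr_landscape> %g x %g km, %.3g km resolution, %d roads, %d tracks\n",
    extent_width(x$extent), extent_height(x$extent), x$resolution,
    dplyr::n_distinct(x$roads$line_id), dplyr::n_distinct(x$tracks$line_id)
  ))
  invisible(x)
}

# Random polylines crossing the extent edge to edge, with jittered interior
# vertices; emulates roads / snowmobile and ski transects.
random_polylines <- function(n, extent, prefix = "line", n_mid = 3) {
  if (n == 0) {
    return(tibble(line_id = character(), x = double(), y = double()))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    horizontal <- runif(1) < 0.5
    w <- extent_width(extent)
    h <- extent_height(extent)
    if (horizontal) {
      y0 <- runif(1, extent[3], extent[4])
      y1 <- runif(1, extent[3], extent[4])
      xs <- seq(extent[1], extent[2], length.out = n_mid + 2)
      ys <- seq(y0, y1, length.out = n_mid + 2) +
        c(0, rnorm(n_mid, sd = h / 12), 0)
      ys <- pmin(pmax(ys, extent[3]), extent[4])
    } else {
      x0 <- runif(1, extent[1], extent[2])
      x1 <- runif(1, extent[1], extent[2])
      ys <- seq(extent[3], extent[4], length.out = n_mid + 2)
      xs <- seq(x0, x1, length.out = n_mid + 2) +
        c(0, rnorm(n_mid, sd = w / 12), 0)
      xs <- pmin(pmax(xs, extent[1]), extent[2])
    }
    tibble(line_id = sprintf("%s_%02d", prefix, i), x = xs, y = ys)
  })
}

# Total polyline length (km) falling in each cell of a regular grid, by dense
# sampling of points along each segment (step = cell_side / 20).  Adequate for
# synthetic effort surfaces; not an exact geometric clip.
polyline_cell_lengths <- function(lines, extent, cell_side) {
  nx <- round(extent_width(extent) / cell_side)
  ny <- round(extent_height(extent) / cell_side)
  total <- numeric(nx * ny)
  if (nrow(lines) == 0) return(total)
  step <- cell_side / 20
  for (id in unique(lines$line_id)) {
    v <- lines[lines$line_id == id, ]
    for (k in seq_len(nrow(v) - 1)) {
      dx <- v$x[k + 1] - v$x[k]
      dy <- v$y[k + 1] - v$y[k]
      len <- sqrt(dx^2 + dy^2)
      if (len < 1e-12) next
      npts <- max(1L, ceiling(len / step))
      t_mid <- (seq_len(npts) - 0.5) / npts
      px <- v$x[k] + t_mid * dx
      py <- v$y[k] + t_mid * dy
      keep <- in_extent(px, py, extent)
      if (!any(keep)) next
      ix <- pmin(pmax(ceiling((px[keep] - extent[1]) / cell_side), 1L), nx)
      iy <- pmin(pmax(ceiling((py[keep] - extent[3]) / cell_side), 1L), ny)
      idx <- (iy - 1L) * nx + ix
      seg_len <- len / npts
      tab <- tabulate(idx, nbins = nx * ny)
      total <- total + tab * seg_len
    }
  }
  total
}
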