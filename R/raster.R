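#' Create a gridded raster surface
#'
#' A minimal planar raster: a matrix of cell values on a regular grid in km
#' coordinates.  Row 1 of `values` is the southernmost row (lowest y); columns
#' run west to east.  Used for forest-cover surfaces and density maps.
#'
#' @param values Numeric matrix of cell values, `nrow = ny`, `ncol = nx`.
#' @param extent Extent `c(x_min, x_max, y_min, y_max)` in km.
#' @param resolution Cell side in km; must be consistent with `values` and
#'   `extent`.
#' @return An object of class `scr_raster`.
#' @export
scr_raster <- function(values, extent, resolution = NULL) {
  extent <- as_extent(extent)
  if (!is.matrix(values)) values <- as.matrix(values)
  nx <- ncol(values)
  ny <- nrow(values)
  res_x <- extent_width(extent) / nx
  res_y <- extent_height(extent) / ny
  if (abs(res_x - res_y) > 1e-8) {
    abort("raster cells must be square", class = "foxscr_error_config")
  }
  if (!is.null(resolution) && abs(resolution - res_x) > 1e-8) {
    abort("`resolution` disagrees with extent and matrix dimensions",
          class = "foxscr_error_config")
  }
  structure(
    list(values = values, extent = extent, resolution = res_x),
    class = "scr_raster"
  )
}

#' @export
print.scr_raster <- function(x, ...) {
  cat(sprintf(
    "<scr_raster> %d x %d cells, %.3g km resolution, extent [%g, %g] x [%g, %g]\n",
    ncol(x$values), nrow(x$values), x$resolution,
    x$extent[1], x$extent[2], x$extent[3], x$extent[4]
  ))
  invisible(x)
}

# Cell-centre coordinates of a raster, as a tibble in raster storage order.
raster_cells <- function(r) {
  nx <- ncol(r$values)
  ny <- nrow(r$values)
  xs <- r$extent[1] + (seq_len(nx) - 0.5) * r$resolution
  ys <- r$extent[3] + (seq_len(ny) - 0.5) * r$resolution
  tibble(
    x = rep(xs, times = ny),
    y = rep(ys, each = nx),
    value = as.vector(t(r$values))
  )
}

# Nearest-cell lookup with clamping, so points outside raster coverage take
# the value of the closest covered cell (nearest-cell extension).
raster_lookup <- function(r, x, y) {
  ix <- pmin(pmax(ceiling((x - r$extent[1]) / r$resolution), 1L), ncol(r$values))
  iy <- pmin(pmax(ceiling((y - r$extent[3]) / r$resolution), 1L), nrow(r$values))
  r$values[cbind(iy, ix)]
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text grid interchange used for covariate surfaces and density maps.
#' Values are stored row-wise from the northernmost row, as the format
#' requires; `read_esri_ascii()` returns them in [scr_raster()] south-up
#' storage order.
#'
#' @param path File path.
#' @param raster An [scr_raster()].
#' @param digits Significant digits written.
#' @return `read_esri_ascii()` returns an [scr_raster()];
#'   `write_esri_ascii()` returns `path` invisibly.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      body_start <- i + 1L
    } else {
      break
    }
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) {
    abort("not a valid ESRI ASCII grid header", class = "foxscr_error_input")
  }
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  m <- m[ny:1, , drop = FALSE]  # top-down file order -> south-up storage
  scr_raster(m, extent = c(
    hdr$xllcorner, hdr$xllcorner + nx * hdr$cellsize,
    hdr$yllcorner, hdr$yllcorner + ny * hdr$cellsize
  ))
}

#' @rdname read_esri_ascii
#' @export
write_esri_ascii <- function(raster, path, digits = 7) {
  m <- raster$values
  ny <- nrow(m)
  m_out <- m[ny:1, , drop = FALSE]
  m_out[is.na(m_out)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", ny),
    sprintf("xllcorner %.10g", raster$extent[1]),
    sprintf("yllcorner %.10g", raster$extent[3]),
    sprintf("cellsize %.10g", raster$resolution),
    "NODATA_value -9999"
  )
  body <- apply(m_out, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Focal (moving-window) mean over cells whose centres lie within `radius_km`,
# inclusive.  Edge cells average over the in-bounds part of the window.
raster_focal_mean <- function(r, radius_km) {
  if (radius_km < 0) {
    abort("smoothing radius must be non-negative", class = "foxscr_error_domain")
  }
  m <- r$values
  if (radius_km == 0) return(r)
  k <- floor(radius_km / r$resolution + 1e-9)
  offs <- expand.grid(dx = -k:k, dy = -k:k)
  offs <- offs[(offs$dx^2 + offs$dy^2) * r$resolution^2 <= radius_km^2 + 1e-9, ]
  ny <- nrow(m); nx <- ncol(m)
  acc <- matrix(0, ny, nx)
  cnt <- matrix(0, ny, nx)
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    src_r <- max(1, 1 - dy):min(ny, ny - dy)
    src_c <- max(1, 1 - dx):min(nx, nx - dx)
    dst_r <- src_r + dy
    dst_c <- src_c + dx
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + m[src_r, src_c]
    cnt[dst_r, dst_c] <- cnt[dst_r, dst_c] + 1
  }
  scr_raster(acc / cnt, extent = r$extent)
}
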