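# Internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Round half away from zero, matching how results tables are typically printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# An extent is c(x_min, x_max, y_min, y_max) in km.
as_extent <- function(x) {
  if (!is.numeric(x) || length(x) != 4) {
    abort("an extent must be numeric c(x_min, x_max, y_min, y_max) in km",
          class = "foxscr_error_config")
  }
  x <- unname(x)
  if (x[2] <= x[1] || x[4] <= x[3]) {
    abort("extent has non-positive width or height", class = "foxscr_error_config")
  }
  setNames(x, c("x_min", "x_max", "y_min", "y_max"))
}

extent_width <- function(extent) unname(extent[2] - extent[1])
extent_height <- function(extent) unname(extent[4] - extent[3])

divides_evenly <- function(width, step, tol = 1e-8) {
  abs(width / step - round(width / step)) < tol
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("a single integer `seed` is required for every stochastic operation",
          class = "foxscr_error_config")
  }
  as.integer(seed %% .Machine$integer.max)
}

# Deterministic per-stage sub-seed derived from a base seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}

in_extent <- function(x, y, extent) {
  x >= extent[1] & x <= extent[2] & y >= extent[3] & y <= extent[4]
}

# z-standardisation bookkeeping so fitted coefficients can be mapped back to
# the raw covariate scale at prediction time.
make_scaler <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) s <- 1
  list(mean = mean(x), sd = s)
}

apply_scaler <- function(x, scaler) (x - scaler$mean) / scaler$sd
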