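# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulator calls are reproducible
# without clobbering user RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gaussian bump parameterized by its full width at half maximum.
gauss_fwhm <- function(x, center, fwhm) {
  exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

# Wrap angles into [0, 2*pi).
wrap_angle <- function(theta) theta %% (2 * pi)

# Signed smallest angular difference a - b in (-pi, pi].
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Periodic linear interpolation of y(theta) with period 2*pi.
# theta must be sorted increasing within [0, 2*pi).
interp_periodic <- function(theta, y, theta_out) {
  n <- length(theta)
  tx <- c(theta[n] - 2 * pi, theta, theta[1] + 2 * pi)
  ty <- c(y[n], y, y[1])
  approx(tx, ty, xout = wrap_angle(theta_out), rule = 2)$y
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
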