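# internal numerical helpers

# trapezoidal rule on an arbitrary (typically uniform) grid
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L))) / 2
}

# index of the grid node closest to x0; errors if not within half a step
grid_node <- function(r, x0, what = "value") {
  j <- which.min(abs(r - x0))
  dr <- if (length(r) > 1L) r[2L] - r[1L] else Inf
  if (abs(r[j] - x0) > dr / 2 + 1e-12)
    stop(sprintf("grid does not contain a node near %s = %g", what, x0))
  j
}

# linear convolution of a uniformly sampled signal with a short kernel,
# via FFT; returns the central part aligned with `x`.  Equivalent to
# trapezoid quadrature of the convolution integral because the kernels
# used here vanish at both support endpoints.
conv_uniform <- function(x, kernel, dr) {
  nk <- length(kernel)
  stopifnot(nk %% 2L == 1L)  # kernel centred on its middle sample
  half <- (nk - 1L) / 2L
  full <- stats::convolve(x, rev(kernel), type = "open") * dr
  full[(half + 1L):(half + length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
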