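# Exact structure of the 1D hard-rod (Tonks) fluid.
#
# In the grand-canonical Tonks fluid the distance from a particle to its
# n-th neighbour on the right is gamma-distributed with rate beta*p =
# rho/(1 - rho*sigma), shifted by n*sigma; summing the neighbour
# distributions and dividing by rho gives the exact g(r).

# reduced pressure beta*p of the Tonks equation of state
tonks_betap <- function(spec) spec$rho / (1 - spec$rho * spec$sigma)

check_tonks <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim != 1L)
    stop("unsupported model: the Tonks fluid is one-dimensional (dim = 1)")
  if (spec$rho * spec$sigma >= 1)
    stop("invalid state: rho*sigma must be < 1")
  invisible(spec)
}

#' Distance distribution of the n-th neighbour in the 1D hard-rod fluid
#'
#' Probability density `p_n(r)` that the n-th nearest neighbour to the
#' right of a given rod lies at distance `r`: a gamma density with shape
#' `n` and rate `beta*p = rho / (1 - rho*sigma)`, shifted by `n*sigma`
#' (the space blocked by the intervening hard cores).
#'
#' @param n neighbour order, integer >= 1.
#' @param spec a 1D [fluid_spec()].
#' @param r distances (vectorised), >= 0.
#' @return Density values; 0 for \eqn{r < n\sigma}.
#' @examples
#' sp <- fluid_spec(1, 0.8, dim = 1)
#' tonks_nn_distribution(1, sp, c(0.5, 1, 2))
#' @export
tonks_nn_distribution <- function(n, spec, r) {
  check_tonks(spec)
  stopifnot(n >= 1, n == round(n), all(r >= 0))
  bp <- tonks_betap(spec)
  x <- r - n * spec$sigma
  out <- numeric(length(r))
  ok <- x >= 0
  out[ok] <- dgamma(x[ok], shape = n, rate = bp)
  out
}

#' Exact radial distribution function of the 1D hard-rod fluid
#'
#' Sums the neighbour-distance densities `p_n(r)` over n (both sides of
#' the tagged particle are equivalent, hence the single-sided sum
#' divided by `rho`).  The sum is truncated once the omitted terms are
#' below machine precision on the whole grid: terms with
#' `n*sigma > r_max + 10 * n_extra / (beta*p)` widths are dropped.
#'
#' The returned grid starts at 0; nodes strictly inside the hard core
#' hold 0 and the node at \eqn{r = \sigma} holds the contact limit
#' `g(sigma+) = 1 / (1 - rho*sigma)`.
#'
#' @param spec a 1D [fluid_spec()].
#' @param r_max largest tabulated distance (default `50 * sigma`).
#' @param dr grid spacing (default `1e-3 * sigma`).
#' @param n_cap safety cap on the number of neighbour terms (default
#'   4096); exceeding it raises an error suggesting a smaller `r_max`.
#' @return A [tabulated_rdf()].
#' @examples
#' rdf <- tonks_rdf(fluid_spec(1, 0.8, dim = 1), r_max = 10)
#' rdf$g[rdf$r == 0.8]  # contact value 1/(1 - 0.8) = 5
#' @export
tonks_rdf <- function(spec, r_max = 50 * spec$sigma, dr = 1e-3 * spec$sigma,
                      n_cap = 4096L) {
  check_tonks(spec)
  bp <- tonks_betap(spec)
  # include terms until the gamma density is negligible at r_max:
  # mean of term n is n*(sigma + 1/bp); 10 rate-scale widths of slack
  n_max <- ceiling((r_max + 10 * (1 + sqrt(r_max * bp)) / bp) /
                     (spec$sigma + 1 / bp)) + 5L
  if (n_max > n_cap)
    stop("r_max = ", r_max, " requires ", n_max, " neighbour terms, above the cap of ",
         n_cap, "; reduce r_max or raise n_cap")
  r <- seq(0, r_max, by = dr)
  g <- numeric(length(r))
  for (n in seq_len(n_max)) {
    x <- r - n * spec$sigma
    ok <- x >= 0
    if (!any(ok)) break
    g[ok] <- g[ok] + dgamma(x[ok], shape = n, rate = bp)
  }
  tabulated_rdf(r, g / spec$rho, spec, hard_core = TRUE)
}
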