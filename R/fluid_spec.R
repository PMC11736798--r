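#' Thermodynamic state of a hard-core fluid
#'
#' Bundles the number density, hard-core diameter, spatial dimension and
#' inverse temperature of a homogeneous hard-sphere (or hard-rod) fluid.
#' All lengths are expressed in the same units as `sigma`; hard-core
#' systems are athermal, so `beta` only fixes the unit of pressure.
#'
#' @param rho number density (particles per hypervolume). Must satisfy
#'   `rho * sigma < 1` in 1D and a packing fraction
#'   `eta = pi * rho * sigma^3 / 6` below close packing `pi / sqrt(18)`
#'   in 3D.
#' @param sigma hard-core diameter (default 1, i.e. reduced units).
#' @param dim spatial dimension, 1 or 3.
#' @param beta inverse temperature (default 1; athermal models).
#'
#' @return An object of class `fluid_spec`.
#' @examples
#' fluid_spec(rho = 1, sigma = 0.8, dim = 1)
#' fluid_spec(rho = 0.4, dim = 3)
#' @export
fluid_spec <- function(rho, sigma = 1, dim = 3L, beta = 1) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (rho <= 0) stop("rho must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (!dim %in% c(1L, 3L)) stop("dim must be 1 or 3")
  dim <- as.integer(dim)
  if (dim == 1L && rho * sigma >= 1)
    stop("invalid 1D state: filling fraction rho*sigma = ",
         format(rho * sigma), " must be < 1")
  if (dim == 3L) {
    eta <- pi * rho * sigma^3 / 6
    # close packing itself (the FCC solid) is admissible
    if (eta > pi / sqrt(18) + 1e-9)
      stop("invalid 3D state: packing fraction eta = ", format(eta),
           " exceeds close packing pi/sqrt(18)")
  }
  structure(list(rho = rho, sigma = sigma, dim = dim, beta = beta),
            class = "fluid_spec")
}

#' Packing (filling) fraction of a fluid state
#'
#' `rho * sigma` in 1D, `pi * rho * sigma^3 / 6` in 3D.
#'
#' @param spec a [fluid_spec()].
#' @return Dimensionless filling fraction.
#' @export
packing_fraction <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim == 1L) spec$rho * spec$sigma else pi * spec$rho * spec$sigma^3 / 6
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> %dD hard-core fluid: rho = %g, sigma = %g, beta = %g (eta = %.4f)\n",
              x$dim, x$rho, x$sigma, x$beta, packing_fraction(x)))
  invisible(x)
}
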