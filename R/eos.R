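# Closed-form equations of state used as thermodynamic ground truth.
#
# Throughout, nu_inf denotes the thermodynamic-limit relative number
# fluctuation rho*kappa_T/beta = 1 / d(beta p)/d rho.

compressibility_result <- function(kappa_T, nu_inf, route) {
  structure(list(kappa_T = kappa_T, nu_inf = nu_inf, route = route),
            class = "compressibility_result")
}

#' @export
print.compressibility_result <- function(x, ...) {
  cat(sprintf("<compressibility_result> route = %s: kappa_T = %.6g, nu_inf = %.6g\n",
              x$route, x$kappa_T, x$nu_inf))
  invisible(x)
}

#' Exact isothermal compressibility of the 1D hard-rod fluid
#'
#' From the Tonks equation of state `beta p = rho / (1 - rho sigma)`:
#' `kappa_T = beta (1 - rho sigma)^2 / rho`, hence
#' `nu_inf = (1 - rho sigma)^2`.  Strictly size-independent.
#'
#' @param spec a 1D [fluid_spec()].
#' @return A `compressibility_result`.
#' @examples
#' tonks_kappa(fluid_spec(1, 0.8, dim = 1))$nu_inf  # 0.04
#' @export
tonks_kappa <- function(spec) {
  check_tonks(spec)
  nu <- (1 - spec$rho * spec$sigma)^2
  compressibility_result(spec$beta * nu / spec$rho, nu, "tonks")
}

#' Isobaric (NpT) length moments of the 1D hard-rod fluid
#'
#' In the isobaric ensemble the length of an N-rod system is
#' `N sigma` plus a gamma variate with shape `N` and rate `beta p`:
#' `<L> = N sigma + N/(beta p)`, `Var(L) = N/(beta p)^2`.  The
#' compressibility from these moments, `beta Var(L)/<L>`, equals the
#' exact [tonks_kappa()] at the implied density `rho = N/<L>` for every
#' `N` --- the fluctuation route is size-independent.
#'
#' @param N particle count, >= 1.
#' @param betap reduced pressure `beta p`, > 0.
#' @param sigma rod length.
#' @return List with `mean_L`, `var_L`, and `kappa_T` (the
#'   fluctuation-route compressibility `beta Var/<L>` with `beta = 1`).
#' @examples
#' tonks_npt_moments(1, betap = 5, sigma = 0.8)  # mean 1, variance 0.04
#' @export
tonks_npt_moments <- function(N, betap, sigma) {
  stopifnot(N >= 1, N == round(N), betap > 0, sigma > 0)
  mean_L <- N * sigma + N / betap
  var_L <- N / betap^2
  list(mean_L = mean_L, var_L = var_L, kappa_T = var_L / mean_L)
}

#' Carnahan-Starling compressibility of the 3D hard-sphere fluid
#'
#' `beta p = rho Z(eta)` with
#' `Z = (1 + eta + eta^2 - eta^3)/(1 - eta)^3`; the density derivative
#' is taken analytically,
#' `d(beta p)/d rho = Z + eta Z'` with
#' `Z' = (4 + 4 eta - 2 eta^2)/(1 - eta)^4`, and
#' `nu_inf = 1 / (Z + eta Z')`.
#'
#' @param spec a 3D [fluid_spec()] with packing fraction below 0.64.
#' @return A `compressibility_result`.
#' @examples
#' carnahan_starling_nu(fluid_spec(0.2, 1))$nu_inf  # 0.4406
#' @export
carnahan_starling_nu <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim != 3L) stop("carnahan_starling_nu requires dim = 3")
  eta <- packing_fraction(spec)
  if (eta >= 0.64)
    stop("invalid state: Carnahan-Starling is used below eta = 0.64")
  Z <- (1 + eta + eta^2 - eta^3) / (1 - eta)^3
  Zp <- (4 + 4 * eta - 2 * eta^2) / (1 - eta)^4   # dZ/deta
  nu <- 1 / (Z + eta * Zp)
  compressibility_result(spec$beta * nu / spec$rho, nu, "carnahan_starling")
}

#' Percus-Yevick compressibility-route fluctuation limit
#'
#' The closed form `nu_inf = (1 - eta)^4 / (1 + 2 eta)^2`, i.e. the
#' zero-wavevector structure factor of the PY solution.  Serves as the
#' independent oracle for the large-L intercepts of PY fluctuation
#' curves.
#'
#' @param spec a 3D [fluid_spec()].
#' @return A `compressibility_result`.
#' @export
py_compressibility_nu <- function(spec) {
  eta <- check_py(spec)
  nu <- (1 - eta)^4 / (1 + 2 * eta)^2
  compressibility_result(spec$beta * nu / spec$rho, nu, "py_compressibility")
}
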