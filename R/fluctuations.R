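# Finite-volume Kirkwood-Buff machinery.
#
# The relative particle-number fluctuation of an open subvolume of
# linear size L (segment length in 1D, sphere diameter in 3D) is
#
#   nu(L)  = 1 + rho * int_0^L w(r) (g(r)  - 1) dr     (point particles)
#   nu~(L) =     rho * int_0^L w(r) (g~(r) - 1) dr     (modified RDF)
#
# where w(r) is the geometric pair-distance weight of the subvolume.
# The +1 compensates the diagonal terms omitted from g; with the
# modified RDF the diagonal is inside g~ and the constant is absent.
# The "running KBI" replaces w(r) by 2 (1D) or 4*pi*r^2 (3D), i.e.
# truncates the infinite-volume integral at L; it is kept as a
# diagnostic of what goes wrong without the finite-volume weights.

#' Geometric weight function of a finite subvolume
#'
#' Pair-distance distribution weight of an open subvolume: for a 1D
#' segment of length `L`, `w = 2 (1 - r/L)`; for a 3D sphere of
#' diameter `L`, `w = 4 pi r^2 (1 - 3x/2 + x^3/2)` with `x = r/L`.
#' `w(L) = 0`, and the integral of `w` from 0 to `L` equals the
#' subvolume hypervolume (`L`, or `pi L^3/6`).
#'
#' @param r distances, `0 <= r <= L`.
#' @param L subvolume linear size (segment length / sphere diameter).
#' @param dim 1 or 3.
#' @return Weight values.
#' @export
weight_function <- function(r, L, dim) {
  if (any(r < 0) || any(r > L + 1e-12 * L))
    stop("weight_function requires 0 <= r <= L")
  if (dim == 1) 2 * (1 - r / L)
  else if (dim == 3) { x <- r / L; 4 * pi * r^2 * (1 - 1.5 * x + 0.5 * x^3) }
  else stop("dim must be 1 or 3")
}

# hypervolume of the subvolume of linear size L
subvolume_measure <- function(L, dim) if (dim == 1) L else pi * L^3 / 6

# closed form of int_0^s w(r) dr for s <= L (the analytic hard-core part)
weight_core_integral <- function(s, L, dim) {
  if (dim == 1) 2 * s - s^2 / L
  else 4 * pi * (s^3 / 3 - 3 * s^4 / (8 * L) + s^6 / (12 * L^3))
}

default_L_grid <- function(rdf) {
  sp <- rdf$spec
  r_max <- max(rdf$r)
  lo <- if (rdf$includes_diagonal) max(rdf$profile_diameter, 2e-2 * sp$sigma)
        else sp$sigma
  seq(lo, 0.8 * r_max, by = 0.1 * sp$sigma)
}

make_fluct_curve <- function(L, nu, method, rdf) {
  structure(list(L = L, nu = nu, method = method,
                 modified = isTRUE(rdf$includes_diagonal),
                 spec = rdf$spec,
                 a = rdf$profile_diameter),
            class = "fluctuation_curve")
}

#' @export
print.fluctuation_curve <- function(x, ...) {
  cat(sprintf("<fluctuation_curve> %s%s, %d sizes L in [%g, %g], nu in [%.4g, %.4g]\n",
              x$method, if (x$modified) " (modified RDF)" else "",
              length(x$L), min(x$L), max(x$L), min(x$nu), max(x$nu)))
  invisible(x)
}

nu_integral <- function(rdf, L, weighting = c("finite_volume", "running")) {
  weighting <- match.arg(weighting)
  sp <- rdf$spec
  r <- rdf$r; g <- rdf$g
  if (L > max(r) + 1e-9)
    stop(sprintf("L = %g exceeds the RDF coverage r_max = %g (shortfall %g)",
                 L, max(r), L - max(r)))
  wfun <- function(ri)
    if (weighting == "finite_volume") weight_function(ri, L, sp$dim)
    else if (sp$dim == 1) rep(2, length(ri)) else 4 * pi * ri^2
  if (rdf$hard_core && !rdf$includes_diagonal) {
    # analytic core contribution: g = 0 on [0, sigma)
    s <- min(sp$sigma, L)
    core <- if (weighting == "finite_volume") weight_core_integral(s, L, sp$dim)
            else if (sp$dim == 1) 2 * s else 4 * pi * s^3 / 3
    i <- r >= sp$sigma - 1e-12 & r <= L + 1e-12
    sp$rho * (-core + trapz(r[i], wfun(r[i]) * (g[i] - 1)))
  } else {
    i <- r <= L + 1e-12
    sp$rho * trapz(r[i], wfun(r[i]) * (g[i] - 1))
  }
}

#' Finite-volume number-fluctuation curve nu(L)
#'
#' Computes the relative particle-number fluctuation
#' `<dN^2>/<N>` of an open subvolume as a function of its linear size
#' `L`, from a tabulated (plain or modified) RDF, by trapezoidal
#' quadrature with the geometric weight [weight_function()].  For an
#' unmodified RDF the curve is `1 + rho int w (g-1)`; for a modified
#' RDF the constant 1 is absent because the diagonal term is inside
#' `g~`.  Hard-core regions are integrated analytically.
#'
#' For a `shell_rdf` (perfect crystal) the integral over the delta comb
#' is evaluated exactly as a weighted sum over shells.
#'
#' @param rdf a [tabulated_rdf()], modified RDF, or [fcc_shells()]
#'   object.
#' @param L_grid subvolume sizes; default: `sigma` (or the profile
#'   diameter `a` for modified RDFs) up to `0.8 * r_max` in steps of
#'   `0.1 * sigma`.
#' @return A `fluctuation_curve` object with fields `L`, `nu`,
#'   `method`, `modified`, `spec`, `a`.
#' @examples
#' sp <- fluid_spec(1, 0.8, dim = 1)
#' nu <- nu_curve(tonks_rdf(sp, r_max = 12))
#' range(nu$nu)
#' @export
nu_curve <- function(rdf, L_grid = NULL) UseMethod("nu_curve")

#' @export
nu_curve.tabulated_rdf <- function(rdf, L_grid = NULL) {
  L_grid <- L_grid %||% default_L_grid(rdf)
  base <- if (rdf$includes_diagonal) 0 else 1
  nu <- vapply(L_grid, function(L) base + nu_integral(rdf, L), 0)
  make_fluct_curve(L_grid, nu, "finite_volume", rdf)
}

#' @export
nu_curve.shell_rdf <- function(rdf, L_grid = NULL) {
  L_grid <- L_grid %||% seq(2 * rdf$sigma, 0.8 * max(rdf$shell_distances),
                            by = 0.1 * rdf$sigma)
  rho <- rdf$density
  nu <- vapply(L_grid, function(L) {
    sel <- rdf$shell_distances <= L
    # rho*int w g dr over the comb: each shell contributes n_k * wbar(d_k)
    d <- rdf$shell_distances[sel]
    wg <- sum(rdf$shell_counts[sel] *
                weight_function(d, L, 3) / (4 * pi * d^2))
    1 + wg - rho * subvolume_measure(L, 3)
  }, 0)
  fake <- list(includes_diagonal = FALSE, profile_diameter = NULL,
               spec = structure(list(rho = rho, sigma = rdf$sigma, dim = 3L,
                                     beta = 1), class = "fluid_spec"))
  make_fluct_curve(L_grid, nu, "finite_volume", fake)
}

#' Running Kirkwood-Buff integral curve (diagnostic)
#'
#' Same integrals as [nu_curve()] but with the geometric weight
#' replaced by `2` (1D) or `4 pi r^2` (3D), i.e. the infinite-volume
#' compressibility integral truncated at `L`.  The result oscillates,
#' can turn negative (unphysical for a fluctuation), and diverges for
#' crystals --- which is why the finite-volume weights are needed.
#'
#' @inheritParams nu_curve
#' @return A `fluctuation_curve` with `method = "running_kbi"`.
#' @export
running_kbi_curve <- function(rdf, L_grid = NULL) UseMethod("running_kbi_curve")

#' @export
running_kbi_curve.tabulated_rdf <- function(rdf, L_grid = NULL) {
  L_grid <- L_grid %||% default_L_grid(rdf)
  base <- if (rdf$includes_diagonal) 0 else 1
  nu <- vapply(L_grid, function(L) base + nu_integral(rdf, L, "running"), 0)
  make_fluct_curve(L_grid, nu, "running_kbi", rdf)
}

#' @export
running_kbi_curve.shell_rdf <- function(rdf, L_grid = NULL) {
  L_grid <- L_grid %||% seq(2 * rdf$sigma, 0.8 * max(rdf$shell_distances),
                            by = 0.1 * rdf$sigma)
  rho <- rdf$density
  nu <- vapply(L_grid, function(L) {
    1 + shell_cumulative_count(rdf, L) - rho * 4 * pi * L^3 / 3
  }, 0)
  fake <- list(includes_diagonal = FALSE, profile_diameter = NULL,
               spec = structure(list(rho = rho, sigma = rdf$sigma, dim = 3L,
                                     beta = 1), class = "fluid_spec"))
  make_fluct_curve(L_grid, nu, "running_kbi", fake)
}

#' Large-L asymptote of a fluctuation curve
#'
#' Ordinary least-squares fit of `nu(L) = nu(inf) + C/L` over a stated
#' fit range, with a stability report: the fit is repeated on a 20%
#' shrunken range and the intercept shift is recorded.
#'
#' @param curve a `fluctuation_curve`.
#' @param fit_range numeric `c(L_lo, L_hi)`; default
#'   `[10 * sigma, max(L)]`.
#' @return An `asymptote_fit` object: `nu_inf`, `slope`, `fit_range`,
#'   `residual_norm`, `stability` (absolute intercept shift under the
#'   perturbed range) and `n_points`.
#' @examples
#' cv <- structure(list(L = 10:40, nu = 0.3 + 0.5 / (10:40),
#'                      method = "finite_volume", modified = FALSE,
#'                      spec = fluid_spec(0.3), a = NULL),
#'                 class = "fluctuation_curve")
#' fit_asymptote(cv)$nu_inf  # 0.3
#' @export
fit_asymptote <- function(curve, fit_range = NULL) {
  stopifnot(inherits(curve, "fluctuation_curve"))
  fit_range <- fit_range %||% c(10 * curve$spec$sigma, max(curve$L))
  sel <- curve$L >= fit_range[1L] - 1e-9 & curve$L <= fit_range[2L] + 1e-9
  if (sum(sel) < 10L)
    stop("fit_asymptote needs at least 10 points inside the fit range; got ",
         sum(sel))
  fit1 <- lm(nu ~ I(1 / L), data = list(nu = curve$nu[sel], L = curve$L[sel]))
  # perturbed-range refit: shrink the window by 20% on both ends
  span <- diff(fit_range)
  pr <- c(fit_range[1L] + 0.1 * span, fit_range[2L] - 0.1 * span)
  sel2 <- curve$L >= pr[1L] - 1e-9 & curve$L <= pr[2L] + 1e-9
  stab <- if (sum(sel2) >= 10L) {
    fit2 <- lm(nu ~ I(1 / L), data = list(nu = curve$nu[sel2], L = curve$L[sel2]))
    abs(coef(fit2)[[1L]] - coef(fit1)[[1L]])
  } else NA_real_
  structure(list(nu_inf = coef(fit1)[[1L]], slope = coef(fit1)[[2L]],
                 fit_range = fit_range,
                 residual_norm = sqrt(sum(resid(fit1)^2)),
                 stability = stab, n_points = sum(sel)),
            class = "asymptote_fit")
}

#' @export
print.asymptote_fit <- function(x, ...) {
  cat(sprintf("<asymptote_fit> nu(inf) = %.6g, C = %.6g  (fit on [%g, %g], %d pts, |resid| = %.2g, stability %.2g)\n",
              x$nu_inf, x$slope, x$fit_range[1L], x$fit_range[2L],
              x$n_points, x$residual_norm, x$stability))
  invisible(x)
}

#' Export a fluctuation curve as a delimited text table
#'
#' Two columns `L nu` with a `#` metadata header recording the method,
#' state and profile diameter.
#'
#' @param curve a `fluctuation_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fluctuation_curve"))
  hdr <- c(sprintf("# method: %s", curve$method),
           sprintf("# modified: %s", curve$modified),
           sprintf("# rho: %.17g", curve$spec$rho),
           sprintf("# sigma: %.17g", curve$spec$sigma),
           sprintf("# dim: %d", curve$spec$dim),
           if (!is.null(curve$a)) sprintf("# a: %.17g", curve$a),
           "# columns: L nu")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(cbind(curve$L, curve$nu), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
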