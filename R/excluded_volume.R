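# Excluded-volume machinery: particle profile kernels, the modified RDF
# g~(r) obtained by convolving the full two-particle density (pair part
# rho^2 g plus the diagonal delta) with the profile overlap kernel, and
# the empirical effective-diameter corrections.
#
# The particle is given a uniform internal density on a hypersphere of
# diameter a (hypervolume V0 = a in 1D, pi*a^3/6 in 3D).  The kernel
# chi(r) is the self-convolution of that profile: the overlap of two
# profiles at centre distance r, normalised to unit integral over all
# space.  The diagonal (i = j) term of the two-particle density enters
# g~ analytically as chi(r)/rho; only the pair part is convolved
# numerically.

#' Excluded-volume overlap kernel of a uniform particle profile
#'
#' Self-convolution of a uniform density profile of diameter `a`:
#' in 1D the triangle `(a - |r|)/a^2`; in 3D the sphere-overlap kernel
#' `(6/(pi a^3)) (1 - 3y/2 + y^3/2)` with `y = r/a`.  The support is
#' \eqn{r < a}; the integral over all space (line or 3D volume) is 1.
#'
#' @param r centre-to-centre distances (vectorised), >= 0.
#' @param a particle profile diameter, > 0.
#' @param dim 1 or 3.
#' @return Kernel values (per unit hypervolume).
#' @examples
#' kernel_chi(0, a = 0.8, dim = 1)   # peak 1/a = 1.25
#' kernel_chi(0.8, a = 0.8, dim = 1) # support boundary: 0
#' @export
kernel_chi <- function(r, a, dim) {
  stopifnot(a > 0, all(r >= 0))
  if (!dim %in% c(1, 3)) stop("dim must be 1 or 3")
  y <- r / a
  if (dim == 1) {
    ifelse(y < 1, (1 - y) / a, 0)
  } else {
    ifelse(y < 1, 6 / (pi * a^3) * (1 - 1.5 * y + 0.5 * y^3), 0)
  }
}

# k1(u) = 2*pi*int_{|u|}^{a} t chi(t) dt : the reduced 1D kernel of the
# radially symmetric 3D convolution (applied to u(r) = r f(r)).
kernel_k1 <- function(u, a) {
  z <- pmin(abs(u) / a, 1)
  (12 / a) * (1 / 10 - (z^2 / 2 - z^3 / 2 + z^5 / 10))
}

# g extended beyond its grid by its asymptotic value 1 (fluids); the
# hard core (r < sigma) is already part of the stored table.
extend_g <- function(rdf, n_pad) {
  c(rdf$g, rep(1, n_pad))
}

#' Modified RDF with excluded volume
#'
#' Convolves the full two-particle density of a fluid --- pair part
#' `rho^2 g(r)` plus the diagonal delta `rho delta(r)` --- with the
#' uniform-profile kernel [kernel_chi()] of diameter `a`, and returns
#' `g~ = (convolution)/rho^2`.  The diagonal term is added analytically
#' as `chi(r)/rho` and also stored separately.  In 3D the radially
#' symmetric convolution reduces to a one-dimensional convolution of
#' the odd extension of \eqn{r g(r)} with the reduced kernel
#' \eqn{k1(u) = 2\pi \int_{|u|}^{a} t \chi(t) dt}.
#'
#' The grid is extended internally by the asymptotic value `g = 1`
#' beyond `r_max`, and at the hard-core contact node the value is
#' averaged with the inside limit 0 so that the sampled convolution
#' remains second-order accurate across the jump.
#'
#' @param rdf an unmodified [tabulated_rdf()] on a uniform grid starting
#'   at 0.
#' @param a particle profile diameter, `0 < a <= sigma`.
#' @return A modified [tabulated_rdf()] (class `modified_rdf`) on the
#'   same grid, with the diagonal component stored separately.
#' @examples
#' sp <- fluid_spec(1, 0.8, dim = 1)
#' gt <- modify_rdf(tonks_rdf(sp, r_max = 10), a = 0.8)
#' max(abs(gt$g[gt$r >= 0.8] - 1))  # ~0.057: oscillations suppressed
#' @export
modify_rdf <- function(rdf, a) {
  stopifnot(inherits(rdf, "tabulated_rdf"))
  if (inherits(rdf, "modified_rdf") || rdf$includes_diagonal)
    stop("RDF is already modified; refusing to convolve twice")
  sp <- rdf$spec
  if (a <= 0 || a > sp$sigma + 1e-12)
    stop("profile diameter a must satisfy 0 < a <= sigma")
  r <- rdf$r
  dr <- r[2L] - r[1L]
  if (abs(r[1L]) > 1e-12 || max(abs(diff(r) - dr)) > 1e-9 * dr)
    stop("modify_rdf requires a uniform grid starting at r = 0")
  g <- rdf$g
  if (rdf$hard_core) {              # midpoint value at the contact jump
    j <- grid_node(r, sp$sigma, "sigma")
    g[j] <- g[j] / 2
  }
  n_pad <- ceiling(a / dr) + 2L
  gx <- c(g, rep(1, n_pad))         # extend with the asymptotic limit
  nu <- length(gx)
  ker_u <- (-n_pad:n_pad) * dr      # symmetric odd-length kernel grid
  if (sp$dim == 1L) {
    # even extension of g(|s|) about 0, triangle kernel
    sig <- c(rev(gx[-1L]), gx)
    ker <- kernel_chi(abs(ker_u), a, 1L)
    pair_full <- conv_uniform(sig, ker, dr)
    pair <- pair_full[nu:(2L * nu - 1L)][seq_along(r)]
  } else {
    # odd extension of s*g(s), reduced kernel k1
    ug <- (seq_len(nu) - 1L) * dr * gx
    sig <- c(-rev(ug[-1L]), ug)
    ker <- kernel_k1(ker_u, a)
    pair_full <- conv_uniform(sig, ker, dr)
    pair <- pair_full[nu:(2L * nu - 1L)][seq_along(r)] / r
    # r = 0: direct quadrature of F(0) = int chi(s) g(s) 4 pi s^2 ds
    s_in <- r <= a
    pair[1L] <- trapz(r[s_in], kernel_chi(r[s_in], a, 3L) * g[s_in] *
                        4 * pi * r[s_in]^2)
  }
  diag_part <- kernel_chi(r, a, sp$dim) / sp$rho
  tabulated_rdf(r, pair + diag_part, sp,
                includes_diagonal = TRUE, profile_diameter = a,
                diagonal = diag_part, hard_core = FALSE)
}

#' Modified RDF of a delta-comb (crystal) RDF
#'
#' For an immobile crystal the pair part of the two-particle density is
#' a weighted comb of delta shells, so the convolution with the profile
#' kernel is evaluated analytically as a sum of shifted kernels: in 3D
#' `g~_pair(r) = sum_k n_k [k1(r - d_k) - k1(r + d_k)] / (4 pi rho d_k r)`,
#' plus the diagonal term `chi(r)/rho`.  No histogram binning is
#' involved.
#'
#' @param shells a [fcc_shells()] object.
#' @param a particle profile diameter (> 0).
#' @param r_max largest grid distance (default `10 * sigma`); the shell
#'   table must extend to `r_max + a`.
#' @param dr grid spacing (default `1e-3 * sigma`).
#' @return A modified [tabulated_rdf()] with `spec` at the crystal
#'   density.
#' @export
modify_shell_rdf <- function(shells, a, r_max = 10 * shells$sigma,
                             dr = 1e-3 * shells$sigma) {
  stopifnot(inherits(shells, "shell_rdf"), a > 0)
  if (max(shells$shell_distances) < r_max + a)
    stop("shell table reaches r = ", max(shells$shell_distances),
         " but the requested grid needs shells up to r_max + a = ",
         r_max + a, "; enlarge the shell enumeration")
  rho <- shells$density
  r <- seq(0, r_max, by = dr)
  dk <- shells$shell_distances
  nk <- shells$shell_counts
  use <- dk <= r_max + a
  dk <- dk[use]; nk <- nk[use]
  pair <- numeric(length(r))
  rp <- r[-1L]
  acc <- numeric(length(rp))
  for (ii in seq_along(dk)) {
    acc <- acc + nk[ii] * (kernel_k1(rp - dk[ii], a) -
                             kernel_k1(rp + dk[ii], a)) / dk[ii]
  }
  pair[-1L] <- acc / (4 * pi * rho * rp)
  pair[1L] <- sum(nk * kernel_chi(dk, a, 3L)) / rho
  diag_part <- kernel_chi(r, a, 3L) / rho
  # close packing sits exactly on the fluid_spec bound: build directly
  spec <- structure(list(rho = rho, sigma = shells$sigma, dim = 3L, beta = 1),
                    class = "fluid_spec")
  tabulated_rdf(r, pair + diag_part, spec,
                includes_diagonal = TRUE, profile_diameter = a,
                diagonal = diag_part, hard_core = FALSE)
}

#' Effective profile diameters for size-independent fluctuations
#'
#' Reduced particle diameters that make the modified fluctuation curve
#' `nu~(L)` size-independent at a given density: in 1D
#' `a1 = sigma * (1 - (1 - rho*sigma)^3)`, in 3D
#' `a3 = sigma * (1 - exp(-5.6 * rho * sigma^3))`.  Both tend to 0 in
#' the ideal-gas limit (the modified RDF then reduces to the point-like
#' definition) and approach `sigma` at high filling.
#'
#' @param spec a [fluid_spec()] of matching dimension.
#' @return The effective diameter (same units as `sigma`).
#' @examples
#' effective_diameter_1d(fluid_spec(1, 0.8, dim = 1)) / 0.8  # 0.992
#' effective_diameter_3d(fluid_spec(0.5, 1, dim = 3))        # 0.939
#' @export
effective_diameter_1d <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim != 1L) stop("effective_diameter_1d requires dim = 1")
  if (spec$rho * spec$sigma >= 1) stop("invalid state: rho*sigma must be < 1")
  spec$sigma * (1 - (1 - spec$rho * spec$sigma)^3)
}

#' @rdname effective_diameter_1d
#' @export
effective_diameter_3d <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim != 3L) stop("effective_diameter_3d requires dim = 3")
  check_py(spec)
  spec$sigma * (1 - exp(-5.6 * spec$rho * spec$sigma^3))
}
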