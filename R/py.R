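# Percus-Yevick hard-sphere structure in 3D.
#
# Two routes to the same analytic solution:
#
#  * "oz": Fourier inversion of the Ornstein-Zernike relation using the
#    closed-form PY direct correlation function c(r).  The transform is
#    applied to gamma = h - c (continuous everywhere), so the hard-core
#    discontinuity of g never passes through the FFT; accuracy is
#    uniform in r and the route is stable at every density.  Default.
#
#  * "shells": Wertheim's piecewise-analytic shell expansion of the
#    Laplace-space solution.  The inverse transform of shell n is an
#    order-n residue sum over the three roots of the cubic S(t); in
#    double precision the residue cancellation grows like exp(t0*r)
#    (t0 the real root), so this route is only offered within its
#    reliable range and serves as an independent cross-check.

py_lambdas <- function(eta) {
  list(l1 = (1 + 2 * eta)^2 / (1 - eta)^4,
       l2 = -(1 + eta / 2)^2 / (1 - eta)^4)
}

# PY direct correlation function, r in units of sigma (r < 1; 0 outside)
py_c_direct <- function(r, eta) {
  lam <- py_lambdas(eta)
  ifelse(r < 1, -lam$l1 - 6 * eta * lam$l2 * r - eta / 2 * lam$l1 * r^3, 0)
}

# 3D Fourier transform of c(r): chat(k), k in units of 1/sigma
py_c_hat <- function(k, eta) {
  lam <- py_lambdas(eta)
  s <- sin(k); cc <- cos(k)
  I1 <- (s - k * cc) / k^2
  I2 <- (2 * k * s - (k^2 - 2) * cc - 2) / k^3
  I4 <- ((4 * k^3 - 24 * k) * s - (k^4 - 12 * k^2 + 24) * cc + 24) / k^5
  -4 * pi / k * (lam$l1 * I1 + 6 * eta * lam$l2 * I2 + eta / 2 * lam$l1 * I4)
}

# discrete sine transform S_k = sum_{j=1}^{M-1} b_j sin(pi j k / M)
dst_1 <- function(b) {
  M <- length(b) + 1L
  -Im(fft(c(0, b, 0, -rev(b))))[2:M] / 2
}

check_py <- function(spec) {
  stopifnot(inherits(spec, "fluid_spec"))
  if (spec$dim != 3L)
    stop("unsupported model: the Percus-Yevick solution used here is 3D (dim = 3)")
  eta <- packing_fraction(spec)
  if (eta >= 0.74)
    stop("invalid state: packing fraction eta = ", format(eta), " must be < 0.74")
  invisible(eta)
}

#' Percus-Yevick radial distribution function of the 3D hard-sphere fluid
#'
#' Evaluates the Wertheim analytic PY solution for hard spheres on a
#' uniform grid.  The default route inverts the Ornstein-Zernike
#' relation with the closed-form PY direct correlation function by a
#' fast sine transform of `gamma = h - c` (which is continuous, so the
#' contact discontinuity is handled exactly); `method = "shells"`
#' evaluates the piecewise-analytic shell expansion of the Laplace-space
#' solution by order-n residue sums instead.
#'
#' The grid node at \eqn{r = \sigma} stores the contact limit `g(sigma+)`;
#' nodes strictly inside the core store 0.
#'
#' @param spec a 3D [fluid_spec()].
#' @param r_max largest tabulated distance (default `30 * sigma`).
#' @param dr grid spacing (default `1e-3 * sigma`).
#' @param method `"oz"` (default) or `"shells"`.
#' @param n_shells number of shells for `method = "shells"` (default 30;
#'   `r_max` must not exceed `n_shells * sigma`).
#' @return A [tabulated_rdf()].
#' @examples
#' sp <- fluid_spec(0.4, 1, dim = 3)
#' rdf <- py_rdf(sp, r_max = 6)
#' rdf$g[rdf$r == 1]  # contact value (1 + eta/2)/(1 - eta)^2
#' @export
py_rdf <- function(spec, r_max = 30 * spec$sigma, dr = 1e-3 * spec$sigma,
                   method = c("oz", "shells"), n_shells = 30L) {
  eta <- check_py(spec)
  method <- match.arg(method)
  s_max <- r_max / spec$sigma       # reduced units
  ds <- dr / spec$sigma
  if (method == "oz") {
    g <- py_g_oz(eta, s_max, ds)
  } else {
    if (s_max > n_shells)
      stop("r_max = ", r_max, " exceeds the implemented shell count (",
           n_shells, " shells); raise n_shells or reduce r_max")
    g <- py_g_shells(eta, s_max, ds, n_shells)
  }
  tabulated_rdf(g$r * spec$sigma, g$g, spec, hard_core = TRUE)
}

# OZ/FFT route, sigma = 1 units
py_g_oz <- function(eta, s_max, ds) {
  rho <- 6 * eta / pi
  # transform box must comfortably contain the decay of gamma(r)
  M <- 2^ceiling(log2(max(2.1 * s_max, 60) / ds))
  r <- (1:(M - 1)) * ds
  dk <- pi / (M * ds)
  k <- (1:(M - 1)) * dk
  chat <- py_c_hat(k, eta)
  gamma_hat <- rho * chat^2 / (1 - rho * chat)
  gam <- dst_1(k * gamma_hat) * dk / (2 * pi^2 * r)
  g <- 1 + gam + py_c_direct(r, eta)
  g[r < 1] <- 0
  j <- which.min(abs(r - 1))
  g[j] <- 1 + gam[j]                 # one-sided contact limit (c(1+) = 0)
  keep <- r <= s_max + ds / 2
  list(r = c(0, r[keep]), g = c(0, g[keep]))
}

# --- Wertheim shell expansion ------------------------------------------

# S(t) and L(t) polynomials (ascending coefficients), sigma = 1
py_S_coef <- function(eta)
  c(-12 * eta * (1 + 2 * eta), 18 * eta^2, 6 * eta * (1 - eta), (1 - eta)^2)
py_L_coef <- function(eta) 12 * eta * c(1 + 2 * eta, 1 + eta / 2)

poly_mul <- function(a, b) {
  out <- complex(length.out = length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

poly_eval <- function(p, x) {
  v <- 0i
  for (cf in rev(p)) v <- v * x + cf
  v
}

# Taylor coefficients of polynomial p about t0, up to order m-1
poly_taylor <- function(p, t0, m) {
  out <- complex(length.out = m)
  cur <- p
  for (k in 0:(m - 1L)) {
    out[k + 1L] <- poly_eval(cur, t0)   # k-th derivative value
    cur <- if (length(cur) > 1L)
      cur[-1L] * complex(real = seq_len(length(cur) - 1L)) else 0i
  }
  out / factorial(0:(m - 1L))
}

series_mul_trunc <- function(a, b, m) {
  out <- complex(length.out = m)
  for (i in seq_len(min(length(a), m))) {
    jmax <- min(length(b), m - i + 1L)
    out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

series_div_trunc <- function(a, b, m) {
  a <- c(a, complex(length.out = max(0L, m - length(a))))[seq_len(m)]
  b <- c(b, complex(length.out = max(0L, m - length(b))))[seq_len(m)]
  q <- complex(length.out = m)
  for (k in seq_len(m)) {
    s <- a[k]
    if (k > 1L) s <- s - sum(q[seq_len(k - 1L)] * b[k:2])
    q[k] <- s / b[1L]
  }
  q
}

py_g_shells <- function(eta, s_max, ds, n_shells) {
  roots <- polyroot(py_S_coef(eta))
  Lc <- complex(real = py_L_coef(eta))
  r <- seq(ds, s_max, by = ds)
  rg <- numeric(length(r))
  Ln <- c(1 + 0i)
  for (n in seq_len(n_shells)) {
    x <- r - n
    sel <- x >= 0
    if (!any(sel)) break
    xs <- x[sel]
    Ln <- poly_mul(Ln, Lc)            # L(t)^n
    Np <- c(0i, Ln)                   # t * L(t)^n
    pref <- (-1)^(n - 1) / (12 * eta) / (1 - eta)^(2 * n)
    Hn <- numeric(length(xs))
    for (i in 1:3) {
      ti <- roots[i]
      a_num <- poly_taylor(Np, ti, n)
      den <- c(1 + 0i)
      for (j in (1:3)[-i]) {
        d <- ti - roots[j]
        fac <- complex(real = choose(n, 0:(n - 1L))) * d^(n - (0:(n - 1L)))
        den <- series_mul_trunc(den, fac, n)
      }
      a <- series_div_trunc(a_num, den, n)
      pw <- outer(xs, (n - 1L):0, "^") /
        matrix(rep(factorial((n - 1L):0), each = length(xs)), ncol = n)
      Hn <- Hn + Re(exp(ti * xs) * as.vector(pw %*% a))
    }
    rg[sel] <- rg[sel] + pref * Hn
  }
  g <- rg / r
  g[r < 1] <- 0
  list(r = c(0, r), g = c(0, g))
}

#' Reliable range of the shell-expansion route
#'
#' The order-n residue sums of the shell expansion cancel to a result of
#' order 1 while individual terms grow like `exp(t0*(r - 1))`, `t0` the
#' real root of the Wertheim cubic; beyond the distance where that
#' amplification reaches `1/tol` machine cancellation dominates.
#'
#' @param spec a 3D [fluid_spec()].
#' @param tol acceptable absolute error in g (default `1e-6`).
#' @return Largest reliable `r` (same units as `sigma`).
#' @export
py_shell_rmax <- function(spec, tol = 1e-6) {
  eta <- check_py(spec)
  roots <- polyroot(py_S_coef(eta))
  t0 <- max(Re(roots[abs(Im(roots)) < 1e-9 * max(abs(roots))]))
  spec$sigma * (1 + log(tol / .Machine$double.eps) / t0)
}
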