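# Monte Carlo oracle: canonical hard-rod configurations on a ring,
# RDF histograms, and direct window-counting fluctuation measurements
# with discrete (centre counting) or fractional (excluded-volume-aware)
# particle counts.
#
# The windows are much smaller than the box, so the canonical sampler
# emulates an open (grand-canonical) subvolume; the residual
# fixed-N correction is of order L_w / L_box and the default box keeps
# it well below the statistical resolution.

#' Sample 1D hard-rod configurations (canonical Metropolis)
#'
#' Metropolis single-particle displacement sampling of `N =
#' round(rho * L_box)` hard rods on a periodic ring.  Runs are
#' reproducible: the sampler draws from R's RNG stream, so call
#' `set.seed()` or pass `seed`.
#'
#' @param spec a 1D [fluid_spec()].
#' @param L_box box length, at least `20 * sigma`.
#' @param n_sweeps number of MC sweeps (one attempted move per particle
#'   each).
#' @param seed optional integer seed (`set.seed` is called if given).
#' @param burn_in equilibration sweeps to discard (default
#'   `n_sweeps %/% 5`).
#' @param thin store every `thin`-th sweep after burn-in (default 10).
#' @param delta maximum displacement (default: the mean free gap).
#' @return Object of class `tonks_configs`: a matrix with one sorted,
#'   wrapped configuration per row, with attributes `sigma`, `L_box`,
#'   `spec`.
#' @examples
#' cfg <- sample_tonks(fluid_spec(0.5, 1, dim = 1), L_box = 40,
#'                     n_sweeps = 200, seed = 1)
#' dim(cfg)
#' @export
sample_tonks <- function(spec, L_box = 200 * spec$sigma, n_sweeps = 1000L,
                         seed = NULL, burn_in = n_sweeps %/% 5L, thin = 10L,
                         delta = NULL) {
  check_tonks(spec)
  if (L_box < 20 * spec$sigma) stop("L_box must be at least 20*sigma")
  N <- round(spec$rho * L_box)
  if (N < 1) stop("box too small: round(rho * L_box) < 1")
  if (N * spec$sigma >= L_box)
    stop("packing error: ", N, " rods of length ", spec$sigma,
         " do not fit in L_box = ", L_box)
  if (!is.null(seed)) set.seed(seed)
  free <- L_box / N - spec$sigma
  delta <- delta %||% free
  start <- (seq_len(N) - 1) * L_box / N      # equally spaced, valid
  m <- tonks_mc_run(start, spec$sigma, L_box, as.integer(n_sweeps),
                    as.integer(burn_in), as.integer(thin), delta)
  structure(m, sigma = spec$sigma, L_box = L_box, spec = spec,
            class = c("tonks_configs", "matrix", "array"))
}

overlap_free <- function(configs) {
  L_box <- attr(configs, "L_box"); sigma <- attr(configs, "sigma")
  gaps <- t(apply(unclass(configs), 1L, function(p)
    diff(c(p, p[1L] + L_box))))
  all(gaps >= sigma - 1e-9)
}

# periodic overlap length of interval [lo, hi] with window [w0, w1]
# (all within a ring of length L_box; interval length < L_box)
interval_overlap <- function(lo, hi, w0, w1, L_box) {
  ov <- 0
  for (shift in c(-L_box, 0, L_box)) {
    ov <- ov + pmax(0, pmin(hi + shift, w1) - pmax(lo + shift, w0))
  }
  ov
}

#' Window-counting fluctuation measurement
#'
#' Places `n_windows` random windows of length `L_w` in every stored
#' configuration and measures the particle content.  In `discrete` mode
#' the content is the number of rod centres inside the window; in
#' `fractional` mode each rod is given a uniform profile of length `a`
#' and contributes the exact fraction of its profile inside the window
#' (interval intersection length / a).  The relative fluctuation
#' estimate is `var(N_w)/mean(N_w)` with a batch-means standard error
#' over 20 batches of configurations.
#'
#' @param configs a `tonks_configs` object.
#' @param L_w window length, at most `L_box / 4`.
#' @param mode `"discrete"` or `"fractional"`.
#' @param a profile length for fractional counting (default `sigma`).
#' @param n_windows random windows per configuration (default 8).
#' @param n_batches batches for the standard error (default 20).
#' @return Object of class `window_stats`: `L_w`, `n_samples`,
#'   `mean_count`, `var_count`, `nu_hat`, `se_nu`, `mode`, `a`.
#' @export
window_fluctuations <- function(configs, L_w, mode = c("discrete", "fractional"),
                                a = NULL, n_windows = 8L, n_batches = 20L) {
  stopifnot(inherits(configs, "tonks_configs"))
  mode <- match.arg(mode)
  L_box <- attr(configs, "L_box"); sigma <- attr(configs, "sigma")
  if (L_w > L_box / 4)
    stop("window L_w = ", L_w, " exceeds L_box/4 = ", L_box / 4,
         " (window decorrelation)")
  a <- a %||% sigma
  m <- unclass(configs)
  n_cfg <- nrow(m)
  counts <- matrix(0, n_cfg, n_windows)
  for (ic in seq_len(n_cfg)) {
    pos <- m[ic, ]
    w0 <- stats::runif(n_windows, 0, L_box)
    for (iw in seq_len(n_windows)) {
      if (mode == "discrete") {
        # centres in [w0, w0 + L_w) on the ring
        d <- (pos - w0[iw]) %% L_box
        counts[ic, iw] <- sum(d < L_w)
      } else {
        counts[ic, iw] <- sum(interval_overlap(pos - a / 2, pos + a / 2,
                                               w0[iw], w0[iw] + L_w, L_box)) / a
      }
    }
  }
  cnt <- as.vector(t(counts))
  nu_hat <- var(cnt) / mean(cnt)
  # batch means over configuration blocks
  bi <- cut(seq_len(n_cfg), breaks = n_batches, labels = FALSE)
  nu_b <- vapply(seq_len(n_batches), function(b) {
    cb <- as.vector(counts[bi == b, , drop = FALSE])
    var(cb) / mean(cb)
  }, 0)
  se <- stats::sd(nu_b) / sqrt(n_batches)
  structure(list(L_w = L_w, n_samples = length(cnt),
                 mean_count = mean(cnt), var_count = var(cnt),
                 nu_hat = nu_hat, se_nu = se, mode = mode,
                 a = if (mode == "fractional") a else NULL),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("<window_stats> %s counting, L_w = %g: nu_hat = %.5f +/- %.5f (%d samples)\n",
              x$mode, x$L_w, x$nu_hat, x$se_nu, x$n_samples))
  invisible(x)
}

#' RDF histogram from sampled configurations
#'
#' Normalised pair-distance histogram with periodic minimum-image
#' distances; bin centres on the standard uniform grid.
#'
#' @param configs a `tonks_configs` object with at least 100 stored
#'   configurations.
#' @param bin_width histogram bin width (default `0.05 * sigma`).
#' @param r_max largest distance (default `L_box / 2`).
#' @return A [tabulated_rdf()] whose grid holds the bin centres, with
#'   attribute `se` (per-bin standard error).
#' @export
rdf_histogram <- function(configs, bin_width = 0.05 * attr(configs, "sigma"),
                          r_max = attr(configs, "L_box") / 2) {
  stopifnot(inherits(configs, "tonks_configs"))
  m <- unclass(configs)
  if (nrow(m) < 100L)
    stop("rdf_histogram needs at least 100 decorrelated configurations")
  L_box <- attr(configs, "L_box")
  spec <- attr(configs, "spec")
  N <- ncol(m)
  r_max <- min(r_max, L_box / 2)
  breaks <- seq(0, r_max, by = bin_width)
  acc <- numeric(length(breaks) - 1L)
  acc2 <- numeric(length(breaks) - 1L)
  for (ic in seq_len(nrow(m))) {
    d <- as.vector(stats::dist(m[ic, ]))
    d <- pmin(d, L_box - d)               # minimum image
    h <- tabulate(findInterval(d[d < r_max], breaks), nbins = length(acc))
    acc <- acc + h
    acc2 <- acc2 + h^2
  }
  # unordered pair density at distance r is N * rho * g(r) dr per config
  norm <- nrow(m) * N * spec$rho * bin_width
  g <- acc / norm
  se <- sqrt(pmax(acc2 / nrow(m) - (acc / nrow(m))^2, 0) / nrow(m)) *
    nrow(m) / norm
  centers <- breaks[-1L] - bin_width / 2
  out <- tabulated_rdf(centers, g, spec, hard_core = FALSE)
  attr(out, "se") <- se
  out
}
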