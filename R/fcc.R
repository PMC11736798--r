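# Face-centred-cubic hard-sphere solid at close packing.
#
# At the maximum filling fraction pi/sqrt(18) the spheres touch: the
# nearest-neighbour distance equals sigma, the conventional cubic cell
# parameter is sigma*sqrt(2) and the density is sqrt(2)/sigma^3.  The
# RDF of the immobile crystal is a weighted comb of delta functions at
# the lattice shell distances.

#' Coordination shells of the FCC hard-sphere crystal
#'
#' Enumerates all pair distances of the close-packed FCC lattice up to
#' `r_max`, with their neighbour counts (shell multiplicities), by
#' direct enumeration of lattice vectors.  The nearest-neighbour
#' distance is scaled to the sphere diameter `sigma`.
#'
#' @param sigma sphere diameter (default 1).
#' @param r_max largest pair distance to enumerate; must be at least
#'   `2 * sigma`.
#' @return An object of class `shell_rdf`: list with `shell_distances`,
#'   `shell_counts`, `density` (`sqrt(2)/sigma^3`) and `sigma`.
#' @examples
#' sh <- fcc_shells(r_max = 3)
#' sh$shell_counts[1:2]  # 12 touching neighbours, then 6
#' @export
fcc_shells <- function(sigma = 1, r_max = 6 * sigma) {
  stopifnot(sigma > 0)
  if (r_max < 2 * sigma) stop("r_max must be at least 2*sigma")
  # FCC as the cubic lattice points with even coordinate sum, in units
  # of half the conventional cell: position = (i,j,k)*sigma/sqrt(2)
  m <- ceiling(r_max * sqrt(2) / sigma) + 1L
  idx <- -m:m
  pts <- expand.grid(i = idx, j = idx, k = idx)
  keep <- (pts$i + pts$j + pts$k) %% 2L == 0L
  pts <- pts[keep, ]
  d2 <- (pts$i^2 + pts$j^2 + pts$k^2)        # integer squared distances (x2)
  d2 <- d2[d2 > 0L]
  d <- sigma * sqrt(d2 / 2)
  tab <- table(round(d2))                     # exact integer classes
  dist <- sigma * sqrt(as.numeric(names(tab)) / 2)
  sel <- dist <= r_max + 1e-9 * sigma
  structure(list(shell_distances = dist[sel],
                 shell_counts = as.integer(tab[sel]),
                 density = sqrt(2) / sigma^3,
                 sigma = sigma),
            class = "shell_rdf")
}

#' @export
print.shell_rdf <- function(x, ...) {
  cat(sprintf("<shell_rdf> FCC crystal, sigma = %g, rho = %.6g, %d shells up to r = %g\n",
              x$sigma, x$density, length(x$shell_distances),
              max(x$shell_distances)))
  invisible(x)
}

#' Cumulative neighbour count of a shell RDF
#'
#' Number of lattice neighbours within distance `r` of a central site.
#'
#' @param shells a [fcc_shells()] object.
#' @param r distance (vectorised).
#' @return Integer counts.
#' @export
shell_cumulative_count <- function(shells, r) {
  stopifnot(inherits(shells, "shell_rdf"))
  vapply(r, function(ri)
    sum(shells$shell_counts[shells$shell_distances <= ri + 1e-9]), 0)
}
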