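#' Tabulated radial distribution function
#'
#' Container for a discretised pair correlation function g(r) on a
#' uniform grid, together with the thermodynamic state it belongs to.
#' Modified (excluded-volume-aware) RDFs additionally carry the particle
#' profile diameter `a` and the diagonal (self) component, and are
#' marked by `includes_diagonal = TRUE`.
#'
#' Convention at the hard-core boundary: for an unmodified hard-core
#' model the grid node at \eqn{r = \sigma} stores the one-sided contact limit
#' `g(sigma+)`; all nodes strictly inside the core store 0.  Quadratures
#' in [nu_curve()] treat the core analytically, so no accuracy is lost
#' at the discontinuity.
#'
#' @param r strictly increasing distance grid (should start at 0 and be
#'   uniformly spaced).
#' @param g pair correlation values on `r`, non-negative.
#' @param spec the [fluid_spec()] of the system.
#' @param includes_diagonal logical; `TRUE` only for modified RDFs that
#'   contain the diagonal (i = j) self term.
#' @param profile_diameter the particle profile diameter `a` used for a
#'   modified RDF, or `NULL`.
#' @param diagonal the diagonal component chi(r)/rho stored separately
#'   for modified RDFs, or `NULL`.
#' @param hard_core logical; if `NULL`, detected from the data
#'   (all `g = 0` strictly inside \eqn{r < \sigma}).
#'
#' @return An object of class `tabulated_rdf` (and `modified_rdf` if
#'   `includes_diagonal` is `TRUE`).
#' @export
tabulated_rdf <- function(r, g, spec, includes_diagonal = FALSE,
                          profile_diameter = NULL, diagonal = NULL,
                          hard_core = NULL) {
  stopifnot(inherits(spec, "fluid_spec"), length(r) == length(g))
  if (any(diff(r) <= 0)) stop("r grid must be strictly increasing")
  if (any(g < -1e-12)) stop("g(r) must be non-negative")
  if (includes_diagonal && is.null(profile_diameter))
    stop("a modified RDF must record its profile diameter")
  if (is.null(hard_core)) {
    inside <- r < spec$sigma - 1e-9
    hard_core <- !includes_diagonal && any(inside) && all(g[inside] == 0)
  }
  structure(
    list(r = as.numeric(r), g = as.numeric(g), spec = spec,
         includes_diagonal = isTRUE(includes_diagonal),
         profile_diameter = profile_diameter,
         diagonal = diagonal, hard_core = isTRUE(hard_core)),
    class = c(if (isTRUE(includes_diagonal)) "modified_rdf", "tabulated_rdf"))
}

#' @export
print.tabulated_rdf <- function(x, ...) {
  cat(sprintf("<%s> %dD, rho = %g, sigma = %g, %d points on [%g, %g]%s\n",
              if (x$includes_diagonal) "modified_rdf" else "tabulated_rdf",
              x$spec$dim, x$spec$rho, x$spec$sigma, length(x$r),
              min(x$r), max(x$r),
              if (x$includes_diagonal)
                sprintf(", profile a = %g", x$profile_diameter) else ""))
  invisible(x)
}

#' Read / write tabulated RDFs as plain text
#'
#' The on-disk format is whitespace-delimited columns "r g" (plus a
#' third column `diagonal` for modified RDFs) preceded by `#`-prefixed
#' metadata lines of the form `# key: value`.  Required keys: `rho`,
#' `sigma`, `dim`.  Optional: `beta`, `modified`, `a`, `hard_core`.
#'
#' @param path file path.
#' @return `read_rdf` returns a [tabulated_rdf()]; `write_rdf` returns
#'   `path` invisibly.
#' @examples
#' rdf <- tonks_rdf(fluid_spec(0.5, 1, dim = 1), r_max = 5)
#' f <- tempfile(fileext = ".dat")
#' write_rdf(rdf, f)
#' rt <- read_rdf(f)
#' all.equal(rt$g, rdf$g)
#' @export
read_rdf <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^\\s*#\\s*([A-Za-z_.]+)\\s*:\\s*(\\S+)", ml))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  required <- c("rho", "sigma", "dim")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("RDF file ", path, " lacks required metadata key(s): ",
         paste(missing, collapse = ", "))
  body <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (!length(body)) stop("RDF file ", path, " contains no data rows")
  dat <- read.table(text = lines[body], header = FALSE)
  if (ncol(dat) < 2L) stop("RDF file must have at least two columns (r, g)")
  r <- dat[[1L]]; g <- dat[[2L]]
  bad <- which(diff(r) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone r grid at data line %d of %s", bad[1L] + 1L, path))
  if (any(g < 0))
    stop(sprintf("negative g(r) at data line %d of %s", which(g < 0)[1L], path))
  spec <- fluid_spec(rho = as.numeric(meta$rho), sigma = as.numeric(meta$sigma),
                     dim = as.integer(meta$dim),
                     beta = as.numeric(meta$beta %||% 1))
  modified <- isTRUE(as.logical(meta$modified %||% FALSE))
  tabulated_rdf(r, g, spec,
                includes_diagonal = modified,
                profile_diameter = if (modified) as.numeric(meta$a),
                diagonal = if (modified && ncol(dat) >= 3L) dat[[3L]],
                hard_core = if (!is.null(meta$hard_core)) as.logical(meta$hard_core))
}

#' @param rdf a [tabulated_rdf()].
#' @rdname read_rdf
#' @export
write_rdf <- function(rdf, path) {
  stopifnot(inherits(rdf, "tabulated_rdf"))
  sp <- rdf$spec
  hdr <- c(sprintf("# rho: %.17g", sp$rho),
           sprintf("# sigma: %.17g", sp$sigma),
           sprintf("# dim: %d", sp$dim),
           sprintf("# beta: %.17g", sp$beta),
           sprintf("# hard_core: %s", rdf$hard_core),
           if (rdf$includes_diagonal) c(
             "# modified: TRUE",
             sprintf("# a: %.17g", rdf$profile_diameter)))
  cols <- if (rdf$includes_diagonal && !is.null(rdf$diagonal))
    cbind(rdf$r, rdf$g, rdf$diagonal) else cbind(rdf$r, rdf$g)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(cols, digits = 17, trim = TRUE, scientific = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
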