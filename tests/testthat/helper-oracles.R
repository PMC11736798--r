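# shared fixtures and small independent oracles used across test files

# adaptive quadrature wrapper (tight tolerances, many subdivisions)
quad <- function(f, lower, upper, ...) {
  integrate(f, lower, upper, subdivisions = 2000L,
            rel.tol = 1e-10, abs.tol = 1e-12, ...)$value
}

# ideal-gas tabulated RDF (g identically 1)
ideal_rdf <- function(rho, dim, r_max = 10, dr = 1e-3, sigma = 1) {
  r <- seq(0, r_max, by = dr)
  tabulated_rdf(r, rep(1, length(r)),
                fluid_spec(rho, sigma, dim = dim), hard_core = FALSE)
}

# brute-force FCC pair counting oracle: conventional cubic cells with a
# 4-atom basis, distances from one central atom
fcc_supercell_counts <- function(sigma, r_max, n_cells = 5L) {
  a_c <- sigma * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- expand.grid(i = -n_cells:n_cells, j = -n_cells:n_cells,
                       k = -n_cells:n_cells)
  pts <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b)
    cbind(cells$i + basis[b, 1], cells$j + basis[b, 2], cells$k + basis[b, 3])))
  d <- a_c * sqrt(rowSums(pts^2))
  d <- d[d > 1e-9]
  sum(d <= r_max + 1e-9)
}

# hand-made tonks_configs object for unit tests of window counting
fake_configs <- function(positions, sigma, L_box) {
  structure(matrix(positions, nrow = 1L), sigma = sigma, L_box = L_box,
            spec = fluid_spec(length(positions) / L_box, sigma, dim = 1L),
            class = c("tonks_configs", "matrix", "array"))
}
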