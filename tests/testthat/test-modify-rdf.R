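test_that("modifying an ideal gas adds exactly the diagonal term", {
  # convolution of a constant is the constant: g~ = 1 + chi/rho
  for (dim in c(1L, 3L)) {
    rho <- 0.6
    rdf <- ideal_rdf(rho, dim)
    m <- modify_rdf(rdf, 0.9)
    expect_lt(max(abs(m$g - (1 + kernel_chi(rdf$r, 0.9, dim) / rho))), 1e-9)
    expect_equal(m$diagonal, kernel_chi(rdf$r, 0.9, dim) / rho)
  }
})

test_that("modification suppresses hard-rod oscillations at high filling", {
  # the unmodified g oscillates between 0 and 5; g~ is flat to a few
  # percent.  The residual extremum sits at contact: g~(sigma) = 0.9432
  # (verified against direct quadrature of the convolution integral).
  sp <- fluid_spec(1, 0.8, dim = 1)
  m <- modify_rdf(tonks_rdf(sp, r_max = 20), a = 0.8)
  i <- m$r >= 0.8
  expect_lt(max(abs(m$g[i] - 1)), 0.06)
  expect_equal(m$g[abs(m$r - 0.8) < 1e-9], 0.943224, tolerance = 1e-5)
  expect_lt(max(abs(m$g[m$r >= 1.2] - 1)), 0.05)
})

test_that("the long-range integral is invariant under the modification", {
  # 1 + rho int w (g-1) and rho int w (g~-1) agree as L -> infinity,
  # whatever the profile diameter
  sp <- fluid_spec(1, 0.8, dim = 1)
  rdf <- tonks_rdf(sp, r_max = 40)
  Ls <- seq(8, 32, by = 0.08)
  nu_inf <- fit_asymptote(nu_curve(rdf, Ls), c(8, 32))$nu_inf
  for (a in c(0.24, 0.8)) {
    m <- modify_rdf(rdf, a)
    nut_inf <- fit_asymptote(nu_curve(m, Ls), c(8, 32))$nu_inf
    expect_equal(nut_inf, nu_inf, tolerance = 1e-3)
  }
})

test_that("the convolution is linear in the RDF", {
  sp <- fluid_spec(0.5, 1, dim = 1)
  r <- seq(0, 12, by = 1e-3)
  gA <- tonks_rdf(sp, r_max = 12)$g
  gB <- rep(1, length(r))
  mix <- tabulated_rdf(r, 0.5 * gA + 0.5 * gB, sp, hard_core = FALSE)
  mA <- modify_rdf(tabulated_rdf(r, gA, sp, hard_core = FALSE), 0.7)
  mB <- modify_rdf(tabulated_rdf(r, gB, sp, hard_core = FALSE), 0.7)
  mMix <- modify_rdf(mix, 0.7)
  expect_lt(max(abs(mMix$g - (0.5 * mA$g + 0.5 * mB$g))), 1e-12)
})

test_that("parameter and double-modification errors", {
  rdf <- tonks_rdf(fluid_spec(1, 0.8, dim = 1), r_max = 5)
  expect_error(modify_rdf(rdf, 1.2), "a must satisfy")
  expect_error(modify_rdf(rdf, -0.1), "a must satisfy")
  expect_error(modify_rdf(modify_rdf(rdf, 0.8), 0.8), "already modified")
})

test_that("the crystal modified RDF is flat away from the diagonal peak", {
  sh <- fcc_shells(sigma = 1, r_max = 12)
  m <- modify_shell_rdf(sh, a = 1, r_max = 10.5)
  # diagonal part at r = 0 is the kernel peak over the density
  expect_equal(m$diagonal[1], kernel_chi(0, 1, 3) / sqrt(2))
  expect_equal(m$g[1], kernel_chi(0, 1, 3) / sqrt(2), tolerance = 1e-6)
  # flat and equal to 1 outside the small-r diagonal peak region
  i <- m$r >= 0.5
  expect_lt(max(abs(m$g[i] - 1)), 0.05)
  expect_lt(abs(m$g[abs(m$r - 10) < 1e-9] - 1), 0.05)
})

test_that("shrinking the profile sharpens the crystal comb", {
  sh <- fcc_shells(sigma = 1, r_max = 4)
  peak <- function(a) max(modify_shell_rdf(sh, a, r_max = 2, dr = 5e-3)$g)
  expect_gt(peak(0.1), peak(0.3))
  expect_gt(peak(0.3), peak(1))
  expect_gt(peak(0.1), 20)           # approaching the delta comb
})

test_that("the shell table must cover the requested grid", {
  sh <- fcc_shells(sigma = 1, r_max = 4)
  expect_error(modify_shell_rdf(sh, a = 1, r_max = 6), "enlarge")
})

test_that("effective diameters follow the stated limits and values", {
  # 1D: vanishes with density, reaches sigma at close packing
  expect_lt(effective_diameter_1d(fluid_spec(1e-6, 0.8, dim = 1)), 1e-5)
  expect_equal(effective_diameter_1d(fluid_spec(1.2499999, 0.8, dim = 1)), 0.8,
               tolerance = 1e-5)
  # at rho*sigma = 0.8 the reduction is exactly 0.8%
  a1 <- effective_diameter_1d(fluid_spec(1, 0.8, dim = 1))
  expect_equal(1 - a1 / 0.8, 0.008, tolerance = 1e-12)
  # strictly increasing in density
  rr <- seq(0.01, 1.24, length.out = 200)
  a1s <- vapply(rr, function(p) effective_diameter_1d(fluid_spec(p, 0.8, dim = 1)), 0)
  expect_true(all(diff(a1s) > 0))
  # 3D: three-decimal reference values
  a3 <- function(rho) effective_diameter_3d(fluid_spec(rho, 1, dim = 3))
  expect_equal(round(a3(0.1), 3), 0.429)
  expect_equal(round(a3(0.5), 3), 0.939)
  expect_equal(round(a3(0.7), 3), 0.980)
  # dimension guards
  expect_error(effective_diameter_1d(fluid_spec(0.4, 1, dim = 3)), "dim = 1")
  expect_error(effective_diameter_3d(fluid_spec(0.4, 1, dim = 1)), "dim = 3")
})
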