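test_that("weight functions vanish at L and integrate to the subvolume", {
  expect_equal(weight_function(2, 2, 1), 0)
  expect_equal(weight_function(1, 1, 3), 0)
  # quadrature oracle for the closed-form volume integrals
  expect_equal(quad(function(r) weight_function(r, 2, 1), 0, 2), 2,
               tolerance = 1e-10)
  expect_equal(quad(function(r) weight_function(r, 1, 3), 0, 1), pi / 6,
               tolerance = 1e-10)
  expect_error(weight_function(1.5, 1, 3), "r <= L")
})

test_that("the ideal gas has unit fluctuations for every subvolume", {
  for (dim in c(1L, 3L)) {
    rdf <- ideal_rdf(0.7, dim)
    expect_equal(nu_curve(rdf, c(1, 3, 7))$nu, rep(1, 3), tolerance = 1e-12)
    expect_equal(running_kbi_curve(rdf, c(1, 3, 7))$nu, rep(1, 3),
                 tolerance = 1e-12)
  }
})

test_that("fitted hard-rod intercepts reproduce the exact compressibility", {
  for (phi in c(0.2, 0.5, 0.8)) {
    sp <- fluid_spec(phi / 0.8, 0.8, dim = 1)
    rdf <- tonks_rdf(sp, r_max = 30 * 0.8)
    Ls <- seq(8 * 0.8, 24 * 0.8, by = 0.08)
    fit <- fit_asymptote(nu_curve(rdf, Ls), range(Ls))
    expect_equal(fit$nu_inf, (1 - phi)^2, tolerance = 1e-3)
  }
})

test_that("finite-volume fluctuations are non-negative across the models", {
  curves <- list(
    nu_curve(tonks_rdf(fluid_spec(0.25, 0.8, dim = 1), r_max = 16)),
    nu_curve(tonks_rdf(fluid_spec(1, 0.8, dim = 1), r_max = 16)),
    nu_curve(py_rdf(fluid_spec(0.3, 1, dim = 3), r_max = 15)),
    nu_curve(py_rdf(fluid_spec(0.7, 1, dim = 3), r_max = 15)),
    nu_curve(modify_shell_rdf(fcc_shells(r_max = 12), 1, r_max = 10.5),
             seq(2, 8, by = 0.1)))
  for (cv in curves) expect_gt(min(cv$nu), -1e-9)
})

test_that("running KBI shows its known pathologies", {
  # 1D hard rods at high filling: negative values
  rk <- running_kbi_curve(tonks_rdf(fluid_spec(1, 0.8, dim = 1), r_max = 16))
  expect_lt(min(rk$nu), 0)
  # crystal: oscillation envelope grows with L (divergence diagnostic)
  rk_fcc <- running_kbi_curve(fcc_shells(r_max = 12), seq(2, 9.6, by = 0.1))
  early <- max(abs(rk_fcc$nu[rk_fcc$L <= 3.5]))
  late <- max(abs(rk_fcc$nu[rk_fcc$L >= 7]))
  expect_gt(late, 2 * early)
  expect_gt(late, 10)
})

test_that("asymptote fitting is exact on a noiseless 1/L curve", {
  sp <- fluid_spec(0.3, 1, dim = 3)
  cv <- structure(list(L = seq(10, 40, 0.5), nu = 0.3 + 0.5 / seq(10, 40, 0.5),
                       method = "finite_volume", modified = FALSE,
                       spec = sp, a = NULL), class = "fluctuation_curve")
  fit <- fit_asymptote(cv)
  expect_equal(fit$nu_inf, 0.3, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_lt(fit$residual_norm, 1e-12)
  expect_lt(fit$stability, 1e-12)
  expect_error(fit_asymptote(cv, c(39, 40)), "at least 10 points")
})

test_that("curves refuse subvolumes beyond the tabulated range", {
  rdf <- tonks_rdf(fluid_spec(1, 0.8, dim = 1), r_max = 8)
  expect_error(nu_curve(rdf, c(2, 9)), "shortfall")
})

test_that("with the corrected 1D diameter the curve is flat to 0.005", {
  sp <- fluid_spec(1, 0.8, dim = 1)
  m <- modify_rdf(tonks_rdf(sp, r_max = 24), effective_diameter_1d(sp))
  Ls <- seq(0.8, 16, by = 0.08)
  cv <- nu_curve(m, Ls)
  nut_inf <- fit_asymptote(cv, c(8, 16))$nu_inf
  expect_lt(max(abs(cv$nu - nut_inf)), 0.005)
})

test_that("curves export with their metadata", {
  f <- withr::local_tempfile(fileext = ".dat")
  cv <- nu_curve(tonks_rdf(fluid_spec(0.5, 0.8, dim = 1), r_max = 8),
                 c(1, 2, 4))
  write_curve(cv, f)
  lines <- readLines(f)
  expect_true(any(grepl("# method: finite_volume", lines)))
  dat <- read.table(f)
  expect_equal(dat[[1]], cv$L)
  expect_equal(dat[[2]], cv$nu, tolerance = 1e-6)
})
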