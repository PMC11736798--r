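test_that("sampled configurations are overlap-free and reproducible", {
  sp <- fluid_spec(1, 0.8, dim = 1)
  cfg <- sample_tonks(sp, L_box = 40, n_sweeps = 500, seed = 3)
  m <- unclass(cfg)
  gaps <- t(apply(m, 1, function(p) diff(c(p, p[1] + 40))))
  expect_gte(min(gaps), 0.8 - 1e-9)
  expect_true(all(m >= 0 & m < 40))
  cfg2 <- sample_tonks(sp, L_box = 40, n_sweeps = 500, seed = 3)
  expect_identical(unclass(cfg), unclass(cfg2))   # bit-reproducible
  cfg3 <- sample_tonks(sp, L_box = 40, n_sweeps = 500, seed = 4)
  expect_false(identical(unclass(cfg), unclass(cfg3)))
})

test_that("sampler validates box and packing", {
  sp <- fluid_spec(1, 0.8, dim = 1)
  expect_error(sample_tonks(sp, L_box = 10), "20\\*sigma")
})

test_that("histogram RDF matches the exact solution within 3 SE per bin", {
  sp <- fluid_spec(0.5, 1, dim = 1)
  cfg <- sample_tonks(sp, L_box = 100, n_sweeps = 3e4, seed = 5, thin = 10)
  h <- rdf_histogram(cfg, bin_width = 0.1, r_max = 8)
  exact <- tonks_rdf(sp, r_max = 9)
  # bin-averaged exact g (the histogram estimates the bin mean, not the
  # midpoint value)
  bin <- findInterval(exact$r, seq(0, 8, by = 0.1), rightmost.closed = FALSE)
  keep <- exact$r > 0 & exact$r <= 8
  gi <- as.numeric(tapply(exact$g[keep], bin[keep], mean))[seq_along(h$r)]
  se <- pmax(attr(h, "se"), 1e-3)
  out <- h$r > 1.05 | h$r < 0.95      # contact bin straddles the jump
  z <- abs(h$g - gi)[out] / se[out]
  # per-bin agreement: with ~80 bins the extreme-order statistic of pure
  # noise occasionally passes 3, so bound the count of outliers and the
  # overall scale as well as the maximum
  expect_lt(max(z), 5)
  expect_lte(sum(z > 3), 3)
  expect_lt(mean(z^2), 2)
  # hard core: empty bins below sigma
  expect_equal(sum(h$g[h$r < 0.95]), 0)
})

test_that("fractional counting handles containment, straddling and wrap", {
  ov <- nanofluct:::interval_overlap
  # rod fully inside the window contributes its whole profile
  expect_equal(ov(2, 3, 1, 5, 20) / 1, 1)
  # rod straddling the boundary by half its length contributes 0.5
  expect_equal(ov(4.5, 5.5, 1, 5, 20) / 1, 0.5)
  # window wrapping through the origin
  expect_equal(ov(19.4, 20.4, 19.5, 21, 20), 0.9)
})

test_that("window statistics validate the window size", {
  cfg <- fake_configs(c(1, 5, 9, 13, 17), sigma = 0.8, L_box = 20)
  expect_error(window_fluctuations(cfg, L_w = 8), "L_box/4")
})

test_that("discrete window counts match the finite-volume quadrature", {
  sp <- fluid_spec(1, 0.8, dim = 1)
  cfg <- sample_tonks(sp, L_box = 160, n_sweeps = 3e4, seed = 9, thin = 10)
  rdf <- tonks_rdf(sp, r_max = 10)
  for (Lw in c(0.8, 1.6, 4)) {
    ws <- window_fluctuations(cfg, L_w = Lw, mode = "discrete")
    # fixed-N sampling shrinks the open-window variance by (1 - L_w/L_box)
    # (exact for the ideal gas, leading order here)
    nu_exact <- nu_curve(rdf, Lw)$nu * (1 - Lw / 160)
    expect_lt(abs(ws$nu_hat - nu_exact) / ws$se_nu, 3)
    expect_equal(ws$mean_count, sp$rho * Lw, tolerance = 0.02)
  }
})

test_that("fractional counts reproduce the modified-RDF fluctuations and
          are nearly flat with the corrected diameter", {
  sp <- fluid_spec(1, 0.8, dim = 1)
  a1 <- effective_diameter_1d(sp)
  cfg <- sample_tonks(sp, L_box = 160, n_sweeps = 3e4, seed = 13, thin = 10)
  m <- modify_rdf(tonks_rdf(sp, r_max = 10), a1)
  Lws <- c(1.6, 2.4, 4)
  stats <- lapply(Lws, function(Lw)
    window_fluctuations(cfg, L_w = Lw, mode = "fractional", a = a1))
  nus <- vapply(stats, `[[`, 0, "nu_hat")
  ses <- vapply(stats, `[[`, 0, "se_nu")
  # each point agrees with the independent convolution route
  nut <- nu_curve(m, Lws)$nu
  expect_lt(max(abs(nus - nut) / ses), 3.5)
  # weighted LS slope over L_w consistent with zero at 2 SE
  w <- 1 / ses^2
  xb <- sum(w * Lws) / sum(w); yb <- sum(w * nus) / sum(w)
  slope <- sum(w * (Lws - xb) * (nus - yb)) / sum(w * (Lws - xb)^2)
  se_slope <- sqrt(1 / sum(w * (Lws - xb)^2))
  expect_lt(abs(slope), 2 * se_slope + 1e-12)
})

test_that("rdf_histogram demands enough configurations", {
  cfg <- fake_configs(c(1, 5, 9), sigma = 0.8, L_box = 24)
  expect_error(rdf_histogram(cfg), "at least 100")
})
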