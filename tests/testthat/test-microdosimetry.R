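test_that("single-line spectra reproduce the closed-form saturation correction", {
  y0 <- 150
  for (y in c(0.1, 1, 15, 50, 150, 500, 1000)) {
    sp <- generate_spectrum("ion", y, width = 0)
    expected <- y0^2 * (1 - exp(-(y / y0)^2)) / y
    expect_equal(compute_ystar(sp, y0), expected, tolerance = 1e-8)
  }
  # hand-evaluated anchor points
  expect_equal(compute_ystar(generate_spectrum("ion", 15, width = 0), 150),
               14.92525, tolerance = 1e-6)
  expect_equal(compute_ystar(generate_spectrum("ion", 150, width = 0), 150),
               150 * (1 - exp(-1)), tolerance = 1e-7)
})

test_that("y* approaches y in the low lineal-energy limit", {
  sp <- generate_spectrum("ion", 0.1, width = 0)
  expect_equal(compute_ystar(sp, 150), 0.1, tolerance = 1e-4)
})

test_that("y* respects the analytic saturation bound and grid refinement", {
  for (let in c(5, 50, 200)) {
    y <- exp(seq(log(let) - 2, log(let) + 2, length.out = 300))
    f <- dlnorm(y, log(let), 0.3)
    sp <- mds_spectrum(y, f)
    bound <- 150^2 / y_frequency_mean(sp)
    expect_lt(compute_ystar(sp, 150), bound + 1e-9)
    y2 <- exp(seq(log(let) - 2, log(let) + 2, length.out = 599))
    sp2 <- mds_spectrum(y2, dlnorm(y2, log(let), 0.3))
    expect_equal(compute_ystar(sp, 150), compute_ystar(sp2, 150),
                 tolerance = 1e-4)
  }
})

test_that("spectrum construction validates and renormalizes", {
  expect_error(mds_spectrum(c(1, 2), c(-1, 1)), "invalid-spectrum")
  expect_error(mds_spectrum(c(2, 1), c(1, 1)), "increasing")
  expect_error(mds_spectrum(c(0, 1), c(1, 1)), "invalid-spectrum")
  expect_error(mds_spectrum(c(1, 2), c(0, 0)), "normalize")
  y <- seq(1, 100, length.out = 200)
  sp <- mds_spectrum(y, 7.3 * dlnorm(y, log(20), 0.4))  # unnormalized input
  expect_equal(sum(diff(y) * (sp$density[-1] + sp$density[-200]) / 2), 1,
               tolerance = 1e-9)
})

test_that("dose-weighted d(y) dialect converts through f(y) ~ d(y)/y", {
  y <- exp(seq(log(1), log(300), length.out = 400))
  f <- dlnorm(y, log(40), 0.35)
  sp_f <- mds_spectrum(y, f)
  sp_d <- mds_spectrum(y, y * f, dialect = "dy")
  expect_equal(compute_ystar(sp_d, 150), compute_ystar(sp_f, 150),
               tolerance = 1e-12)
})

test_that("z1D* conversion is dimensionally correct, linear and r_d^-2", {
  expect_identical(compute_z1dstar(0, domain_geometry(0.42)), 0)
  # hand conversion: 100 keV/um in a 0.42 um water domain
  expect_equal(compute_z1dstar(100, domain_geometry(0.42)),
               100 * 1.602176634e-16 * 1e6 / (1000 * pi * (0.42e-6)^2),
               tolerance = 1e-12)
  expect_equal(compute_z1dstar(100, domain_geometry(0.42)), 28.9,
               tolerance = 1e-3)
  g1 <- domain_geometry(0.3); g2 <- domain_geometry(0.6)
  expect_equal(compute_z1dstar(37, g1) / compute_z1dstar(37, g2), 4,
               tolerance = 1e-12)
  expect_equal(compute_z1dstar(80, g1), 2 * compute_z1dstar(40, g1),
               tolerance = 1e-12)
  expect_error(domain_geometry(-0.1), "geometry")
})

test_that("generated spectra are deterministic and track the nominal LET", {
  sp <- generate_spectrum("ion", 50, width = 0)
  expect_equal(y_frequency_mean(sp), 50, tolerance = 1e-9)
  a <- generate_spectrum("ion", 50, width = 0.3, noise = 0.05, seed = 42)
  b <- generate_spectrum("ion", 50, width = 0.3, noise = 0.05, seed = 42)
  expect_identical(a$density, b$density)
  c2 <- generate_spectrum("ion", 50, width = 0.3, noise = 0.05, seed = 43)
  expect_false(identical(a$density, c2$density))
})

test_that("y* of generated spectra rises with LET then saturates", {
  lets <- c(1, 2, 5, 10, 20, 40, 80)
  ys <- sapply(lets, function(l)
    compute_ystar(generate_spectrum("ion", l, width = 0.25), 150))
  expect_true(all(diff(ys) > 0))
  # beyond the saturation scale the correction caps and turns over
  y_high <- sapply(c(150, 300, 500), function(l)
    compute_ystar(generate_spectrum("ion", l, width = 0.25), 150))
  expect_true(all(y_high < 150^2 / 100))
  expect_lt(y_high[3], y_high[1])
})
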