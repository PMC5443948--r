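vis <- ideal_visual_system()

spectrum_of <- function(f, step = 5) {
  wl <- seq(300, 700, by = step)
  tibble::tibble(wavelength_nm = wl, reflectance = f(wl))
}

test_that("photon catch is linear in reflectance and normalised white gives 1", {
  r1 <- spectrum_of(function(w) 0.3 + 0.2 * sin(w / 40))
  r2 <- spectrum_of(function(w) exp(-((w - 500) / 60)^2))
  for (rec in c("uv", "sw", "mw", "lw", "double")) {
    q1 <- photon_catch(r1, vis, rec)
    q2 <- photon_catch(r2, vis, rec)
    mix <- r1
    mix$reflectance <- 0.4 * r1$reflectance + 0.6 * r2$reflectance
    expect_equal(photon_catch(mix, vis, rec), 0.4 * q1 + 0.6 * q2,
                 tolerance = 1e-10)
  }
  white <- spectrum_of(function(w) rep(1, length(w)))
  for (rec in c("uv", "sw", "mw", "lw", "double")) {
    expect_equal(photon_catch(white, vis, rec), 1, tolerance = 1e-9)
  }
  black <- spectrum_of(function(w) rep(0, length(w)))
  expect_equal(photon_catch(black, vis, "mw"), 0)
})

test_that("photon catch matches a fine-grid trapezoid oracle", {
  bump <- function(w) 0.8 * exp(-((w - 520) / 45)^2)
  spec5 <- spectrum_of(bump, step = 5)
  sens <- function(w) exp(-0.5 * ((w - 508) / 32)^2)   # the mw curve
  fine <- seq(300, 700, by = 0.5)
  oracle <- pracma::trapz(fine, bump(fine) * sens(fine)) /
    pracma::trapz(fine, sens(fine))
  ours <- photon_catch(spec5, vis, "mw")
  expect_lt(abs(ours - oracle) / oracle, 1e-3)
})

test_that("disjoint wavelength ranges are an error", {
  uvspec <- tibble::tibble(wavelength_nm = 200:250,
                           reflectance = rep(0.5, 51))
  expect_error(photon_catch(uvspec, vis, "uv"), "overlap")
})

test_that("granularity energies vanish for a constant image and obey Parseval on a full mask", {
  flat <- egg_image(matrix(0.6, 64, 64), matrix(TRUE, 64, 64))
  g <- granularity_spectrum(flat)
  expect_true(all(g$energy < 1e-20))

  set.seed(7)
  px <- matrix(runif(64 * 64), 64, 64)
  img <- egg_image(px, matrix(TRUE, 64, 64))
  g <- granularity_spectrum(img)
  total_var <- mean((px - mean(px))^2)
  expect_equal(sum(g$energy), total_var, tolerance = 1e-10)
})

test_that("a grating's energy peaks in the band containing its period", {
  px <- matrix(0.5 + 0.4 * sin(2 * pi * col(matrix(0, 128, 128)) / 16),
               128, 128)
  img <- egg_image(px, matrix(TRUE, 128, 128))
  g <- granularity_spectrum(img)
  peak <- g[which.max(g$energy), ]
  expect_true(peak$freq_lo < 1 / 16 && 1 / 16 <= peak$freq_hi)
  expect_equal(peak$scale_px, 16)
})

test_that("granularity is invariant to a DC shift", {
  img <- generate_spot_image(96, 96, 6, 0.3, seed = 71)
  g1 <- granularity_spectrum(img)
  img2 <- egg_image(img$pixels + 0.1, img$mask)
  g2 <- granularity_spectrum(img2)
  expect_equal(g1$energy, g2$energy, tolerance = 1e-12)
})

test_that("pattern metrics: degenerate, half-dark and spot-size cases", {
  flat <- egg_image(matrix(0.6, 64, 64), elliptical_mask_for_test(64, 64))
  pm <- pattern_metrics(flat)
  expect_equal(pm$coverage, 0)
  expect_equal(pm$contrast, 0)
  expect_equal(pm$main_contribution, 0)
  expect_true(is.na(pm$marking_size))

  # exactly half the mask darker
  mask <- matrix(TRUE, 60, 60)
  px <- matrix(0.8, 60, 60); px[, 1:30] <- 0.2
  pm <- pattern_metrics(egg_image(px, mask))
  expect_equal(pm$coverage, 0.5)

  # predominant marking size falls in the band containing the spot diameter
  img <- generate_spot_image(128, 128, spot_radius_px = 8,
                             coverage_target = 0.3, seed = 81)
  g <- granularity_spectrum(img)
  pm <- pattern_metrics(img, g)
  band <- g[g$scale_px == pm$marking_size, ]
  expect_true(band$freq_lo < 1 / 16 && 1 / 16 <= band$freq_hi)
})

test_that("clustered markings have higher dispersion than spread markings", {
  mask <- matrix(TRUE, 60, 120)
  spread <- matrix(0.8, 60, 120)
  spread[, seq(5, 115, by = 10)] <- 0.2            # evenly spaced stripes
  clustered <- matrix(0.8, 60, 120)
  clustered[, 1:12] <- 0.2                          # all dark in one zone
  pm_s <- pattern_metrics(egg_image(spread, mask))
  pm_c <- pattern_metrics(egg_image(clustered, mask))
  expect_gt(pm_c$dispersion, pm_s$dispersion)
})

test_that("pattern metrics are invariant to translating the masked egg", {
  img <- generate_spot_image(100, 100, 6, 0.25, seed = 91)
  shift <- function(m, dy, dx, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  # embed in a larger canvas so the shift stays in-frame
  big_px <- matrix(0.75, 140, 140); big_mk <- matrix(FALSE, 140, 140)
  big_px[21:120, 21:120] <- img$pixels; big_mk[21:120, 21:120] <- img$mask
  a <- egg_image(big_px, big_mk)
  b <- egg_image(shift(big_px, 7, 11, 0.75), shift(big_mk, 7, 11, FALSE))
  pm_a <- pattern_metrics(a, granularity_spectrum(a))
  pm_b <- pattern_metrics(b, granularity_spectrum(b))
  expect_equal(pm_a, pm_b, tolerance = 1e-9)
})

test_that("egg_phenotype assembles the canonical 10-trait row", {
  spec <- spectrum_of(function(w) 0.4 + 0.3 * exp(-((w - 450) / 50)^2))
  img <- generate_spot_image(96, 96, 6, 0.3, seed = 99)
  ph <- egg_phenotype(spec, img)
  expect_identical(names(ph), egg_traits())
  expect_true(all(vapply(ph, is.finite, logical(1))))
})
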