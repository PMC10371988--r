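# spectrum I/O, preprocessing, binning and colorimetric indices

test_that("read/write round-trips and validates", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sp <- gen_spectra(spectra_scenario(seed = 2), n_backgrounds = 2,
                    n_tadpoles_per_bg = 1, n_reps = 2)
  write_spectra(sp, tmp)
  back <- read_spectra(tmp)
  expect_equal(back$reflectance, sp$reflectance, tolerance = 1e-12)
  expect_equal(back$wavelength, sp$wavelength)

  toy <- data.frame(wavelength = c(400, 410, 420), reflectance = c(1, 2, 3),
                    specimen_id = "a", role = "tadpole", replicate = 1)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy, tmp2, row.names = FALSE)
  expect_equal(nrow(read_spectra(tmp2)), 3)

  dup <- toy; dup$wavelength[2] <- 400
  utils::write.csv(dup, tmp2, row.names = FALSE)
  expect_error(read_spectra(tmp2), "strictly increasing.*'a'")

  utils::write.csv(toy[, -1], tmp2, row.names = FALSE)
  expect_error(read_spectra(tmp2), "wavelength")
})

test_that("process_spectrum trims and the smoother reproduces polynomials", {
  const <- flat_spectrum(40)
  out <- process_spectrum(const)
  expect_true(all(out$wavelength >= 400 & out$wavelength <= 700))
  expect_equal(out$reflectance, rep(40, nrow(out)), tolerance = 1e-9)

  ramp <- data.frame(wavelength = 360:740,
                     reflectance = (360:740 - 360) * 0.2)
  out2 <- process_spectrum(ramp)
  expect_equal(out2$reflectance, (out2$wavelength - 360) * 0.2,
               tolerance = 1e-9)

  quad <- data.frame(wavelength = 360:740,
                     reflectance = 20 + 1e-4 * (360:740 - 550)^2)
  out3 <- process_spectrum(quad)
  expect_equal(out3$reflectance, 20 + 1e-4 * (out3$wavelength - 550)^2,
               tolerance = 1e-7)
})

test_that("smoothing attenuates a single-point spike by more than half", {
  s <- flat_spectrum(30)
  i <- which(s$wavelength == 550)
  s$reflectance[i] <- 30 + 20          # 20-unit spike
  out <- process_spectrum(s)
  spike_left <- max(abs(out$reflectance - 30))
  expect_lt(spike_left, 10)
})

test_that("process_spectrum rejects degenerate windows and spans", {
  few <- data.frame(wavelength = c(398, 400, 500, 600, 702),
                    reflectance = 1:5)
  expect_error(process_spectrum(few), "fewer than 5")
  expect_error(process_spectrum(flat_spectrum(10), span = 0), "span")
  expect_error(process_spectrum(flat_spectrum(10), lo = 700, hi = 400), "lo")
})

test_that("bin_spectrum tiles exactly and averages per bin", {
  flat <- process_spectrum(flat_spectrum(50), span = NULL)
  b <- bin_spectrum(flat)
  expect_length(b, 20)
  expect_true(all(b == 50))
  expect_identical(names(b)[1], "400")

  ramp <- data.frame(wavelength = 400:700, reflectance = 400:700 - 400)
  b2 <- bin_spectrum(ramp, width = 150)
  expect_length(b2, 2)
  # [400,550): mean of 0..149 = 74.5; [550,700]: mean of 150..300 = 225
  expect_equal(unname(b2), c(74.5, 225), ignore_attr = TRUE)

  expect_error(bin_spectrum(ramp, width = 7), "does not tile")
  short <- data.frame(wavelength = 450:700, reflectance = 1)
  expect_error(bin_spectrum(short), "cover")
})

test_that("normalize_mean_zero centres exactly and is idempotent", {
  expect_equal(unname(normalize_mean_zero(c(10, 20, 30))), c(-10, 0, 10))
  b <- bin_spectrum(process_spectrum(flat_spectrum(50), span = NULL))
  expect_true(all(normalize_mean_zero(b) == 0))
  set.seed(9)
  v <- runif(20, 0, 100)
  n1 <- normalize_mean_zero(v)
  expect_lt(abs(mean(n1)), 1e-12)
  expect_equal(normalize_mean_zero(n1), n1)
})

test_that("color_indices implements B2, H1, S8 and the flat flag", {
  flat <- data.frame(wavelength = 400:700, reflectance = 50)
  ci <- color_indices(flat)
  expect_equal(ci$B2, 50)
  expect_equal(ci$S8, 0)
  expect_true(ci$flat_flag)

  s <- data.frame(wavelength = c(400, 500, 600), reflectance = c(10, 20, 30))
  expect_equal(color_indices(s)$S8, 1.0)     # (30 - 10) / 20

  wl <- 400:700
  bump <- data.frame(wavelength = wl,
                     reflectance = 10 + 40 * exp(-(wl - 550)^2 / 800))
  expect_equal(color_indices(bump)$H1, 550)

  # ties resolved to the smallest wavelength
  tie <- data.frame(wavelength = 400:404, reflectance = c(1, 5, 5, 2, 1))
  expect_equal(color_indices(tie)$H1, 401)

  zero <- data.frame(wavelength = 400:700, reflectance = 0)
  ci0 <- color_indices(zero)
  expect_true(is.na(ci0$S8) && ci0$flat_flag)
})

test_that("regress_index matches closed-form OLS and lm", {
  exact <- regress_index(1:5, 2 * (1:5) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$adj_R2, 1)

  orth <- regress_index(c(1, 2, 3, 4), c(1, -1, -1, 1))
  expect_equal(orth$slope, 0)
  expect_equal(orth$F, 0)

  # hand-computed normal equations: x = 1:4, y = (2,3,5,4)
  # slope = 16/20 = 0.8, intercept = 1.5, SSE = 1.8, SST = 5, F = 3.2/0.9
  r <- regress_index(1:4, c(2, 3, 5, 4))
  expect_equal(r$slope, 0.8)
  expect_equal(r$intercept, 1.5)
  expect_equal(r$adj_R2, 1 - 0.36 * 3 / 2)
  expect_equal(r$F, 32 / 9)
  expect_equal(r$df, c(1L, 2L))
  # lm as an independent oracle
  lmfit <- summary(stats::lm(y ~ x, data.frame(x = 1:4, y = c(2, 3, 5, 4))))
  expect_equal(r$F, unname(lmfit$fstatistic[1]))
  expect_equal(r$adj_R2, lmfit$adj.r.squared)

  expect_error(regress_index(rep(1, 4), 1:4), "zero variance")
  expect_error(regress_index(1:2, 1:2), "3 paired")
})

test_that("trimming/binning invariants hold", {
  sp <- gen_spectra(spectra_scenario(seed = 5), n_backgrounds = 1,
                    n_tadpoles_per_bg = 1, n_reps = 1)
  one <- sp[sp$role == "tadpole", ]
  p1 <- process_spectrum(one)
  # trimming an already-trimmed spectrum changes nothing, so binning after
  # a second trim gives identical bins
  p2 <- process_spectrum(p1, span = NULL)
  expect_equal(bin_spectrum(p2), bin_spectrum(p1))

  # B2 is (near-)invariant under exact-tiling bin widths; the closed last
  # bin holds one extra grid point, so equality is to ~1% not machine eps
  b2 <- color_indices(p1)$B2
  for (w in c(15, 30, 75)) {
    expect_equal(mean(bin_spectrum(p1, width = w)), b2,
                 tolerance = 0.01)
  }
})

test_that("smoothing preserves the mean of symmetric noise", {
  set.seed(4)
  s <- flat_spectrum(50)
  s$reflectance <- s$reflectance + rnorm(nrow(s), 0, 2)
  raw_mean <- mean(s$reflectance[s$wavelength >= 400 & s$wavelength <= 700])
  sm_mean <- mean(process_spectrum(s)$reflectance)
  expect_equal(sm_mean, raw_mean, tolerance = 0.05)
})
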