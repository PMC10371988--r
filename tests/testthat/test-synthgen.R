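# generators: noise-free mean structure, determinism, ground-truth recovery

test_that("gen_spectra reproduces the noiseless brightness response exactly", {
  # floor 5, gain 0.4 on a black (0%) background: tadpoles flat at 5%
  sc <- spectra_scenario(background_kind = "grey", background_brightness = 0,
                         replicate_noise_sd = 0, tadpole_gain = 0.4,
                         tadpole_floor = 5, seed = 1)
  sp <- gen_spectra(sc, n_tadpoles_per_bg = 2, n_reps = 1)
  tad <- sp[sp$role == "tadpole", ]
  expect_true(all(tad$reflectance == 5))

  # white (100%) background: 5 + 0.4 * 100 = 45
  sc2 <- spectra_scenario(background_kind = "grey",
                          background_brightness = 100,
                          replicate_noise_sd = 0, tadpole_gain = 0.4,
                          tadpole_floor = 5, seed = 1)
  sp2 <- gen_spectra(sc2, n_tadpoles_per_bg = 1, n_reps = 1)
  expect_equal(mean(sp2$reflectance[sp2$role == "tadpole"]), 45)
})

test_that("generators are bit-identical under a fixed seed", {
  sc <- spectra_scenario(seed = 11)
  expect_identical(gen_spectra(sc, n_tadpoles_per_bg = 1, n_reps = 2),
                   gen_spectra(sc, n_tadpoles_per_bg = 1, n_reps = 2))
  ks <- kinetics_scenario(seed = 11)
  expect_identical(gen_luma_series(ks), gen_luma_series(ks))
  ss <- shape_scenario(seed = 11)
  expect_identical(gen_landmarks(ss), gen_landmarks(ss))
  ps <- panel_scenario(seed = 11)
  expect_identical(gen_panel(ps), gen_panel(ps))
  rs <- raman_scenario(seed = 11)
  expect_identical(gen_raman(rs), gen_raman(rs))
})

test_that("gen_spectra validates brightness and rejects bad inputs", {
  expect_error(spectra_scenario(background_brightness = 120), "\\[0, 100\\]")
  expect_error(spectra_scenario(background_kind = "colour"), "hue_peak")
  expect_error(gen_spectra(spectra_scenario(), n_reps = 0), "n_reps")
})

test_that("tadpole B2 regressed on background B2 recovers the gain", {
  sc <- spectra_scenario(background_brightness = seq(5, 95, by = 10),
                         tadpole_gain = 0.6, tadpole_floor = 2,
                         replicate_noise_sd = 1, seed = 21)
  sp <- gen_spectra(sc, n_tadpoles_per_bg = 5, n_reps = 3)
  truth <- attr(sp, "truth")
  vis <- sp$wavelength >= 400 & sp$wavelength <= 700
  tad <- sp[sp$role == "tadpole" & vis, ]
  b2 <- tapply(tad$reflectance, tad$specimen_id, mean)
  bg_b2 <- truth$bg_b2[match(substr(names(b2), 1, 4), truth$background_id)]
  fit <- summary(stats::lm(b2 ~ bg_b2))
  expect_lt(abs(fit$coefficients["bg_b2", "Estimate"] - 0.6),
            3 * fit$coefficients["bg_b2", "Std. Error"])
})

test_that("gen_luma_series follows the quadratic-plateau mean", {
  sc <- kinetics_scenario(a = 0.451, b = -0.057, xs = 12.673, noise_sd = 0,
                          times = c(0, 5, 12.673, 30, 60))
  s <- gen_luma_series(sc)
  expect_equal(s$luma[1], 0.451)                         # intercept at t = 0
  expect_equal(s$luma[5], 0.451 - 0.057 * 12.673 / 2)    # plateau, = 0.0898195
  expect_equal(s$luma[5], 0.0898195, tolerance = 1e-7)
  expect_identical(s$direction[1], "light_to_dark")

  flat <- gen_luma_series(kinetics_scenario(a = 0.3, b = 0, xs = 5,
                                            noise_sd = 0))
  expect_true(all(flat$luma == 0.3))
  expect_error(kinetics_scenario(xs = -1), "xs")
  expect_error(kinetics_scenario(times = c(3, 2, 1)), "increasing")
})

test_that("gen_landmarks: noise-free structure and group displacement", {
  sc0 <- shape_scenario(landmark_noise_sd = 0,
                        group_effect = matrix(0, 22, 2), n_per_group = 2,
                        seed = 1)
  cfgs <- gen_landmarks(sc0)
  for (cf in cfgs) expect_equal(cf$coords, tadpole_template())

  delta <- matrix(0, 22, 2); delta[4, 1] <- -0.05
  sc1 <- shape_scenario(landmark_noise_sd = 0, group_effect = delta,
                        n_per_group = 2, seed = 1)
  cfgs1 <- gen_landmarks(sc1)
  grp <- vapply(cfgs1, `[[`, "", "group")
  dark <- cfgs1[grp == "dark"]; light <- cfgs1[grp == "light"]
  expect_equal(dark[[1]]$coords, dark[[2]]$coords)       # within-group: 0
  expect_gt(sum((dark[[1]]$coords - light[[1]]$coords)^2), 0)
})

test_that("quadratic bending bends a straight midline into a parabola", {
  tmpl <- cbind(seq(0, 1, length.out = 22), 0)
  sc <- shape_scenario(template = tmpl, landmark_noise_sd = 0,
                       group_effect = matrix(0, 22, 2), n_per_group = 2,
                       bend_coefficient = 0.2, seed = 1)
  coords <- gen_landmarks(sc)[[1]]$coords
  h <- diff(tmpl[1:2, 1])
  d2 <- diff(diff(coords[, 2]))
  expect_equal(d2, rep(2 * 0.2 * h^2, 20), tolerance = 1e-10)
})

test_that("gen_panel draws around the scenario means with positive glutathione", {
  sc <- panel_scenario(n_per_group = 200, seed = 3)
  p <- gen_panel(sc)
  expect_setequal(unique(p$group), c("dark", "light"))
  expect_true(all(p$GSH > 0) && all(p$GSSG > 0))
  m <- sc$group_means
  for (v in rownames(m)) {
    got <- tapply(p[[v]], p$group, mean)
    expect_equal(as.numeric(got[colnames(m)]), as.numeric(m[v, ]),
                 tolerance = 0.1)
  }
  expect_error(panel_scenario(group_means = {
    m2 <- sc$group_means; m2["GSSG", 1] <- -1; m2
  }), "GSSG")
})

test_that("gen_raman places noiseless band maxima at the band centres", {
  local_max <- function(df) {
    y <- df$intensity
    df$wavenumber[which(diff(sign(diff(y))) == -2) + 1L]
  }
  eu <- gen_raman(raman_scenario(band_centers = c(1380, 1580),
                                 band_amplitudes = c(1, 1),
                                 band_widths = c(40, 40),
                                 baseline_poly = 0, noise_sd = 0))
  expect_setequal(local_max(eu), c(1380, 1580))

  ph <- gen_raman(raman_scenario(band_centers = c(500, 1490, 2000),
                                 band_amplitudes = c(1, 1, 1),
                                 band_widths = c(30, 30, 30),
                                 baseline_poly = 0, noise_sd = 0))
  expect_setequal(local_max(ph), c(500, 1490, 2000))

  zero <- gen_raman(raman_scenario(band_centers = numeric(0),
                                   band_amplitudes = numeric(0),
                                   band_widths = numeric(0),
                                   baseline_poly = 0, noise_sd = 0))
  expect_true(all(zero$intensity == 0))
  expect_error(raman_scenario(band_centers = 3000), "wavenumber_range")
})
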