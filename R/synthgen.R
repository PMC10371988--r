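## Synthetic-data generators.
##
## Every input the analysis stages consume can be simulated here with known
## ground truth: reflectance spectra of rearing backgrounds and of tadpoles
## whose brightness tracks the background, luma time series from a
## quadratic-plateau process, landmark configurations with a group-specific
## tail-fin displacement, antioxidant enzyme panels with group mean shifts,
## and Raman spectra built from Gaussian bands on a smooth baseline.

# wavelength grid of the simulated spectrophotometer (nm)
SPEC_GRID_LO <- 360
SPEC_GRID_HI <- 740

#' Scenario for synthetic reflectance spectra
#'
#' Describes a set of rearing backgrounds (flat grey spectra, or Gaussian
#' colour bumps on a low pedestal) and the brightness response of the
#' tadpoles reared on them.  Tadpole dorsal spectra are generated flat
#' (achromatic): the modelled animals regulate brightness only, with an
#' attenuated match on light backgrounds controlled by `tadpole_gain` and
#' `tadpole_floor`: expected tadpole B2 = floor + gain * background B2.
#'
#' @param background_kind `"grey"` or `"colour"`; recycled to the number of
#'   backgrounds.
#' @param background_brightness Mean reflectance of each background over the
#'   visible range, percent in `[0, 100]`.  Vector = one value per background.
#' @param hue_peak Peak wavelength (nm, in `[400, 700]`) for colour
#'   backgrounds; ignored for grey ones.
#' @param peak_width Gaussian sd of the colour bump (nm).
#' @param replicate_noise_sd Measurement noise sd (percent reflectance),
#'   applied both as a per-replicate offset and as per-wavelength jitter.
#' @param tadpole_gain Slope of tadpole B2 on background B2 (unitless).
#' @param tadpole_floor Minimum tadpole brightness (percent).
#' @param seed Integer seed.
#' @return An object of class `"spectra_scenario"`.
#' @export
spectra_scenario <- function(background_kind = "grey",
                             background_brightness = c(2, 12, 25, 45, 65, 80, 92),
                             hue_peak = NULL,
                             peak_width = 40,
                             replicate_noise_sd = 1,
                             tadpole_gain = 0.6,
                             tadpole_floor = 2,
                             seed = 1L) {
  if (any(!is.finite(background_brightness)) ||
      any(background_brightness < 0) || any(background_brightness > 100))
    stop("`background_brightness` must lie in [0, 100]", call. = FALSE)
  assert_scalar_num(replicate_noise_sd, "replicate_noise_sd", lo = 0)
  assert_scalar_num(tadpole_gain, "tadpole_gain")
  assert_scalar_num(tadpole_floor, "tadpole_floor", lo = 0, hi = 100)
  background_kind <- match.arg(background_kind, c("grey", "colour"),
                               several.ok = TRUE)
  if (any(background_kind == "colour")) {
    if (is.null(hue_peak))
      stop("colour backgrounds need `hue_peak`", call. = FALSE)
    if (any(hue_peak < 400 | hue_peak > 700))
      stop("`hue_peak` must lie in [400, 700] nm", call. = FALSE)
    assert_scalar_num(peak_width, "peak_width", lo = 1)
  }
  structure(list(background_kind = background_kind,
                 background_brightness = background_brightness,
                 hue_peak = hue_peak, peak_width = peak_width,
                 replicate_noise_sd = replicate_noise_sd,
                 tadpole_gain = tadpole_gain, tadpole_floor = tadpole_floor,
                 seed = seed),
            class = "spectra_scenario")
}

# noiseless mean reflectance curve of one background on the instrument grid
background_curve <- function(kind, brightness, hue_peak, peak_width,
                             wl = SPEC_GRID_LO:SPEC_GRID_HI) {
  if (kind == "grey") return(rep(brightness, length(wl)))
  shape <- 0.15 + exp(-(wl - hue_peak)^2 / (2 * peak_width^2))
  vis <- wl >= 400 & wl <= 700
  shape * brightness / mean(shape[vis])
}

#' Generate a labelled set of background and tadpole reflectance spectra
#'
#' Emulates the rearing design: `n_backgrounds` containers, each read
#' `n_reps` times, and `n_tadpoles_per_bg` tadpoles per container, each also
#' read `n_reps` times.  Spectra are returned in long format on a 1-nm grid
#' over 360--740 nm, the raw instrument range, so the trimming stage has
#' something to trim.
#'
#' @param scenario A [spectra_scenario()].
#' @param n_backgrounds Number of backgrounds; scenario fields are recycled
#'   to this length.
#' @param n_tadpoles_per_bg Tadpoles reared per background.
#' @param n_reps Replicate readings per specimen (>= 1).
#' @return A `data.frame` with columns `specimen_id`, `role`
#'   (`"tadpole"`/`"background"`), `replicate`, `background_id`,
#'   `wavelength`, `reflectance`, and attribute `truth` holding the
#'   noiseless per-background and per-tadpole B2 values.
#' @export
gen_spectra <- function(scenario,
                        n_backgrounds = length(scenario$background_brightness),
                        n_tadpoles_per_bg = 5, n_reps = 3) {
  stopifnot(inherits(scenario, "spectra_scenario"))
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  kind <- rep_len(scenario$background_kind, n_backgrounds)
  bright <- rep_len(scenario$background_brightness, n_backgrounds)
  hue <- if (is.null(scenario$hue_peak)) rep(NA_real_, n_backgrounds)
         else rep_len(scenario$hue_peak, n_backgrounds)
  wl <- SPEC_GRID_LO:SPEC_GRID_HI
  vis <- wl >= 400 & wl <= 700
  sd_ <- scenario$replicate_noise_sd

  with_seed(scenario$seed, {
    out <- vector("list", n_backgrounds)
    truth <- data.frame(background_id = character(0), bg_b2 = numeric(0),
                        tad_b2 = numeric(0))
    for (i in seq_len(n_backgrounds)) {
      bg_id <- sprintf("bg%02d", i)
      curve <- background_curve(kind[i], bright[i], hue[i],
                                scenario$peak_width, wl)
      bg_b2 <- mean(curve[vis])
      tad_b2 <- clip01(scenario$tadpole_floor + scenario$tadpole_gain * bg_b2,
                       0, 100)
      truth <- rbind(truth, data.frame(background_id = bg_id, bg_b2 = bg_b2,
                                       tad_b2 = tad_b2))
      specs <- list()
      for (r in seq_len(n_reps)) {
        specs[[length(specs) + 1L]] <- data.frame(
          specimen_id = bg_id, role = "background", replicate = r,
          background_id = bg_id, wavelength = wl,
          reflectance = clip01(curve + stats::rnorm(1, 0, sd_) +
                                 stats::rnorm(length(wl), 0, sd_), 0, 100))
      }
      for (j in seq_len(n_tadpoles_per_bg)) {
        tid <- sprintf("%s_tad%02d", bg_id, j)
        for (r in seq_len(n_reps)) {
          specs[[length(specs) + 1L]] <- data.frame(
            specimen_id = tid, role = "tadpole", replicate = r,
            background_id = bg_id, wavelength = wl,
            reflectance = clip01(tad_b2 + stats::rnorm(1, 0, sd_) +
                                   stats::rnorm(length(wl), 0, sd_), 0, 100))
        }
      }
      out[[i]] <- do.call(rbind, specs)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- truth
    res
  })
}

#' Scenario for a quadratic-plateau luma time series
#'
#' The generative twin of the colour-change model: luma follows
#' `y(t) = a + b t - b/(2 xs) t^2` up to the join point `xs` and stays at
#' the plateau `a + b xs / 2` afterwards, plus Gaussian noise.  Defaults are
#' the light-to-dark transition estimates (intercept 0.451 luma, slope
#' -0.057 luma/day, breakpoint 12.673 days) on the observation schedule of
#' the transplant experiment: daily for the first week, then every third or
#' fourth day out to day 60.
#'
#' @param a Luma intercept at t = 0.
#' @param b Initial slope (luma/day).
#' @param xs Join point (days, > 0).
#' @param noise_sd Gaussian noise sd (luma).
#' @param times Observation days, non-negative and strictly increasing.
#' @param seed Integer seed.
#' @export
kinetics_scenario <- function(a = 0.451, b = -0.057, xs = 12.673,
                              noise_sd = 0.02,
                              times = c(0:7, 10, 14, 17, 21, 24, 28, 31, 35,
                                        38, 42, 45, 49, 52, 56, 60),
                              seed = 1L) {
  assert_scalar_num(xs, "xs")
  if (xs <= 0) stop("`xs` must be > 0", call. = FALSE)
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  structure(list(a = a, b = b, xs = xs, noise_sd = noise_sd, times = times,
                 seed = seed),
            class = "kinetics_scenario")
}

# noiseless quadratic-plateau mean function
plateau_mean <- function(t, a, b, xs) {
  ifelse(t <= xs, a + b * t - b / (2 * xs) * t^2, a + b * xs / 2)
}

#' Generate a luma time series from a quadratic-plateau process
#'
#' @param scenario A [kinetics_scenario()].
#' @param individual_id Label attached to the series.
#' @return A `data.frame` with columns `individual_id`, `direction`
#'   (inferred from the sign of the slope), `t` (days) and `luma`, clipped
#'   to `[0, 1]`.
#' @export
gen_luma_series <- function(scenario, individual_id = "sim1") {
  stopifnot(inherits(scenario, "kinetics_scenario"))
  with_seed(scenario$seed, {
    mu <- plateau_mean(scenario$times, scenario$a, scenario$b, scenario$xs)
    y <- clip01(mu + stats::rnorm(length(mu), 0, scenario$noise_sd))
    data.frame(individual_id = individual_id,
               direction = if (scenario$b < 0) "light_to_dark" else "dark_to_light",
               t = scenario$times, luma = y)
  })
}

## ---------------------------------------------------------------------------
## landmarks

#' Template tadpole landmark configuration
#'
#' A stylised lateral tadpole profile in body-length units: 9 fixed
#' landmarks (snout, eye, dorsal body, dorsal and ventral tail-fin
#' insertions, mid-tail dorsal/ventral musculature, tail tip, ventral body)
#' and 13 sliding semilandmarks along the dorsal (7) and ventral (6) fin
#' margins.
#'
#' @return A 22 x 2 coordinate matrix.
#' @export
tadpole_template <- function() {
  fixed <- rbind(
    c(0.00,  0.000),   # 1 snout tip
    c(0.12,  0.060),   # 2 eye
    c(0.28,  0.120),   # 3 dorsal body peak
    c(0.42,  0.100),   # 4 dorsal tail-fin insertion
    c(0.70,  0.050),   # 5 mid-tail dorsal musculature
    c(1.00,  0.000),   # 6 tail tip
    c(0.70, -0.040),   # 7 mid-tail ventral musculature
    c(0.42, -0.090),   # 8 ventral tail-fin insertion
    c(0.18, -0.100))   # 9 ventral body
  xs_d <- seq(0.49, 0.93, length.out = 7)           # dorsal fin margin
  dors <- cbind(xs_d, 0.10 + 0.12 * sin(pi * (xs_d - 0.42) / 0.58))
  xs_v <- seq(0.90, 0.50, length.out = 6)           # ventral fin margin
  vent <- cbind(xs_v, -0.09 - 0.09 * sin(pi * (xs_v - 0.42) / 0.58))
  rbind(fixed, dors, vent)
}

#' Scenario for synthetic landmark configurations
#'
#' Two groups of specimens around a shared template; the "dark" group gets
#' an additive per-landmark displacement (`group_effect`).  The default
#' effect moves the dorsal tail-fin insertion anteriorly and deepens the
#' anterior fin margin, the divergence observed between dark- and
#' light-reared tadpoles.  An optional quadratic bend (`y <- y + c (x -
#' mean(x))^2`) emulates specimen curvature unrelated to treatment.
#'
#' @param template k x 2 landmark matrix (default [tadpole_template()]).
#' @param fixed_idx,semi_idx Disjoint index sets partitioning the rows.
#' @param curve_order List of semilandmark chains, each an ordered index
#'   vector whose endpoints are anchoring fixed landmarks.
#' @param group_effect k x 2 displacement added to the "dark" group.
#' @param landmark_noise_sd Isotropic digitisation noise sd (coordinate
#'   units).
#' @param n_per_group Specimens per group (>= 2).
#' @param bend_coefficient Curvature of the applied quadratic bend.
#' @param seed Integer seed.
#' @export
shape_scenario <- function(template = tadpole_template(),
                           fixed_idx = 1:9, semi_idx = 10:22,
                           curve_order = list(c(4, 10:16, 6), c(6, 17:22, 8)),
                           group_effect = NULL,
                           landmark_noise_sd = 0.005,
                           n_per_group = 5,
                           bend_coefficient = 0,
                           seed = 1L) {
  template <- as.matrix(template)
  k <- nrow(template)
  if (ncol(template) != 2L) stop("`template` must be k x 2", call. = FALSE)
  if (length(intersect(fixed_idx, semi_idx)) ||
      !setequal(union(fixed_idx, semi_idx), seq_len(k)))
    stop("`fixed_idx` and `semi_idx` must be disjoint and cover all landmarks",
         call. = FALSE)
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  assert_scalar_num(landmark_noise_sd, "landmark_noise_sd", lo = 0)
  if (is.null(group_effect)) {
    group_effect <- matrix(0, k, 2)
    group_effect[4, ] <- c(-0.04, 0.010)       # fin insertion more anterior
    group_effect[10:12, 2] <- 0.020            # deeper anterior fin margin
  }
  group_effect <- as.matrix(group_effect)
  if (!all(dim(group_effect) == dim(template)))
    stop("`group_effect` must match the template dimensions", call. = FALSE)
  structure(list(template = template, fixed_idx = fixed_idx,
                 semi_idx = semi_idx, curve_order = curve_order,
                 group_effect = group_effect,
                 landmark_noise_sd = landmark_noise_sd,
                 n_per_group = n_per_group,
                 bend_coefficient = bend_coefficient, seed = seed),
            class = "shape_scenario")
}

apply_bend <- function(coords, coefficient) {
  if (coefficient == 0) return(coords)
  x0 <- mean(coords[, 1])
  coords[, 2] <- coords[, 2] + coefficient * (coords[, 1] - x0)^2
  coords
}

#' Generate landmark configurations for a dark and a light group
#'
#' @param scenario A [shape_scenario()].
#' @return A list of `landmark_config` objects (fields `coords`,
#'   `fixed_idx`, `semi_idx`, `curve_order`, `specimen_id`, `group`).
#' @export
gen_landmarks <- function(scenario) {
  stopifnot(inherits(scenario, "shape_scenario"))
  tmpl <- scenario$template
  k <- nrow(tmpl)
  with_seed(scenario$seed, {
    configs <- list()
    for (grp in c("dark", "light")) {
      base <- tmpl + if (grp == "dark") scenario$group_effect else 0
      for (j in seq_len(scenario$n_per_group)) {
        coords <- base +
          matrix(stats::rnorm(2 * k, 0, scenario$landmark_noise_sd), k, 2)
        coords <- apply_bend(coords, scenario$bend_coefficient)
        configs[[length(configs) + 1L]] <- structure(
          list(coords = coords, fixed_idx = scenario$fixed_idx,
               semi_idx = scenario$semi_idx,
               curve_order = scenario$curve_order,
               specimen_id = sprintf("%s%02d", grp, j), group = grp),
          class = "landmark_config")
      }
    }
    configs
  })
}

## ---------------------------------------------------------------------------
## antioxidant panel

#' Scenario for a synthetic antioxidant panel
#'
#' Seven markers per individual -- the four antioxidant enzymes (SOD, CAT,
#' GR, GPx), the lipid-peroxidation marker MDA, and reduced/oxidised
#' glutathione (GSH, GSSG) -- drawn from group-specific normal
#' distributions.  Defaults reproduce the qualitative dark-vs-light
#' contrast: dark tadpoles with higher GPx and CAT, lower SOD and GR,
#' slightly lower MDA, and a higher GSH/GSSG ratio.
#'
#' @param group_means 7 x 2 matrix (rows SOD, CAT, GR, GPx, MDA, GSH, GSSG;
#'   columns dark, light).
#' @param sd Per-variable sd (length 7).
#' @param n_per_group Individuals per group.
#' @param seed Integer seed.
#' @export
panel_scenario <- function(group_means = NULL, sd = NULL, n_per_group = 6,
                           seed = 1L) {
  vars <- c("SOD", "CAT", "GR", "GPx", "MDA", "GSH", "GSSG")
  if (is.null(group_means)) {
    group_means <- cbind(dark  = c(8, 13, 4.0, 21, 4.4, 30, 8.5),
                         light = c(11, 9, 5.5, 15, 4.8, 25, 10.0))
    rownames(group_means) <- vars
  }
  group_means <- as.matrix(group_means)
  if (!all(dim(group_means) == c(7, 2)))
    stop("`group_means` must be 7 x 2 (SOD, CAT, GR, GPx, MDA, GSH, GSSG)",
         call. = FALSE)
  if (is.null(rownames(group_means))) rownames(group_means) <- vars
  if (is.null(sd)) sd <- 0.15 * rowMeans(group_means)
  if (any(sd < 0)) stop("all `sd` must be >= 0", call. = FALSE)
  if (any(group_means[c("GSH", "GSSG"), ] <= 0))
    stop("GSH and GSSG means must be > 0", call. = FALSE)
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  structure(list(group_means = group_means, sd = sd,
                 n_per_group = n_per_group, seed = seed),
            class = "panel_scenario")
}

#' Generate an antioxidant panel table
#'
#' Enzyme activities and metabolite concentrations are truncated below at a
#' small positive fraction of their mean so that activities stay
#' non-negative and GSH/GSSG ratios are defined.
#'
#' @param scenario A [panel_scenario()].
#' @return A `data.frame` with columns `individual_id`, `group`, `SOD`,
#'   `CAT`, `GR`, `GPx`, `MDA`, `GSH`, `GSSG`.
#' @export
gen_panel <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  m <- scenario$group_means
  with_seed(scenario$seed, {
    rows <- list()
    for (grp in colnames(m)) {
      for (j in seq_len(scenario$n_per_group)) {
        vals <- stats::rnorm(7, m[, grp], scenario$sd)
        vals <- pmax(vals, 0.05 * m[, grp])   # keep activities positive
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("%s%02d", grp, j), group = grp,
          as.list(stats::setNames(vals, rownames(m))))
      }
    }
    do.call(rbind, rows)
  })
}

## ---------------------------------------------------------------------------
## Raman

#' Scenario for a synthetic Raman spectrum
#'
#' Gaussian bands on a smooth polynomial baseline over the analysed
#' wavenumber window 300--2500 cm^-1.  The default band set is the
#' eumelanin profile: strong bands near 1380 and 1580 cm^-1 (the D and G
#' bands of disordered graphite) and a weaker band at 500 cm^-1.
#'
#' @param band_centers Band centres (cm^-1), inside `wavenumber_range`.
#' @param band_amplitudes Band heights (intensity units).
#' @param band_widths Gaussian sds (cm^-1, > 0).
#' @param baseline_poly Polynomial coefficients (intercept first) evaluated
#'   on a unit-scaled wavenumber axis; emulates fluorescence background.
#' @param noise_sd Intensity noise sd.
#' @param wavenumber_range Two-element range (cm^-1).
#' @param step Grid step (cm^-1).
#' @param seed Integer seed.
#' @export
raman_scenario <- function(band_centers = c(500, 1380, 1580),
                           band_amplitudes = c(30, 100, 100),
                           band_widths = c(30, 40, 40),
                           baseline_poly = c(120, -60, 25),
                           noise_sd = 5,
                           wavenumber_range = c(300, 2500),
                           step = 2, seed = 1L) {
  if (length(band_centers)) {
    if (any(band_centers < wavenumber_range[1] |
            band_centers > wavenumber_range[2]))
      stop("`band_centers` must lie inside `wavenumber_range`", call. = FALSE)
    if (any(band_widths <= 0)) stop("`band_widths` must be > 0", call. = FALSE)
    stopifnot(length(band_amplitudes) == length(band_centers),
              length(band_widths) == length(band_centers))
  }
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  structure(list(band_centers = band_centers,
                 band_amplitudes = band_amplitudes,
                 band_widths = band_widths, baseline_poly = baseline_poly,
                 noise_sd = noise_sd, wavenumber_range = wavenumber_range,
                 step = step, seed = seed),
            class = "raman_scenario")
}

#' Generate a Raman spectrum
#'
#' @param scenario A [raman_scenario()].
#' @param specimen_id,replicate Labels attached to the spectrum.
#' @return A `data.frame` with columns `specimen_id`, `replicate`,
#'   `wavenumber`, `intensity`.
#' @export
gen_raman <- function(scenario, specimen_id = "sim1", replicate = 1L) {
  stopifnot(inherits(scenario, "raman_scenario"))
  wn <- seq(scenario$wavenumber_range[1], scenario$wavenumber_range[2],
            by = scenario$step)
  u <- (wn - scenario$wavenumber_range[1]) / diff(scenario$wavenumber_range)
  baseline <- rep(0, length(wn))
  for (p in seq_along(scenario$baseline_poly))
    baseline <- baseline + scenario$baseline_poly[p] * u^(p - 1)
  bands <- rep(0, length(wn))
  for (i in seq_along(scenario$band_centers))
    bands <- bands + scenario$band_amplitudes[i] *
      exp(-(wn - scenario$band_centers[i])^2 / (2 * scenario$band_widths[i]^2))
  with_seed(scenario$seed, {
    data.frame(specimen_id = specimen_id, replicate = replicate,
               wavenumber = wn,
               intensity = baseline + bands +
                 stats::rnorm(length(wn), 0, scenario$noise_sd))
  })
}
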