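## Raman spectroscopy: baseline correction, peak detection, and
## eumelanin/pheomelanin presence calls from diagnostic band positions.
##
## Eumelanin shows the D and G bands of disordered graphite, strong peaks
## near 1380 and 1580 cm^-1 with a weaker corroborating band at 500 cm^-1;
## pheomelanin shows bands near 500, 1490 and 2000 cm^-1.  The 500 cm^-1
## band is shared between the two pigments and never decides a call on its
## own.

EUMELANIN_BANDS <- c(1380, 1580)
PHEOMELANIN_BANDS <- c(1490, 2000)
SHARED_BAND <- 500

#' Baseline-correct a Raman spectrum
#'
#' Estimates the fluorescence background by a morphological opening
#' (rolling minimum followed by rolling maximum over a window of
#' `halfwidth` cm^-1 on each side) smoothed with a rolling mean, and
#' subtracts it.  The opening step makes the estimate track smooth sloped
#' baselines without lag while ignoring bands narrower than the window.
#'
#' @param s `data.frame` with columns `wavenumber` (strictly increasing)
#'   and `intensity`.
#' @param halfwidth Window half-width in cm^-1; must not exceed half the
#'   spectral range, and should be much wider than the grid spacing and the
#'   bands of interest.
#' @return The spectrum with a corrected `intensity` column and the
#'   estimated `baseline` attached as a column.
#' @export
baseline_correct <- function(s, halfwidth = 200) {
  assert_columns(s, c("wavenumber", "intensity"), "Raman spectrum")
  wn <- s$wavenumber
  if (any(diff(wn) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  rng <- max(wn) - min(wn)
  if (halfwidth > rng / 2)
    stop("`halfwidth` exceeds half the spectral range", call. = FALSE)
  step <- stats::median(diff(wn))
  hw <- max(1L, as.integer(round(halfwidth / step)))
  # pad by linear continuation so truncated edge windows do not bias the
  # erosion/dilation on sloped baselines
  y <- pad_linear(s$intensity, hw)
  base <- roll_stat(roll_stat(y, hw, min), hw, max)
  base <- roll_stat(base, hw, mean)
  base <- base[(hw + 1):(hw + length(s$intensity))]
  out <- s
  out$baseline <- base
  out$intensity <- s$intensity - base
  out
}

# rolling statistic with truncated edge windows
roll_stat <- function(y, hw, fun) {
  n <- length(y)
  vapply(seq_len(n), function(i)
    fun(y[max(1, i - hw):min(n, i + hw)]), numeric(1))
}

# extend a signal by hw points on each side, continuing the end slopes
pad_linear <- function(y, hw) {
  n <- length(y)
  k <- min(n, hw + 1L)
  sl <- (y[k] - y[1]) / (k - 1)
  sr <- (y[n] - y[n - k + 1L]) / (k - 1)
  c(y[1] - sl * (hw:1), y, y[n] + sr * seq_len(hw))
}

#' Detect peaks in a baseline-corrected Raman spectrum
#'
#' Lightly smooths the signal (rolling mean over `smooth_halfwidth`
#' points), finds local maxima, and keeps those whose topographic
#' prominence exceeds `min_prominence_snr` times a robust noise scale
#' estimated from the median absolute successive difference of the raw
#' signal (`median(|diff(y)|) / (sqrt(2) * 0.6745)`, the MAD-consistent
#' estimate for white Gaussian noise).  Because the threshold is
#' noise-relative, detection is invariant to intensity rescaling.
#'
#' @param s Baseline-corrected spectrum (`wavenumber`, `intensity`).
#' @param min_prominence_snr Prominence threshold in noise-sd units.
#' @param smooth_halfwidth Rolling-mean half-width in grid points.
#' @return `data.frame` with columns `wavenumber`, `intensity`,
#'   `prominence`, sorted by wavenumber (possibly empty).
#' @export
detect_peaks <- function(s, min_prominence_snr = 5, smooth_halfwidth = 5) {
  assert_columns(s, c("wavenumber", "intensity"), "Raman spectrum")
  y_raw <- s$intensity
  noise <- stats::median(abs(diff(y_raw))) / (sqrt(2) * 0.6745)
  noise <- max(noise, 1e-12 * max(1, max(abs(y_raw))))
  y <- roll_stat(y_raw, smooth_halfwidth, mean)
  n <- length(y)
  is_max <- which(y[-c(1, n)] > y[-c(n - 1, n)] &
                    y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  if (!length(is_max))
    return(data.frame(wavenumber = numeric(0), intensity = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(is_max, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom > min_prominence_snr * noise
  data.frame(wavenumber = s$wavenumber[is_max[keep]],
             intensity = y_raw[is_max[keep]],
             prominence = prom[keep])
}

# topographic prominence: height above the higher of the two key saddles,
# where each saddle is the minimum between the peak and the nearest point
# at least as high (or the spectrum edge)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i == 1) y[1] else {
    j <- i - 1; mn <- y[j]
    while (j >= 1 && y[j] < y[i]) { mn <- min(mn, y[j]); j <- j - 1 }
    mn
  }
  right <- if (i == n) y[n] else {
    j <- i + 1; mn <- y[j]
    while (j <= n && y[j] < y[i]) { mn <- min(mn, y[j]); j <- j + 1 }
    mn
  }
  y[i] - max(left, right)
}

#' Call eumelanin / pheomelanin presence from detected peaks
#'
#' A pigment is called present when BOTH of its strong diagnostic bands are
#' matched by a detected peak within `tolerance`: 1380 and 1580 cm^-1 for
#' eumelanin, 1490 and 2000 cm^-1 for pheomelanin.  The shared 500 cm^-1
#' band is reported when matched but never decides a call, which avoids
#' cross-calling between the two melanins.
#'
#' @param peaks Output of [detect_peaks()] (or a numeric vector of peak
#'   wavenumbers).
#' @param tolerance Band-matching tolerance in cm^-1 (> 0).
#' @return An object of class `"pigment_call"`: logical `eumelanin` and
#'   `pheomelanin`, `matched_peaks` (band, observed peak, prominence,
#'   pigment), `tolerance`.
#' @export
classify_pigment <- function(peaks, tolerance = 40) {
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  if (is.numeric(peaks))
    peaks <- data.frame(wavenumber = peaks,
                        intensity = rep(NA_real_, length(peaks)),
                        prominence = rep(NA_real_, length(peaks)))
  assert_columns(peaks, "wavenumber", "peak table")
  match_band <- function(band) {
    if (!nrow(peaks)) return(NULL)
    d <- abs(peaks$wavenumber - band)
    i <- which.min(d)
    if (d[i] <= tolerance)
      data.frame(band = band, observed = peaks$wavenumber[i],
                 prominence = peaks$prominence[i])
    else NULL
  }
  collect <- function(bands, pigment) {
    hits <- do.call(rbind, lapply(bands, match_band))
    if (!is.null(hits)) hits$pigment <- pigment
    hits
  }
  eu <- collect(EUMELANIN_BANDS, "eumelanin")
  ph <- collect(PHEOMELANIN_BANDS, "pheomelanin")
  sh <- collect(SHARED_BAND, "shared")
  matched <- rbind(eu, ph, sh)
  structure(list(
    eumelanin = !is.null(eu) && nrow(eu) == length(EUMELANIN_BANDS),
    pheomelanin = !is.null(ph) && nrow(ph) == length(PHEOMELANIN_BANDS),
    matched_peaks = if (is.null(matched))
      data.frame(band = numeric(0), observed = numeric(0),
                 prominence = numeric(0), pigment = character(0))
      else matched,
    tolerance = tolerance), class = "pigment_call")
}

#' @export
print.pigment_call <- function(x, ...) {
  cat("Pigment call (tolerance", x$tolerance, "cm^-1):\n")
  cat("  eumelanin:  ", x$eumelanin, "\n")
  cat("  pheomelanin:", x$pheomelanin, "\n")
  if (nrow(x$matched_peaks)) {
    cat("  matched bands:\n")
    print(x$matched_peaks, row.names = FALSE)
  }
  invisible(x)
}

#' Read Raman spectra from CSV
#'
#' @param path CSV with columns `wavenumber`, `intensity`, `specimen_id`,
#'   `replicate`.
#' @return Validated long `data.frame`.
#' @export
read_raman <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("wavenumber", "intensity", "specimen_id", "replicate"),
                 "Raman table")
  if (any(!is.finite(df$intensity)))
    stop("non-finite intensities", call. = FALSE)
  df
}
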