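## Reflectance-spectrum preprocessing and colorimetric indices.
##
## The processing chain mirrors standard spectrophotometry practice for
## animal coloration work: trim to the visible range (400-700 nm), smooth
## with a local quadratic (loess) smoother at span 0.75, bin into 15-nm
## bins, optionally mean-zero normalise, and summarise each spectrum with
## the Montgomerie indices B2 (brightness: mean reflectance), H1 (hue:
## wavelength of maximum reflectance) and S8 (saturation: (max - min) /
## mean).

#' Read reflectance spectra from CSV
#'
#' Expects the long format written by [write_spectra()] and [gen_spectra()]:
#' one row per wavelength reading, with columns `wavelength`, `reflectance`,
#' `specimen_id`, `role` and `replicate`.  Wavelengths must be strictly
#' increasing within each (specimen, replicate) spectrum.
#'
#' @param path CSV file path.
#' @return A validated long `data.frame` of spectra.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_spectra(df)
}

#' @rdname read_spectra
#' @param spectra Long spectra `data.frame`.
#' @export
write_spectra <- function(spectra, path) {
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

validate_spectra <- function(df) {
  assert_columns(df, c("wavelength", "reflectance", "specimen_id", "role",
                       "replicate"), "spectra table")
  if (anyNA(df$wavelength) || anyNA(df$reflectance))
    stop("spectra table contains missing values", call. = FALSE)
  if (!all(df$role %in% c("tadpole", "background")))
    stop("`role` must be 'tadpole' or 'background'", call. = FALSE)
  key <- interaction(df$specimen_id, df$replicate, drop = TRUE)
  for (s in split(df, key)) {
    if (any(diff(s$wavelength) <= 0))
      stop(sprintf(
        "wavelengths not strictly increasing for specimen '%s' replicate %s",
        s$specimen_id[1], s$replicate[1]), call. = FALSE)
  }
  df
}

split_spectra <- function(df) {
  split(df, interaction(df$specimen_id, df$replicate, drop = TRUE))
}

#' Trim and smooth one reflectance spectrum
#'
#' Restricts the spectrum to `[lo, hi]` nm and smooths it with local
#' quadratic regression (loess, tricube weights, direct surface) where each
#' fit uses a neighbourhood of `span * n` points, so polynomials of degree
#' <= 2 are reproduced exactly.  Negative smoothed reflectances are clipped
#' to zero.
#'
#' @param s `data.frame` with columns `wavelength`, `reflectance` (extra
#'   columns are carried through).
#' @param lo,hi Trimming window in nm (defaults: the visible range).
#' @param span Smoothing span as a fraction of points in `(0, 1]`; `NULL`
#'   skips smoothing.
#' @return The processed spectrum, same columns as the input.
#' @export
process_spectrum <- function(s, lo = 400, hi = 700, span = 0.75) {
  assert_columns(s, c("wavelength", "reflectance"), "spectrum")
  if (lo >= hi) stop("`lo` must be < `hi`", call. = FALSE)
  keep <- s$wavelength >= lo & s$wavelength <= hi
  if (sum(keep) < 5)
    stop("fewer than 5 points in the trimming window", call. = FALSE)
  out <- s[keep, , drop = FALSE]
  if (!is.null(span)) {
    if (span <= 0 || span > 1) stop("`span` must be in (0, 1]", call. = FALSE)
    fit <- stats::loess(reflectance ~ wavelength, data = out, span = span,
                        degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    out$reflectance <- pmax(0, stats::fitted(fit))
  }
  rownames(out) <- NULL
  out
}

#' Bin a trimmed spectrum into fixed-width wavelength bins
#'
#' Bins are `[lo, lo+width), ..., [hi-width, hi]` with the last bin closed;
#' each bin value is the arithmetic mean of the reflectances falling in it.
#' The width must tile `[lo, hi]` exactly (no partial final bin).
#'
#' @inheritParams process_spectrum
#' @param width Bin width in nm (default 15, giving 20 bins over 400--700).
#' @return A named numeric vector of bin means (names = bin start
#'   wavelengths), with attributes `width`, `lo`, `hi`.
#' @export
bin_spectrum <- function(s, width = 15, lo = 400, hi = 700) {
  assert_columns(s, c("wavelength", "reflectance"), "spectrum")
  span_nm <- hi - lo
  nbin <- span_nm / width
  if (abs(nbin - round(nbin)) > 1e-9)
    stop(sprintf("bin width %s does not tile [%s, %s] exactly",
                 width, lo, hi), call. = FALSE)
  nbin <- as.integer(round(nbin))
  w <- s$wavelength
  if (min(w) > lo || max(w) < hi)
    stop("spectrum does not cover the binning range", call. = FALSE)
  keep <- w >= lo & w <= hi
  idx <- pmin(floor((w[keep] - lo) / width), nbin - 1L) + 1L
  counts <- tabulate(idx, nbin)
  if (any(counts == 0)) stop("empty wavelength bin", call. = FALSE)
  vals <- as.numeric(tapply(s$reflectance[keep], idx, mean))
  names(vals) <- lo + width * (seq_len(nbin) - 1L)
  structure(vals, width = width, lo = lo, hi = hi)
}

#' Mean-zero normalise a binned spectrum
#'
#' Subtracts the mean bin value, so differences attributable to overall
#' brightness are removed and only spectral shape remains.
#'
#' @param b Numeric vector of bin values (e.g. from [bin_spectrum()]).
#' @return The centred vector (mean exactly 0), attributes preserved.
#' @export
normalize_mean_zero <- function(b) {
  out <- b - mean(b)
  attributes(out) <- attributes(b)
  out
}

#' Colorimetric summary indices of a processed spectrum
#'
#' Computes brightness `B2` (mean reflectance, %), hue `H1` (wavelength of
#' maximum reflectance, nm; smallest wavelength on ties) and saturation
#' `S8` ((max - min) / mean, unitless).  Flat spectra -- spectral contrast
#' below `flat_tol` -- carry unreliable H1/S8, which `flat_flag` records;
#' when the mean reflectance is zero, S8 is undefined and returned as `NA`.
#'
#' @inheritParams process_spectrum
#' @param flat_tol Contrast threshold below which a spectrum is flagged
#'   flat.
#' @return A list of class `"color_indices"` with fields `B2`, `H1`, `S8`,
#'   `flat_flag`.
#' @export
color_indices <- function(s, flat_tol = 0.05) {
  assert_columns(s, c("wavelength", "reflectance"), "spectrum")
  r <- s$reflectance
  b2 <- mean(r)
  h1 <- s$wavelength[which.max(r)]          # which.max takes the first tie
  if (b2 <= 0) {
    s8 <- NA_real_
    flat <- TRUE
  } else {
    s8 <- (max(r) - min(r)) / b2
    flat <- s8 < flat_tol
  }
  structure(list(B2 = b2, H1 = h1, S8 = s8, flat_flag = flat),
            class = "color_indices")
}

#' Ordinary least-squares regression of tadpole index on background index
#'
#' Direct normal-equation OLS with the standard overall F test, used for the
#' per-treatment index regressions (tadpole B2/H1/S8 against the matching
#' background index).  Reports the adjusted R^2 `1 - (1 - R^2)(n-1)/(n-2)`
#' and F on (1, n-2) degrees of freedom.
#'
#' @param x Predictor (background index per treatment).
#' @param y Response (tadpole index per treatment).
#' @return List with `slope`, `intercept`, `adj_R2`, `F`, `df`, `p`.
#' @export
regress_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in predictor", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fittedv <- intercept + slope * x
  sse <- sum((y - fittedv)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  fstat <- if (sse == 0) Inf else (sst - sse) / (sse / (n - 2))
  p <- if (is.infinite(fstat)) 0 else stats::pf(fstat, 1, n - 2,
                                                lower.tail = FALSE)
  list(slope = slope, intercept = intercept, adj_R2 = adj, F = fstat,
       df = c(1L, n - 2L), p = p)
}

#' Build the specimen-by-bin matrix for colour-space analysis
#'
#' Processes every replicate spectrum (trim + smooth), bins it, and averages
#' the replicate bin vectors per specimen, yielding one row per specimen.
#' Replicates are smoothed individually and averaged afterwards.
#'
#' @param spectra Long spectra `data.frame` (see [read_spectra()]).
#' @param lo,hi,span,width Passed to [process_spectrum()] and
#'   [bin_spectrum()].
#' @param normalized Mean-zero normalise each specimen vector.
#' @return Matrix (specimens x bins) with rownames = specimen ids and
#'   attributes `role` and `background_id` (per row, when present in the
#'   input).
#' @export
bin_matrix <- function(spectra, lo = 400, hi = 700, span = 0.75, width = 15,
                       normalized = FALSE) {
  validate_spectra(spectra)
  reps <- split_spectra(spectra)
  binned <- lapply(reps, function(s) {
    v <- bin_spectrum(process_spectrum(s, lo, hi, span), width, lo, hi)
    list(specimen_id = s$specimen_id[1], role = s$role[1],
         background_id = if ("background_id" %in% names(s))
           s$background_id[1] else NA_character_,
         bins = v)
  })
  ids <- vapply(binned, `[[`, "", "specimen_id")
  mat <- t(vapply(binned, function(b) as.numeric(b$bins),
                  numeric(length(binned[[1]]$bins))))
  # rowsum orders rows by sort(unique(ids)); average the replicate vectors
  agg <- rowsum(mat, ids)
  cnt <- as.vector(table(ids)[rownames(agg)])
  agg <- agg / cnt
  meta_idx <- match(rownames(agg), ids)
  if (normalized) agg <- agg - rowMeans(agg)
  colnames(agg) <- names(binned[[1]]$bins)
  attr(agg, "role") <- vapply(binned[meta_idx], `[[`, "", "role")
  attr(agg, "background_id") <- vapply(binned[meta_idx], `[[`, "",
                                       "background_id")
  agg
}
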