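## Colour-change kinetics: luma conversion and the quadratic-plateau model.
##
## The model is the standard three-parameter quadratic-plateau form used in
## segmented regression: y(t) = a + b t + c t^2 up to a join point xs, and
## constant afterwards, with the quadratic coefficient tied to
## c = -b / (2 xs) so the two pieces join with zero slope.  At fixed xs the
## model is linear in (a, b), so fitting profiles the residual sum of
## squares over xs with an exact linear solve inside -- a global,
## deterministic alternative to joint 3-parameter nonlinear search.

#' Relative luminance (luma) from mean RGB channels
#'
#' Rec. 709 luma weights: `0.2126 R + 0.7152 G + 0.0722 B`.  Channels are
#' expected in `[0, 1]`; 8-bit values in `(1, 255]` are divided by 255 with
#' a notice.
#'
#' @param r,g,b Mean channel values (vectorised).
#' @return Luma in `[0, 1]`.
#' @export
luma_from_rgb <- function(r, g, b) {
  ch <- cbind(r, g, b)
  if (any(ch < 0)) stop("negative channel value", call. = FALSE)
  if (any(ch > 1)) {
    if (any(ch > 255)) stop("channel values above 255", call. = FALSE)
    message("channel values above 1 detected; assuming 8-bit scale, dividing by 255")
    ch <- ch / 255
  }
  as.numeric(ch %*% c(0.2126, 0.7152, 0.0722))
}

# design column shared by the profile solve: t - t^2/(2 xs) before the join
# point, xs/2 after (the derivative of the plateau piece is zero)
plateau_design <- function(t, xs) {
  ifelse(t <= xs, t - t^2 / (2 * xs), xs / 2)
}

#' Exact least squares for (a, b) at a fixed join point
#'
#' With the quadratic coefficient tied to `-b/(2 xs)`, the quadratic-plateau
#' model is linear in the intercept `a` and slope `b` at fixed `xs`.  This
#' solves that 2-parameter least-squares problem in closed form and returns
#' the minimised residual sum of squares -- the profile objective that
#' [fit_quadratic_plateau()] minimises over `xs`.
#'
#' @param series `data.frame` with columns `t` and `luma`.
#' @param xs Candidate join point (days).
#' @return List with `a`, `b`, `rss`.
#' @export
profile_rss <- function(series, xs) {
  assert_columns(series, c("t", "luma"), "luma series")
  t <- series$t; y <- series$luma
  z <- plateau_design(t, xs)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  if (szz < 1e-12 * max(1, mean(z)^2) * length(t))
    stop("singular design at this join point (no usable curvature)",
         call. = FALSE)
  b <- sum(zc * (y - mean(y))) / szz
  a <- mean(y) - b * mean(z)
  rss <- sum((y - a - b * z)^2)
  list(a = a, b = b, rss = rss)
}

#' Fit the quadratic-plateau colour-change model
#'
#' Profiles the residual sum of squares over the join point `xs`: a coarse
#' pass over the observed time points in `(t_(2), max(t)]`, then bounded
#' one-dimensional refinement around the best candidate.  If the optimum
#' sits at the last observation the plateau was not reached within the
#' observation window and the fit is flagged (`boundary = TRUE`); the
#' breakpoint of a slow transition can genuinely lie beyond the experiment.
#' With `allow_extrapolation = TRUE` the search extends past the last
#' observation (up to `5 * max(t)`), which lets such a breakpoint be
#' estimated instead of flagged.
#'
#' @param series `data.frame` with columns `t` (days) and `luma`; at least
#'   4 observations.
#' @param allow_extrapolation Permit a join point beyond the last
#'   observation.
#' @return An object of class `"plateau_fit"`: `a` (intercept), `b`
#'   (initial slope, luma/day), `xs` (join point, days), `plateau`
#'   (`a + b xs / 2`), `rss`, `n`, `converged`, `boundary`.
#' @export
fit_quadratic_plateau <- function(series, allow_extrapolation = FALSE) {
  assert_columns(series, c("t", "luma"), "luma series")
  series <- series[order(series$t), , drop = FALSE]
  t <- series$t; y <- series$luma
  n <- length(t)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  tu <- sort(unique(t))
  if (stats::var(y) == 0) {
    return(structure(list(a = y[1], b = 0, xs = NA_real_, plateau = y[1],
                          rss = 0, n = n, converged = FALSE,
                          boundary = FALSE),
                     class = "plateau_fit"))
  }
  lo <- tu[2]; hi <- if (allow_extrapolation) 5 * max(tu) else max(tu)
  cand <- tu[tu > lo]
  if (allow_extrapolation)
    cand <- c(cand, seq(max(tu), hi, length.out = 60)[-1])
  if (!length(cand))
    stop("too few distinct time points to search for a join point",
         call. = FALSE)
  obj <- function(xs) profile_rss(series, xs)$rss
  rss_cand <- vapply(cand, obj, numeric(1))
  i <- which.min(rss_cand)
  left <- if (i == 1) lo + 1e-8 else cand[i - 1]
  right <- if (i == length(cand)) hi else cand[i + 1]
  opt <- stats::optimize(obj, lower = left, upper = right, tol = 1e-9)
  # optimize() never returns the exact endpoints; check them explicitly
  xs_hat <- opt$minimum
  best <- opt$objective
  if (obj(hi) <= best) {
    xs_hat <- hi
    best <- obj(hi)
  }
  sol <- profile_rss(series, xs_hat)
  structure(list(a = sol$a, b = sol$b, xs = xs_hat,
                 plateau = sol$a + sol$b * xs_hat / 2, rss = sol$rss,
                 n = n, converged = TRUE,
                 boundary = abs(xs_hat - hi) < 1e-6),
            class = "plateau_fit")
}

#' Predict luma from a fitted quadratic-plateau model
#'
#' @param object A `"plateau_fit"`.
#' @param t Days (>= 0).
#' @param ... Unused.
#' @return Predicted luma; continuous with zero slope at the join point.
#' @export
predict.plateau_fit <- function(object, t, ...) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (is.na(object$xs)) return(rep(object$a, length(t)))
  plateau_mean(t, object$a, object$b, object$xs)
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("Quadratic-plateau fit (n =", x$n, ")\n")
  cat(sprintf("  intercept a  = %.4f luma\n", x$a))
  cat(sprintf("  slope b      = %.4f luma/day\n", x$b))
  cat(sprintf("  join point   = %.3f days%s\n", x$xs,
              if (isTRUE(x$boundary)) " [at window boundary]" else ""))
  cat(sprintf("  plateau      = %.4f luma\n", x$plateau))
  cat(sprintf("  rss          = %.3g\n", x$rss))
  invisible(x)
}

#' Brute-force grid oracle for the quadratic-plateau join point
#'
#' Evaluates the profile residual sum of squares on a dense uniform grid of
#' candidate join points and returns the best.  Used to verify the fitter's
#' optimum independently; not meant for routine fitting.
#'
#' @inheritParams fit_quadratic_plateau
#' @param step Grid step in days.
#' @return List with `xs`, `rss`, `a`, `b`.
#' @export
plateau_grid_oracle <- function(series, step = 0.001) {
  series <- series[order(series$t), , drop = FALSE]
  tu <- sort(unique(series$t))
  grid <- seq(tu[2] + step, max(tu), by = step)
  z <- outer(series$t, grid, plateau_design)     # n x G design columns
  y <- series$luma
  zm <- colMeans(z)
  zc <- sweep(z, 2, zm)
  szz <- colSums(zc^2)
  b <- colSums(zc * (y - mean(y))) / szz
  a <- mean(y) - b * zm
  rss <- colSums((y - sweep(sweep(z, 2, b, "*"), 2, -a))^2)
  i <- which.min(rss)
  list(xs = grid[i], rss = rss[i], a = a[i], b = b[i])
}

#' Read a luma series table from CSV
#'
#' Input columns: `individual_id`, `day`, `mean_red`, `mean_green`,
#' `mean_blue` (0--1 or 0--255).  Channels are converted to luma.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `individual_id`, `t`, `luma`.
#' @export
read_luma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("individual_id", "day", "mean_red", "mean_green",
                       "mean_blue"), "luma table")
  data.frame(individual_id = df$individual_id, t = df$day,
             luma = luma_from_rgb(df$mean_red, df$mean_green, df$mean_blue))
}
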