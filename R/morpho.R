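## 2D geometric morphometrics: TPS I/O, quadratic unbending, generalized
## Procrustes analysis with sliding semilandmarks, shape PCA, and
## permutation Procrustes ANOVA with residual randomization.

#' Read / write landmark configurations in TPS format
#'
#' Minimal TPS dialect: `LM=k` followed by k `x y` coordinate lines, an
#' optional `SCALE=` line and an `ID=` line per record.
#'
#' @param path File path.
#' @return `read_tps()`: a list of `landmark_config` objects (fields
#'   `coords`, `specimen_id`, `scale`).  Slider information (`fixed_idx`,
#'   `semi_idx`, `curve_order`) is not part of TPS and is attached
#'   separately (see [set_sliders()]).
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop(sprintf("TPS record %d: expected 'LM=' at line %d", rec, i),
           call. = FALSE)
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1)
      stop(sprintf("TPS record %d: bad LM count", rec), call. = FALSE)
    if (i + k > length(lines))
      stop(sprintf("TPS record %d: truncated (expected %d coordinate lines)",
                   rec, k), call. = FALSE)
    coord_lines <- lines[(i + 1L):(i + k)]
    parsed <- lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 2 || anyNA(v)) NULL else v
    })
    if (any(vapply(parsed, is.null, logical(1))))
      stop(sprintf("TPS record %d: LM count disagrees with coordinate lines",
                   rec), call. = FALSE)
    coords <- do.call(rbind, parsed)
    i <- i + k + 1L
    scale <- NA_real_
    id <- sprintf("record%d", rec)
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i],
                                        ignore.case = TRUE)) {
      if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                                ignore.case = TRUE))
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    configs[[length(configs) + 1L]] <- structure(
      list(coords = coords, specimen_id = id, scale = scale),
      class = "landmark_config")
  }
  configs
}

#' @rdname read_tps
#' @param configs List of `landmark_config` objects.
#' @export
write_tps <- function(configs, path) {
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$coords)),
      apply(cf$coords, 1, function(p) sprintf("%.10g %.10g", p[1], p[2])),
      if (!is.null(cf$scale) && !is.na(cf$scale))
        sprintf("SCALE=%.10g", cf$scale),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Attach slider definitions to landmark configurations
#'
#' @param configs List of `landmark_config` objects.
#' @param fixed_idx,semi_idx Disjoint index sets partitioning the
#'   landmarks.
#' @param curve_order List of ordered index chains (anchors at the ends).
#' @return The configs with slider fields set.
#' @export
set_sliders <- function(configs, fixed_idx, semi_idx, curve_order) {
  lapply(configs, function(cf) {
    cf$fixed_idx <- fixed_idx
    cf$semi_idx <- semi_idx
    cf$curve_order <- curve_order
    cf
  })
}

config_coords <- function(cf) {
  if (inherits(cf, "landmark_config")) cf$coords else as.matrix(cf)
}

## ---------------------------------------------------------------------------
## unbending

# signed arc length of y = q0 + q1 x + q2 x^2 from x0 to x1
quad_arclength <- function(q, x0, x1) {
  f <- function(x) sqrt(1 + (q[2] + 2 * q[3] * x)^2)
  vapply(x1, function(xx) stats::integrate(f, x0, xx,
                                           rel.tol = 1e-10)$value,
         numeric(1))
}

#' Remove specimen bending by straightening a fitted quadratic axis
#'
#' Fits `y = q0 + q1 x + q2 x^2` to the axis landmarks by least squares,
#' re-expresses every landmark as (arc length along the curve, signed
#' normal offset), and lays those coordinates out along a straight axis.
#' Axis landmarks therefore end up collinear up to their residual fit
#' error.  Removes curvature of the preserved specimen (e.g. a flexed
#' tail) that is unrelated to treatment.
#'
#' @param config `landmark_config` (or bare k x 2 matrix).
#' @param axis_idx Ordered indices of the landmarks defining the body axis
#'   (>= 3).
#' @return The config with unbent coordinates.
#' @export
unbend <- function(config, axis_idx) {
  coords <- config_coords(config)
  if (length(axis_idx) < 3)
    stop("need at least 3 axis landmarks", call. = FALSE)
  ax <- coords[axis_idx, , drop = FALSE]
  if (stats::sd(ax[, 1]) < 1e-9 * max(1, mean(abs(ax))))
    stop("degenerate axis: x coordinates not spread", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ax[, 1], ax[, 1]^2), ax[, 2])
  q <- fit$coefficients
  xr <- range(coords[, 1])
  pad <- diff(xr) * 0.5 + 1e-6
  # foot of each landmark on the curve: dense grid + local refinement
  foot_x <- vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[i, ]
    d2 <- function(x) (x - p[1])^2 + (q[1] + q[2] * x + q[3] * x^2 - p[2])^2
    grid <- seq(xr[1] - pad, xr[2] + pad, length.out = 400)
    g <- grid[which.min(vapply(grid, d2, numeric(1)))]
    h <- diff(grid[1:2])
    stats::optimize(d2, lower = g - h, upper = g + h)$minimum
  }, numeric(1))
  x0 <- foot_x[match(axis_idx[1], seq_len(nrow(coords)))]
  s <- quad_arclength(q, x0, foot_x)
  fy <- q[1] + q[2] * foot_x + q[3] * foot_x^2
  tang <- cbind(1, q[2] + 2 * q[3] * foot_x)
  tang <- tang / sqrt(rowSums(tang^2))
  dvec <- coords - cbind(foot_x, fy)
  # signed offset: positive on the left of the tangent direction
  off <- dvec[, 2] * tang[, 1] - dvec[, 1] * tang[, 2]
  new_coords <- cbind(coords[axis_idx[1], 1] + s,
                      mean(fy[axis_idx]) + off)
  if (inherits(config, "landmark_config")) {
    config$coords <- new_coords
    config
  } else new_coords
}

## ---------------------------------------------------------------------------
## GPA

center_scale <- function(coords) {
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  cs <- sqrt(sum(cc^2))
  list(coords = cc / cs, size = cs)
}

# optimal rotation (no reflection) aligning A onto B: minimises ||A R - B||_F
optimal_rotation <- function(A, B) {
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

# thin-plate-spline bending energy matrix of a 2D reference configuration
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  r2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(r2 == 0, 0, r2 * log(r2))
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Li <- solve(L)
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

# unit tangent directions for semilandmarks: central difference of chain
# neighbours; chain endpoints are anchors and never slide
semi_tangents <- function(coords, semi_idx, curve_order) {
  tang <- matrix(NA_real_, length(semi_idx), 2)
  for (chain in curve_order) {
    for (pos in seq_along(chain)) {
      lm <- chain[pos]
      m <- match(lm, semi_idx)
      if (is.na(m)) next
      prev <- chain[max(1, pos - 1)]
      nxt <- chain[min(length(chain), pos + 1)]
      v <- coords[nxt, ] - coords[prev, ]
      tang[m, ] <- v / sqrt(sum(v^2))
    }
  }
  if (anyNA(tang))
    stop("every semilandmark needs neighbours on a curve chain", call. = FALSE)
  tang
}

# slide semilandmarks of one aligned config toward the reference, minimising
# bending energy (against the reference's TPS bending-energy matrix) or
# Procrustes distance; returns the updated coordinates
slide_config <- function(coords, ref, semi_idx, curve_order, criterion, Be) {
  U <- semi_tangents(coords, semi_idx, curve_order)
  V <- coords - ref
  k <- nrow(coords)
  m <- length(semi_idx)
  if (criterion == "procrustes_distance") {
    tpar <- -rowSums(U * V[semi_idx, , drop = FALSE])
  } else {
    Ux <- matrix(0, k, m); Uy <- matrix(0, k, m)
    Ux[cbind(semi_idx, seq_len(m))] <- U[, 1]
    Uy[cbind(semi_idx, seq_len(m))] <- U[, 2]
    Aq <- crossprod(Ux, Be %*% Ux) + crossprod(Uy, Be %*% Uy)
    bq <- crossprod(Ux, Be %*% V[, 1]) + crossprod(Uy, Be %*% V[, 2])
    tpar <- -solve(Aq + diag(1e-10, m), bq)[, 1]
  }
  coords[semi_idx, ] <- coords[semi_idx, ] + U * tpar
  coords
}

gpa_criterion <- function(coords, ref, criterion, Be) {
  V <- coords - ref
  if (criterion == "procrustes_distance") sum(V^2)
  else sum(V[, 1] * (Be %*% V[, 1])) + sum(V[, 2] * (Be %*% V[, 2]))
}

#' Generalized Procrustes analysis with optional sliding semilandmarks
#'
#' Iteratively translates every configuration to the origin, scales it to
#' unit centroid size, rotates it onto the current consensus by the
#' least-squares criterion (SVD, reflections disallowed), and updates the
#' consensus until it stabilises.  With `slide = TRUE`, semilandmarks slide
#' along their local tangent (central difference of curve neighbours) each
#' outer iteration to minimise either the thin-plate-spline bending energy
#' against the consensus or the Procrustes distance.
#'
#' @param configs List of `landmark_config` objects (or k x 2 matrices), all
#'   with the same landmark count.  Sliding requires slider fields (see
#'   [set_sliders()]).
#' @param slide Slide semilandmarks.
#' @param criterion `"bending_energy"` (default) or
#'   `"procrustes_distance"`.
#' @param tol Convergence tolerance on the consensus change.
#' @param max_iter Maximum outer iterations.
#' @return An object of class `"gpa_fit"`: `aligned` (n x k x 2 array),
#'   `mean_shape`, `centroid_sizes`, `iterations`, `converged`, `slid`,
#'   and (when sliding) `criterion_trace`, a matrix with the total sliding
#'   criterion before and after each iteration's slide step; within an
#'   iteration (fixed consensus) the slide never increases the criterion.
#' @export
gpa <- function(configs, slide = FALSE,
                criterion = c("bending_energy", "procrustes_distance"),
                tol = 1e-8, max_iter = 100) {
  criterion <- match.arg(criterion)
  n <- length(configs)
  if (n < 2) stop("need at least 2 configurations", call. = FALSE)
  mats <- lapply(configs, config_coords)
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != k))
    stop("configurations differ in landmark count", call. = FALSE)
  semi_idx <- if (inherits(configs[[1]], "landmark_config"))
    configs[[1]]$semi_idx else NULL
  curve_order <- if (inherits(configs[[1]], "landmark_config"))
    configs[[1]]$curve_order else NULL
  if (slide && (is.null(semi_idx) || is.null(curve_order)))
    stop("sliding requires `semi_idx` and `curve_order` on the configs",
         call. = FALSE)

  cs <- lapply(mats, center_scale)
  sizes <- vapply(cs, `[[`, numeric(1), "size")
  A <- lapply(cs, `[[`, "coords")
  ref <- A[[1]]
  converged <- FALSE
  iter <- 0L
  crit_trace <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- lapply(A, function(a) a %*% optimal_rotation(a, ref))
    if (slide) {
      Be <- if (criterion == "bending_energy") bending_energy_matrix(ref)
            else NULL
      total_crit <- function(configs) sum(vapply(configs, gpa_criterion,
                                                 numeric(1), ref = ref,
                                                 criterion = criterion,
                                                 Be = Be))
      before <- total_crit(A)
      A <- lapply(A, function(a)
        slide_config(a, ref, semi_idx, curve_order, criterion, Be))
      after <- total_crit(A)
      crit_trace <- rbind(crit_trace, c(before = before, after = after))
      # sliding moves points off the unit-size sphere; re-normalise
      A <- lapply(A, function(a) center_scale(a)$coords)
      A <- lapply(A, function(a) a %*% optimal_rotation(a, ref))
    }
    new_ref <- center_scale(Reduce(`+`, A) / n)$coords
    delta <- sqrt(sum((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol) { converged <- TRUE; break }
    # with sliding, the consensus keeps adjusting indefinitely at a tiny
    # rate (semilandmarks can crawl along their curves chasing the moving
    # consensus); declare convergence once an iteration improves the
    # criterion by less than 0.1% relative
    if (slide && iter >= 2) {
      prev <- crit_trace[iter - 1L, "after"]
      cur <- crit_trace[iter, "after"]
      if (prev - cur < 1e-3 * max(cur, 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  aligned <- array(NA_real_, c(n, k, 2))
  for (i in seq_len(n)) aligned[i, , ] <- A[[i]] %*% optimal_rotation(A[[i]], ref)
  ids <- vapply(seq_len(n), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config") && !is.null(cf$specimen_id))
      cf$specimen_id else sprintf("spec%02d", i)
  }, character(1))
  dimnames(aligned) <- list(ids, NULL, c("x", "y"))
  structure(list(aligned = aligned, mean_shape = ref,
                 centroid_sizes = stats::setNames(sizes, ids),
                 iterations = iter, converged = converged, slid = slide,
                 criterion_trace = if (slide) crit_trace else NULL),
            class = "gpa_fit")
}

# flatten an n x k x 2 array to n x 2k
flatten_shapes <- function(aligned) {
  n <- dim(aligned)[1]
  matrix(aligned, n, dim(aligned)[2] * 2,
         dimnames = list(dimnames(aligned)[[1]], NULL))
}

#' PCA of Procrustes-aligned shape coordinates
#'
#' @param result A `"gpa_fit"`.
#' @return A [fit_pca()] model of the flattened aligned coordinates
#'   (centred, unscaled).
#' @export
shape_pca <- function(result) {
  stopifnot(inherits(result, "gpa_fit"))
  fit_pca(flatten_shapes(result$aligned), center = TRUE, scale. = FALSE)
}

#' Procrustes ANOVA with residual randomization
#'
#' Decomposes the total sum of squared deviations of the flattened aligned
#' coordinates around the grand mean into between- and within-group parts,
#' forms `F = (SSB / df_b) / (SSW / df_w)` with specimen-level degrees of
#' freedom, and assesses significance by permuting the residuals of the
#' reduced (grand-mean) model `n_perm` times.  `p` uses the +1 correction
#' (the observed statistic counts as one permutation); the effect size `Z`
#' is the observed F in standard deviates of the permutation distribution.
#'
#' @param result A `"gpa_fit"` (or an n x p matrix of shape variables).
#' @param groups Factor of group labels, length n; every group needs >= 2
#'   specimens.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for reproducible permutations.
#' @return An object of class `"procrustes_anova"` with fields `F`, `Z`,
#'   `p`, `df`, `ss` (between/within/total), `n_perm`, `seed`.
#' @export
procrustes_anova <- function(result, groups, n_perm = 1000, seed = NULL) {
  Y <- if (inherits(result, "gpa_fit")) flatten_shapes(result$aligned)
       else as.matrix(result)
  groups <- factor(groups)
  n <- nrow(Y)
  if (length(groups) != n)
    stop("`groups` must match the number of specimens", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 specimens", call. = FALSE)
  grand <- colMeans(Y)
  R <- sweep(Y, 2, grand)        # residuals of the reduced model
  ss_total <- sum(R^2)
  f_stat <- function(res) {
    ssb <- 0
    for (g in levels(groups)) {
      idx <- which(groups == g)
      ssb <- ssb + length(idx) * sum(colMeans(res[idx, , drop = FALSE])^2)
    }
    ssw <- sum(res^2) - ssb
    (ssb / (nlevels(groups) - 1)) / (ssw / (n - nlevels(groups)))
  }
  F_obs <- f_stat(R)
  ssb_obs <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ssb_obs <- ssb_obs + length(idx) * sum(colMeans(R[idx, , drop = FALSE])^2)
  }
  F_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(R[sample.int(n), , drop = FALSE]), numeric(1)))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  Z <- (F_obs - mean(F_perm)) / stats::sd(F_perm)
  structure(list(F = F_obs, Z = Z, p = p,
                 df = c(between = nlevels(groups) - 1L,
                        within = n - nlevels(groups)),
                 ss = c(between = ssb_obs, within = ss_total - ssb_obs,
                        total = ss_total),
                 n_perm = n_perm, seed = seed),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (", x$n_perm, "permutations, residual randomization)\n")
  cat(sprintf("  F = %.3f, Z = %.3f, Df = %d,%d, p = %.4g\n",
              x$F, x$Z, x$df[1], x$df[2], x$p))
  invisible(x)
}
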