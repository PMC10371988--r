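## PCA colour space and the tadpole-background mismatch statistic.

#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around the singular value decomposition of the (optionally
#' centred and scaled) data matrix.  Deterministic sign convention: the
#' largest-magnitude element of each loading column is positive.  Variance
#' explained is computed from the singular values over all components, so
#' it sums to one.
#'
#' @param x Numeric matrix, samples x variables.
#' @param center,scale. Centre / unit-variance scale the columns.
#' @return An object of class `"pca_model"`: `loadings` (variables x
#'   components, orthonormal columns), `scores` (samples x components),
#'   `variance_explained`, `center`, `scale`, `sdev`.
#' @export
fit_pca <- function(x, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  if (anyNA(x)) stop("missing values in PCA input", call. = FALSE)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, ctr)
  scl <- rep(1, ncol(x))
  if (scale.) {
    scl <- apply(xc, 2, stats::sd)
    if (any(scl == 0))
      stop("cannot scale a zero-variance variable", call. = FALSE)
    xc <- sweep(xc, 2, scl, "/")
  }
  sv <- svd(xc)
  tot <- sum(sv$d^2)
  if (tot < .Machine$double.eps * nrow(x) * ncol(x))
    stop("matrix has no variance; PCA undefined", call. = FALSE)
  # sign convention: largest |loading| per component positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- xc %*% loadings
  ncomp <- ncol(loadings)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = sv$d^2 / tot,
                 center = ctr, scale = scl,
                 sdev = sv$d / sqrt(max(1, nrow(x) - 1))),
            class = "pca_model")
}

#' Project new rows into an existing PCA model
#'
#' @param model A [fit_pca()] model.
#' @param newdata Matrix with the same variables as the training data.
#' @return Score matrix (rows x components).
#' @export
project_pca <- function(model, newdata) {
  stopifnot(inherits(model, "pca_model"))
  newdata <- as.matrix(newdata)
  xc <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  xc %*% model$loadings
}

#' Tadpole-background mismatch distances in PCA colour space
#'
#' Euclidean distance between each tadpole and its rearing background in
#' the full PCA score space.  Because all components are retained and
#' loadings are orthonormal, this equals the Euclidean distance between the
#' centred (and, if the model was scaled, scaled) bin vectors; larger
#' distances mean poorer background matching.  The background position is
#' the per-container mean spectrum (one row per container in `x`).
#'
#' @param model [fit_pca()] model fitted on the combined tadpole +
#'   background rows.
#' @param pairing `data.frame` with columns `specimen_id`, `background_id`;
#'   both must be rownames of the model's score matrix.
#' @return `data.frame` with columns `specimen_id`, `background_id`,
#'   `distance`.
#' @export
mismatch <- function(model, pairing) {
  stopifnot(inherits(model, "pca_model"))
  assert_columns(pairing, c("specimen_id", "background_id"), "pairing")
  sc <- model$scores
  miss <- setdiff(unique(c(pairing$specimen_id, pairing$background_id)),
                  rownames(sc))
  if (length(miss))
    stop(sprintf("pairing references unknown specimen(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  d <- sqrt(rowSums((sc[pairing$specimen_id, , drop = FALSE] -
                       sc[pairing$background_id, , drop = FALSE])^2))
  data.frame(specimen_id = pairing$specimen_id,
             background_id = pairing$background_id,
             distance = as.numeric(d))
}

#' Full colour-space mismatch analysis of a spectra set
#'
#' Convenience wrapper: builds the specimen-by-bin matrix (tadpole specimen
#' means and background container means together), fits the PCA on the
#' combined set, and returns per-tadpole mismatch distances.
#'
#' @param spectra Long spectra `data.frame` with a `background_id` column
#'   (as produced by [gen_spectra()]).
#' @param normalized Use mean-zero-normalised spectra (shape-only space).
#' @param ... Passed to [bin_matrix()].
#' @return List with `model` (the [fit_pca()] model), `mismatch`
#'   (distances), and `bins` (the specimen-by-bin matrix).
#' @export
mismatch_analysis <- function(spectra, normalized = FALSE, ...) {
  bins <- bin_matrix(spectra, normalized = normalized, ...)
  role <- attr(bins, "role")
  bg <- attr(bins, "background_id")
  model <- fit_pca(bins, center = TRUE, scale. = FALSE)
  pairing <- data.frame(specimen_id = rownames(bins)[role == "tadpole"],
                        background_id = bg[role == "tadpole"])
  list(model = model, mismatch = mismatch(model, pairing), bins = bins)
}
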