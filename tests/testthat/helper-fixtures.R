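# shared fixtures and small independent helpers for the tests

# residual of A after optimal translation + rotation onto B (no scaling);
# brute-force rotation search keeps this independent of the package's SVD
# alignment when `angles` is supplied
align_residual <- function(A, B, angles = NULL) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  if (is.null(angles)) {
    H <- crossprod(A, B)
    sv <- svd(H)
    R <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
    return(A %*% R - B)
  }
  best <- Inf
  for (th in angles) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    d <- sum((A %*% R - B)^2)
    if (d < best) best <- d
  }
  best
}

rot2 <- function(theta) matrix(c(cos(theta), -sin(theta),
                                 sin(theta), cos(theta)), 2, 2)

# a flat spectrum data.frame on the 1-nm instrument grid
flat_spectrum <- function(level, lo = 360, hi = 740) {
  data.frame(wavelength = lo:hi, reflectance = level)
}

centroid_size <- function(coords) {
  sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
}
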