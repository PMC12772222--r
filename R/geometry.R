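# Distance / plane utilities shared by the interaction detectors.
# Orthorhombic minimum image only.

.min_image_diff <- function(d, box) {
  if (is.null(box)) return(d)
  sweep_box <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
  d - sweep_box * round(d / sweep_box)
}

# pairwise distances between coordinate sets X (n x 3) and Y (m x 3)
.pair_dists <- function(X, Y, box = NULL) {
  X <- matrix(X, ncol = 3); Y <- matrix(Y, ncol = 3)
  n <- nrow(X); m <- nrow(Y)
  dx <- matrix(rep(X[, 1], m), n) - matrix(rep(Y[, 1], each = n), n)
  dy <- matrix(rep(X[, 2], m), n) - matrix(rep(Y[, 2], each = n), n)
  dz <- matrix(rep(X[, 3], m), n) - matrix(rep(Y[, 3], each = n), n)
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

.vec_dist <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# minimum-image displacement vector p - q
.vec_diff <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

# angle at vertex b of the triangle a-b-c, degrees
.angle_deg <- function(a, b, c, box = NULL) {
  u <- .vec_diff(a, b, box); v <- .vec_diff(c, b, box)
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# least-squares plane normal of points (n x 3): right singular vector of
# the centred coordinates with the smallest singular value
.plane_normal <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)
  sv$v[, 3]
}
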