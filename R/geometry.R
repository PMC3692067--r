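# Small 3D geometry helpers: unit vectors, dihedrals, internal-coordinate
# atom placement (NeRF) and Kabsch superposition.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle in degrees of four points, in (-180, 180]
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle in degrees at p2
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  v1 <- unitv(p1 - p2)
  v2 <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Places point D given three predecessors A, B, C, the bond length C-D, the
#' bond angle B-C-D and the dihedral A-B-C-D (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihed) {
  th <- angle * pi / 180
  ph <- -dihed * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  c(m %*% d2) + c
}

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `fixed` (both n x 3).
#' Returns the rotation matrix, translation and RMSD; `apply_fit()` maps
#' arbitrary coordinates through the fit.
#' @keywords internal
kabsch <- function(fixed, mobile) {
  stopifnot(nrow(fixed) == nrow(mobile), ncol(fixed) == 3, nrow(fixed) >= 1)
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  f0 <- sweep(fixed, 2, cf)
  m0 <- sweep(mobile, 2, cm)
  h <- crossprod(m0, f0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- m0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - f0)^2)))
  list(rot = rot, center_mobile = cm, center_fixed = cf, rmsd = rmsd)
}

#' @keywords internal
apply_fit <- function(fit, coords) {
  sweep(sweep(coords, 2, fit$center_mobile) %*% t(fit$rot), 2, fit$center_fixed, "+")
}

#' Wrapped absolute angular difference in degrees, result in [0, 180]
#' @keywords internal
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
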