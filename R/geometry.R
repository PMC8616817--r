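# Small 3D geometry kernel shared by the hydrogen builder, the torsion-driven
# chain builder and the RDC module.  All coordinates are plain numeric
# 3-vectors / n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-10) return(NULL)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C and the internal coordinates
# bond = |C-D|, angle = B-C-D (degrees), dihedral = A-B-C-D (degrees).
# Standard NeRF construction.  Returns NULL if the frame is degenerate
# (A, B, C collinear).
place_internal <- function(A, B, C, bond, angle, dihedral) {
  bc <- unit(C - B)
  if (is.null(bc)) return(NULL)
  ab <- B - A
  n <- unit(vcross(ab, bc))
  if (is.null(n)) return(NULL)
  m <- vcross(n, bc)
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -atan2(y, x) * 180 / pi
}

# Optimal superposition (Kabsch).  Returns the rotation matrix and translation
# mapping `mobile` onto `ref` plus the post-fit RMSD.
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref))
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, center_mobile = cm, center_ref = cr, rmsd = rmsd)
}

apply_kabsch <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile) %*% t(fit$R), 2, fit$center_ref, "+")
}

# RMSD after optimal superposition.
fit_rmsd <- function(mobile, ref) kabsch(mobile, ref)$rmsd

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
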