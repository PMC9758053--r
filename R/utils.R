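# Internal geometry helpers. Angles are degrees at every interface; radians
# appear only inside a function body.

rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle a-b-c at vertex b, degrees.
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  deg(acos(max(-1, min(1, sum(u * v)))))
}

# Signed dihedral a-b-c-d, degrees, IUPAC sign convention.
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(unitv(b2), n1)
  deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# NeRF placement: position a fourth atom given three reference atoms, a bond
# length to `c`, the bond angle b-c-new and the dihedral a-b-c-new (degrees).
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  theta <- rad(angle)
  phi <- rad(dihedral)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(theta), bond * sin(theta) * cos(phi),
          bond * sin(theta) * sin(phi))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# Rotation matrix for `angle` degrees about unit axis (right-handed).
rotationMatrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- rad(angle)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite value in %s", what))
}
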