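## Internal geometry and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Rotation by `angle` degrees about an arbitrary axis (Rodrigues).
rotationAboutAxis <- function(axis, angleDeg) {
  u <- vunit(axis)
  th <- deg2rad(angleDeg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## z-y-z Euler rotation, degrees. Columns of the result are the rotated
## frame's axes expressed in the original frame.
eulerToRotation <- function(alpha, beta, gamma) {
  a <- deg2rad(alpha); b <- deg2rad(beta); g <- deg2rad(gamma)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

## Inverse of eulerToRotation: z-y-z Euler angles (degrees) of a proper
## rotation matrix. beta in [0, 180]; alpha, gamma in (-180, 180].
rotationToEuler <- function(R) {
  b <- acos(max(-1, min(1, R[3, 3])))
  if (sin(b) > 1e-10) {
    a <- atan2(R[2, 3], R[1, 3])
    g <- atan2(R[3, 2], -R[3, 1])
  } else {
    ## gimbal degenerate: fold everything into alpha
    a <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) a <- -a
    g <- 0
  }
  rad2deg(c(a, b, g))
}

## Dihedral angle A-B-C-D in degrees, signed.
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

## Angle A-B-C in degrees.
bondAngle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Natural-extension placement: coordinates of atom D bonded to C with
## bond length r, angle(B, C, D) = thetaDeg and dihedral(A, B, C, D) =
## chiDeg.
nerfPlace <- function(a, b, c, r, thetaDeg, chiDeg) {
  th <- deg2rad(thetaDeg); chi <- deg2rad(chiDeg)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(chi), -r * sin(th) * sin(chi))
  c + cbind(bc, m, n) %*% d2
}
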