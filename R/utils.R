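# Internal geometry and RNG helpers shared across modules.

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.norm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' @keywords internal
#' Natural-extension-reference-frame placement: position atom D given the
#' three preceding atoms A-B-C, the C-D bond length, the B-C-D angle and the
#' A-B-C-D dihedral (both in degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * (cos(dih) * m + sin(dih) * n))
}

# Angle at vertex b (degrees) of the triangle a-b-c.
.angle_deg <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Evaluate `code` under a private RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.  Generators must never leak RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Rotation matrix taking unit vector `from` onto unit vector `to` (Rodrigues).
.rotation_between <- function(from, to) {
  from <- .unit(from)
  to <- .unit(to)
  v <- .cross(from, to)
  s <- .norm(v)
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    axis <- .unit(.cross(from, if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

.stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}
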