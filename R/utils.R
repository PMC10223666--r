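# Small geometric helpers shared across analyzers. Internal length unit is
# Angstrom throughout; report-facing geometry is converted to nm (nm = A / 10).

A_PER_NM <- 10

#' Convert between Angstrom and nanometre
#'
#' Internally all coordinates are stored in Angstrom (the native unit of PDB
#' files); user-facing reports use nanometres.
#'
#' @param x numeric vector of lengths.
#' @return numeric vector in the other unit.
#' @export
ang_to_nm <- function(x) x / A_PER_NM

#' @rdname ang_to_nm
#' @export
nm_to_ang <- function(x) x * A_PER_NM

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps * 10) {
    abort("cannot normalise a zero-length vector", class = "vesitraj_zero_vector")
  }
  v / n
}

row_norms <- function(m) sqrt(rowSums(m^2))

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Rotation matrix mapping unit vector `a` onto unit vector `b` (Rodrigues).
rotation_align <- function(a, b) {
  a <- unit_vec(a)
  b <- unit_vec(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) {
    return(diag(3))
  }
  if (d < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit_vec(cross3(a, p))
    return(2 * tcrossprod(ax) - diag(3))
  }
  v <- cross3(a, b)
  vx <- matrix(
    c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
    nrow = 3
  )
  diag(3) + vx + vx %*% vx / (1 + d)
}

# Quasi-uniform points on the unit sphere (golden-spiral lattice).
# Deterministic; used for both shell placement and Shrake-Rupley sampling.
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Deterministic unit vector perpendicular to u.
perp_vec <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(cross3(u, a))
}

deg <- function(rad) rad * 180 / pi
rad <- function(degv) degv * pi / 180

`%||%` <- function(x, y) if (is.null(x)) y else x
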