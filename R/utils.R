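# Shared constants and small numeric helpers.

#' Boltzmann constant in kcal/mol/K
#' @keywords internal
.KB_KCAL <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(310)
#' @export
kT <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .KB_KCAL * temperature
}

#' Wrap angles to the interval [-180, 180) degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

# Wrap to [-pi, pi) radians.
wrap_rad <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# 2D periodic minimum-image displacement for box length L.
min_image <- function(dx, L) {
  dx - L * round(dx / L)
}

# Lateral (xy) minimum-image distances between one point and a set of points.
# `p` is length-2, `q` an n x 2 matrix, `box` is c(Lx, Ly).
lateral_dist <- function(p, q, box) {
  dx <- min_image(q[, 1] - p[1], box[1])
  dy <- min_image(q[, 2] - p[2], box[2])
  sqrt(dx * dx + dy * dy)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8-digit hex.
# Used to fingerprint run configurations; not cryptographic.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits only (bytes < 256 never touch the high half),
    # then a 32-bit multiply by 16777619 via 16-bit halves; doubles stay exact
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a stage seed (< 2^31) from a master seed and a stage index.
derive_seed <- function(master, stage) {
  ((abs(as.numeric(master)) * 7919 + stage * 104729) %% 2147483563) + 1
}

# Numerical central-difference gradient of scalar function f at x.
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Numerical Hessian via central differences of num_grad.
num_hess <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    H[, i] <- (num_grad(f, xp) - num_grad(f, xm)) / (2 * h)
  }
  (H + t(H)) / 2
}
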