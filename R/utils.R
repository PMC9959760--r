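# Internal helpers: classed conditions, integration, small linear algebra.

#' @keywords internal
"_PACKAGE"

# Standard gravity used for g <-> m/s^2 conversion throughout the package.
GRAVITY_MPS2 <- 9.80665

abort_gs <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "gaitscore_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

warn_gs <- function(message, class) {
  warning(structure(
    class = c(class, "gaitscore_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative trapezoidal integral
#'
#' Integrates `y` over `x` cumulatively; the first element of the result is
#' zero. `y` may be a vector or a matrix (integrated column-wise).
#'
#' @param x numeric vector of abscissae, strictly increasing.
#' @param y numeric vector or matrix of ordinates.
#' @return object of the same shape as `y`.
#' @keywords internal
cumtrapz <- function(x, y) {
  if (is.matrix(y)) {
    out <- apply(y, 2, function(col) cumtrapz(x, col))
    dimnames(out) <- dimnames(y)
    return(out)
  }
  n <- length(x)
  if (n != length(y)) stop("cumtrapz: length mismatch")
  if (n < 2) return(numeric(n))
  dx <- diff(x)
  c(0, cumsum(dx * (y[-n] + y[-1]) / 2))
}

# Rodrigues rotation matrix for rotation vector rv (axis * angle, radians).
rotvec_to_matrix <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) {
    K <- skew(rv)
    return(diag(3) + K)  # first order is exact enough below 1e-12
  }
  k <- rv / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Minimal rotation taking unit vector a to unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(rotvec_to_matrix(pi * v))
  }
  K <- skew(v)
  diag(3) + K + K %*% K / (1 + cth)
}

# Central-difference numerical gradient.
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

# Moving-average smoother with centred window of `n` samples (odd forced).
moving_avg <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(x)
  k <- stats::filter(x, rep(1 / n, n), sides = 2)
  k <- as.numeric(k)
  # shrink window at the edges rather than returning NA
  half <- (n - 1L) %/% 2L
  len <- length(x)
  for (i in which(is.na(k))) {
    lo <- max(1L, i - half); hi <- min(len, i + half)
    k[i] <- mean(x[lo:hi])
  }
  k
}
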