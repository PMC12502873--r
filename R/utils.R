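# Internal numerical helpers shared across modules.

.memsas_env <- new.env(parent = emptyenv())

#' @noRd
gl_nodes <- function(n, a = -1, b = 1) {
  key <- sprintf("gl_%d", n)
  gl <- .memsas_env[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .memsas_env[[key]] <- gl
  }
  mid <- (a + b) / 2
  hw <- (b - a) / 2
  list(x = mid + hw * gl$x, w = hw * gl$w)
}

#' @noRd
stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  invisible(x)
}

# 2 J1(x)/x with the analytic x -> 0 limit; even in x.
#' @noRd
j1c <- function(x) {
  out <- rep(1, length(x))
  ax <- abs(x)
  big <- ax > 1e-6
  out[big] <- 2 * besselJ(ax[big], 1) / ax[big]
  small <- !big & ax > 0
  # series: 2 J1(x)/x = 1 - x^2/8 + x^4/192
  out[small] <- 1 - ax[small]^2 / 8
  out
}

# Trapezoid weights on an arbitrary strictly increasing grid.
#' @noRd
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

# P(l1 < X <= u1, l2 < Y <= u2) for centred bivariate normal variables with
# common sd `sd` and correlation `rho`, by Gauss-Legendre quadrature over the
# conditional normal. Vectorized over the rectangle bounds; `rho`, `sd` scalar.
# Absolute accuracy ~1e-10 with n = 128 nodes (integrand is smooth).
#' @noRd
bvn_rect <- function(l1, u1, l2, u2, rho, sd, n = 128) {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  rho <- min(max(rho, -1), 1)
  m <- max(length(l1), length(u1), length(l2), length(u2))
  l1 <- rep_len(l1, m); u1 <- rep_len(u1, m)
  l2 <- rep_len(l2, m); u2 <- rep_len(u2, m)
  if (abs(rho) >= 1 - 1e-12) {
    # Degenerate: Y = rho * X almost surely.
    if (rho > 0) {
      lo <- pmax(l1, l2); hi <- pmin(u1, u2)
    } else {
      lo <- pmax(l1, -u2); hi <- pmin(u1, -l2)
    }
    return(pmax(stats::pnorm(hi / sd) - stats::pnorm(lo / sd), 0))
  }
  # Truncate the outer integral to the overlap with +-8.5 sd.
  lo <- pmax(l1, -8.5 * sd)
  hi <- pmin(u1, 8.5 * sd)
  out <- numeric(m)
  ok <- hi > lo
  if (!any(ok)) return(out)
  gl <- gl_nodes(n)
  s <- sd * sqrt(1 - rho^2)
  for (i in which(ok)) {
    x <- (lo[i] + hi[i]) / 2 + (hi[i] - lo[i]) / 2 * gl$x
    w <- (hi[i] - lo[i]) / 2 * gl$w
    inner <- stats::pnorm((u2[i] - rho * x) / s) - stats::pnorm((l2[i] - rho * x) / s)
    out[i] <- sum(w * stats::dnorm(x, sd = sd) * inner)
  }
  pmax(out, 0)
}

# Zero-order Hankel transform I(q) = int_0^inf 2 pi r J0(q r) f(r) dr by
# trapezoid quadrature on the supplied r grid. Returns one value per q.
#' @noRd
hankel0 <- function(q, r, f) {
  w <- trapz_weights(r) * 2 * pi * r * f
  vapply(q, function(qi) sum(besselJ(qi * r, 0) * w), numeric(1))
}

# Atomic text write: write to a temp file in the same directory, then rename.
#' @noRd
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not write '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' @noRd
msg_info <- function(..., verbose = getOption("memsas.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[memsas] ", sprintf(...))
}
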