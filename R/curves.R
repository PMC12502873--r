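# Containers for reduced scattering data: 1D elastic curves and (q, tau)
# intermediate-scattering-function surfaces.

#' Reduced 1D elastic scattering curve
#'
#' @param q Scattering vector grid in 1/A, strictly increasing and positive.
#' @param i Intensities per unit membrane area (arbitrary overall scale
#'   allowed when comparing with data).
#' @param sigma Optional positive 1-sigma uncertainties.
#' @param radiation `"neutron"` or `"xray"`.
#' @return An object of class `scattering_curve` (also a `data.frame` with
#'   columns `q`, `i` and, when present, `sigma`).
#' @export
scattering_curve <- function(q, i, sigma = NULL, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  q <- as.numeric(q); i <- as.numeric(i)
  if (length(q) == 0L) stop("empty curve", call. = FALSE)
  if (length(i) != length(q)) stop("`q` and `i` lengths differ", call. = FALSE)
  stopifnot_finite(q, "q")
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  if (any(diff(q) <= 0)) stop("`q` must be strictly increasing", call. = FALSE)
  stopifnot_finite(i, "i")
  df <- data.frame(q = q, i = i)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("`sigma` length mismatch", call. = FALSE)
    stopifnot_finite(sigma, "sigma")
    if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
    df$sigma <- sigma
  }
  structure(df, class = c("scattering_curve", "data.frame"), radiation = radiation)
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] 1/A, %s\n",
              nrow(x), min(x$q), max(x$q), attr(x, "radiation")))
  invisible(x)
}

#' Normalized intermediate scattering function surface
#'
#' Holds `I(q, tau) / I(q, 0)` on the union grid of the supplied `(q, tau)`
#' points, as measured by neutron spin-echo.
#'
#' @param q Scattering vectors in 1/A (one per row).
#' @param tau Correlation times in ns (one per row).
#' @param isf Normalized ISF values (1 at `tau = 0` up to noise).
#' @param sigma Optional positive uncertainties.
#' @return An object of class `isf_surface` (a long-format `data.frame` with
#'   columns `q`, `tau`, `isf` and, when present, `sigma`).
#' @export
isf_surface <- function(q, tau, isf, sigma = NULL) {
  q <- as.numeric(q); tau <- as.numeric(tau); isf <- as.numeric(isf)
  n <- length(q)
  if (n == 0L) stop("empty ISF surface", call. = FALSE)
  if (length(tau) != n || length(isf) != n) stop("column length mismatch", call. = FALSE)
  stopifnot_finite(q, "q"); stopifnot_finite(tau, "tau"); stopifnot_finite(isf, "isf")
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  if (anyDuplicated(paste(q, tau))) stop("duplicate (q, tau) rows", call. = FALSE)
  df <- data.frame(q = q, tau = tau, isf = isf)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != n) stop("`sigma` length mismatch", call. = FALSE)
    stopifnot_finite(sigma, "sigma")
    if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
    df$sigma <- sigma
  }
  bad0 <- df$tau == 0 & abs(df$isf - 1) > 0.05
  if (any(bad0)) {
    warning(sprintf("%d tau = 0 point(s) deviate from 1 by more than 5%%", sum(bad0)),
            call. = FALSE)
  }
  structure(df, class = c("isf_surface", "data.frame"))
}

#' @export
print.isf_surface <- function(x, ...) {
  cat(sprintf("<isf_surface> %d points, %d q value(s), tau in [%.3g, %.3g] ns\n",
              nrow(x), length(unique(x$q)), min(x$tau), max(x$tau)))
  invisible(x)
}
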