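# In-plane statistics of the protein cylinder phase: single-particle form
# factors and geometric covariograms, the hard-disc structure factor, the
# Boolean correlation function and their 2D (Hankel) intensities.

#' Disc form factor
#'
#' Normalized in-plane form factor of a circular cross-section,
#' `P_p(q_xy) = [2 J1(q_xy R_p) / (q_xy R_p)]^2`, with the analytic limit
#' `P_p(0) = 1`.
#'
#' @param q_xy In-plane scattering vector(s) in 1/A.
#' @param r_p Disc radius in A.
#' @return Dimensionless form factor values.
#' @export
disc_form_factor <- function(q_xy, r_p) {
  if (r_p <= 0) stop("`r_p` must be positive", call. = FALSE)
  j1c(q_xy * r_p)^2
}

#' Orientation-averaged ellipse form factor
#'
#' In-plane form factor of an elliptical cross-section with semi-axes
#' `a >= b`, averaged over a uniformly random orientation: the disc kernel is
#' evaluated at the angle-dependent effective radius
#' `r(psi) = sqrt(a^2 sin^2 psi + b^2 cos^2 psi)` and averaged over `psi` by
#' Gauss-Legendre quadrature. Reduces to [disc_form_factor()] when `a = b`.
#'
#' @param q_xy In-plane scattering vector(s) in 1/A.
#' @param a,b Semi-axes in A, `a >= b > 0`.
#' @param n_angle Number of quadrature nodes over `[0, pi/2]`.
#' @return Dimensionless form factor values.
#' @export
ellipse_form_factor <- function(q_xy, a, b, n_angle = 64) {
  if (!(a >= b && b > 0)) stop("need a >= b > 0", call. = FALSE)
  gl <- gl_nodes(n_angle, 0, pi / 2)
  r_eff <- sqrt(a^2 * sin(gl$x)^2 + b^2 * cos(gl$x)^2)
  w <- gl$w / (pi / 2)
  vapply(q_xy, function(q) sum(w * j1c(q * r_eff)^2), numeric(1))
}

#' Geometric covariogram of a disc
#'
#' `K(r_xy, 0)` is the intersection area of two discs of radius `r_p` whose
#' centres are a distance `r_xy` apart (the lens area
#' `2 R^2 [acos(u) - u sqrt(1 - u^2)]` with `u = r_xy / (2 R)`, zero beyond
#' `2 R`). For `tau > 0` and `d_p > 0` the disc performs 2D Brownian motion
#' and the covariogram is the convolution of `K(. , 0)` with the isotropic
#' Gaussian displacement law of per-axis variance `2 d_p tau` (2D mean-square
#' displacement `4 d_p tau`), evaluated through its Hankel representation
#' `K(r, tau) = (1/2pi) int q J0(q r) A_p^2 P_p(q) exp(-q^2 d_p tau) dq`.
#'
#' @param r_xy Centre separation(s) in A.
#' @param r_p Disc radius in A.
#' @param tau Lag time in ns.
#' @param d_p In-plane diffusion coefficient in A^2/ns.
#' @return Intersection areas in A^2.
#' @export
disc_covariogram <- function(r_xy, r_p, tau = 0, d_p = 0) {
  if (r_p <= 0) stop("`r_p` must be positive", call. = FALSE)
  if (any(r_xy < 0)) stop("`r_xy` must be nonnegative", call. = FALSE)
  if (tau < 0) stop("`tau` must be nonnegative", call. = FALSE)
  if (tau == 0 || d_p == 0) {
    u <- pmin(r_xy / (2 * r_p), 1)
    return(2 * r_p^2 * (acos(u) - u * sqrt(pmax(1 - u^2, 0))))
  }
  covariogram_diffused(r_xy, tau, d_p, area = pi * r_p^2,
                       pfun = function(q) disc_form_factor(q, r_p),
                       r_scale = r_p)
}

# Hankel-space Gaussian smearing of a covariogram K with known single-shape
# form factor: K(r, tau) = (1/2pi) int_0^qmax q J0(q r) A^2 P(q) e^{-q^2 D tau} dq.
#' @noRd
covariogram_diffused <- function(r_xy, tau, d_p, area, pfun, r_scale, n_q = 4096) {
  sig <- sqrt(2 * d_p * tau)
  # integrand decays as Gaussian in q beyond 1/sig and as q^-3 envelope of P
  q_max <- max(40 / r_scale, 8 / max(sig, 1e-6))
  q <- seq(0, q_max, length.out = n_q)
  fq <- q * area^2 * pfun(q) * exp(-q^2 * d_p * tau)
  w <- trapz_weights(q)
  vapply(r_xy, function(r) sum(w * fq * besselJ(q * r, 0)) / (2 * pi), numeric(1))
}

#' Isotropized geometric covariogram of an ellipse
#'
#' Mean intersection area of an ellipse (semi-axes `a >= b`) with a copy of
#' itself translated by a distance `r_xy` in a uniformly random direction
#' (equivalently, a randomly oriented ellipse). Obtained from the disc
#' covariogram through the affine map of the unit disc:
#' `K_ell(r) = mean_psi[ a b K_D(r sqrt(cos^2 psi / a^2 + sin^2 psi / b^2)) ]`
#' where `K_D` is the unit-disc covariogram. `K_ell(0) = pi a b`.
#'
#' @inheritParams ellipse_form_factor
#' @param r_xy Translation distance(s) in A.
#' @param tau Lag time in ns.
#' @param d_p In-plane diffusion coefficient in A^2/ns; for `tau > 0` the
#'   covariogram is smeared by the Gaussian displacement law as in
#'   [disc_covariogram()].
#' @return Areas in A^2.
#' @export
ellipse_covariogram <- function(r_xy, a, b, tau = 0, d_p = 0, n_angle = 64) {
  if (!(a >= b && b > 0)) stop("need a >= b > 0", call. = FALSE)
  if (any(r_xy < 0)) stop("`r_xy` must be nonnegative", call. = FALSE)
  if (tau == 0 || d_p == 0) {
    gl <- gl_nodes(n_angle, 0, pi / 2)
    w <- gl$w / (pi / 2)
    inv_r <- sqrt(cos(gl$x)^2 / a^2 + sin(gl$x)^2 / b^2)
    return(vapply(r_xy, function(r) {
      sum(w * a * b * unit_disc_covariogram(r * inv_r))
    }, numeric(1)))
  }
  covariogram_diffused(r_xy, tau, d_p, area = pi * a * b,
                       pfun = function(q) ellipse_form_factor(q, a, b, n_angle),
                       r_scale = b)
}

# covariogram of the unit-radius disc
#' @noRd
unit_disc_covariogram <- function(d) {
  u <- pmin(d / 2, 1)
  2 * (acos(u) - u * sqrt(pmax(1 - u^2, 0)))
}

#' Hard-disc structure factor (low-density approximation)
#'
#' Two-dimensional structure factor of non-overlapping discs of interaction
#' radius `r_hd` at area fraction `phi_p`, in the low-density
#' direct-correlation closure
#' `S(q) = 1 / [1 + 4 phi_p * 2 J1(2 q r_hd) / (2 q r_hd)]`.
#' Satisfies `S -> 1` as `phi_p -> 0` and as `q -> Inf`, and `S(0) < 1`
#' (reduced isothermal compressibility). Intended for `phi_p < 0.5`; a
#' warning is emitted outside that regime.
#'
#' @param q_xy In-plane scattering vector(s) in 1/A.
#' @param r_hd Hard-disc radius in A.
#' @param phi_p Area fraction in `[0, 1)`.
#' @return Dimensionless structure factor values.
#' @export
harddisc_structure_factor <- function(q_xy, r_hd, phi_p) {
  if (r_hd <= 0) stop("`r_hd` must be positive", call. = FALSE)
  if (phi_p < 0 || phi_p >= 1) stop("`phi_p` must be in [0, 1)", call. = FALSE)
  if (phi_p >= 0.5) {
    warning("hard-disc structure factor outside its low-density regime (phi_p >= 0.5)",
            call. = FALSE)
  }
  1 / (1 + 4 * phi_p * j1c(2 * q_xy * r_hd))
}

#' Boolean in-plane correlation function
#'
#' Correlation function of the covered phase of a Boolean model of
#' (overlapping) protein cross-sections centred on a Poisson point process
#' of intensity `theta_p`:
#' `C_p(r, tau) = (1 - phi_p)^2 [exp(theta_p K(r, tau)) - 1]`,
#' with `K` the (time-smeared) geometric covariogram of the cross-section.
#' `C_p(0, 0) = phi_p (1 - phi_p)`, `C_p` vanishes beyond the covariogram
#' support at `tau = 0`, and `C_p ~ theta_p K` in the dilute limit.
#'
#' @param r_xy In-plane separation(s) in A.
#' @param p A [protein_spec()] with `lateral_model = "boolean"`.
#' @param tau Lag time in ns.
#' @return Dimensionless correlation values.
#' @export
boolean_correlation <- function(r_xy, p, tau = 0) {
  stopifnot(inherits(p, "protein_spec"))
  if (p$lateral_model != "boolean") {
    stop("`boolean_correlation()` needs a protein spec with lateral_model = \"boolean\"",
         call. = FALSE)
  }
  K <- protein_covariogram(r_xy, p, tau)
  (1 - p$phi_p)^2 * expm1(p$theta_p * K)
}

#' @noRd
protein_covariogram <- function(r_xy, p, tau = 0) {
  if (p$shape$type == "disc") {
    disc_covariogram(r_xy, p$shape$r_p, tau, p$d_p)
  } else {
    ellipse_covariogram(r_xy, p$shape$a, p$shape$b, tau, p$d_p)
  }
}

# effective maximum cross-section extent (diameter) used to size r grids
#' @noRd
protein_diameter <- function(p) {
  if (p$shape$type == "disc") 2 * p$shape$r_p else 2 * p$shape$a
}

# default radial grid for Hankel transforms of C_p
#' @noRd
inplane_r_grid <- function(p, tau = 0, n_r = 2048) {
  r_max <- max(6 * protein_diameter(p), 6 * sqrt(2 * p$d_p * tau) + protein_diameter(p))
  seq(0, r_max, length.out = n_r)
}

#' In-plane protein scattering intensity
#'
#' 2D scattered intensity per unit area of the protein cylinder phase,
#' `I_p(q_xy, tau)`, i.e. the zero-order Hankel transform of the in-plane
#' correlation function `C_p(r_xy, tau)`.
#'
#' For `lateral_model = "harddisc"` the intensity is assembled directly in
#' reciprocal space, `I_p = theta_p A_p^2 P_p(q_xy) S_HD(q_xy)` (elastic
#' only: the hard-disc route has no dynamic extension, so `tau > 0` with
#' `d_p > 0` is an error). For `lateral_model = "boolean"` the Boolean
#' correlation function is Hankel-transformed by trapezoid quadrature on a
#' truncated radial grid (the integrand has compact support at `tau = 0` and
#' decays rapidly otherwise).
#'
#' @param q_xy In-plane scattering vector(s) in 1/A.
#' @param p A [protein_spec()].
#' @param tau Lag time in ns.
#' @param n_r Number of radial quadrature nodes (Boolean path).
#' @return Intensities in A^2 (per unit membrane area conventions).
#' @export
inplane_intensity <- function(q_xy, p, tau = 0, n_r = 2048) {
  stopifnot(inherits(p, "protein_spec"))
  if (p$lateral_model == "harddisc") {
    if (tau > 0 && p$d_p > 0) {
      stop("the hard-disc model has no time dependence; use the Boolean model for tau > 0",
           call. = FALSE)
    }
    pf <- if (p$shape$type == "disc") {
      disc_form_factor(q_xy, p$shape$r_p)
    } else {
      ellipse_form_factor(q_xy, p$shape$a, p$shape$b)
    }
    return(p$theta_p * p$area^2 * pf * harddisc_structure_factor(q_xy, p$r_hd, p$phi_p))
  }
  r <- inplane_r_grid(p, tau, n_r)
  cp <- boolean_correlation(r, p, tau)
  hankel0(q_xy, r, cp)
}
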