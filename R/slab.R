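# Elastic and inelastic scattering of the static slab membrane, bare and with
# protein inclusions.

#' Rotationally averaged slab-membrane intensity
#'
#' Per-unit-area scattered intensity of a static, laterally uniform SLD
#' profile, `I(q) = 2 pi |rho(q)|^2 / q^2`, where `rho(q)` is the 1D Fourier
#' amplitude of the solvent-contrasted profile ([slab_amplitude()]). The
#' `1/q^2` arises from averaging the planar scattering over all membrane
#' orientations (per projected unit area); finite-thickness stacks therefore
#' show the characteristic `q^-2` power law at low `q`.
#'
#' @param stack A [layer_stack()].
#' @param q Positive scattering vector grid in 1/A (`q = 0` diverges in the
#'   per-area convention and is rejected).
#' @param radiation Radiation label attached to the returned curve.
#' @return A [scattering_curve()].
#' @export
slab_intensity <- function(stack, q, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  q <- as.numeric(q)
  if (any(q <= 0)) stop("`q` must be strictly positive", call. = FALSE)
  amp <- slab_amplitude(stack, q, reference_sld = "solvent")
  scattering_curve(q, 2 * pi * Mod(amp)^2 / q^2, radiation = radiation)
}

#' Slab-membrane intensity with protein inclusions
#'
#' Total per-unit-area intensity of a slab membrane carrying transmembrane
#' protein cylinders, decomposed into its two addends:
#' the membrane term is the slab intensity of the protein-corrected *average*
#' SLD profile, and the protein term couples the *contrast* profile to the
#' in-plane protein intensity through the rotational average
#' `(1/2) int_-1^1 dmu |rho_c(q mu)|^2 I_p(q sqrt(1 - mu^2), tau)`,
#' evaluated by fixed-order Gauss-Legendre quadrature in `mu` with an
#' order-doubling convergence check.
#'
#' @param b A [symmetric_bilayer()] or [layer_stack()].
#' @param p A [protein_spec()].
#' @param q Positive scattering vector grid in 1/A.
#' @param tau Lag time in ns (Boolean lateral model only when positive and
#'   the protein diffuses).
#' @param radiation Radiation label for the returned curves.
#' @param n_mu Gauss-Legendre order for the azimuthal average.
#' @param mu_tol Relative tolerance of the order-doubling check.
#' @return A list with components `total`, `membrane` and `protein`
#'   ([scattering_curve()]s satisfying `total = membrane + protein`
#'   exactly).
#' @export
slab_intensity_with_proteins <- function(b, p, q, tau = 0,
                                         radiation = c("neutron", "xray"),
                                         n_mu = 64, mu_tol = 1e-4) {
  radiation <- match.arg(radiation)
  stack <- as_layer_stack(b)
  stopifnot(inherits(p, "protein_spec"))
  q <- as.numeric(q)
  if (any(q <= 0)) stop("`q` must be strictly positive", call. = FALSE)

  stack_avg <- protein_corrected_slds(stack, p, "average")
  stack_con <- protein_corrected_slds(stack, p, "contrast")
  membrane <- slab_intensity(stack_avg, q, radiation)

  i_protein <- protein_term_mu_average(stack_con, p, q, tau, n_mu, mu_tol)
  total <- scattering_curve(q, membrane$i + i_protein, radiation = radiation)
  list(total = total,
       membrane = membrane,
       protein = scattering_curve(q, i_protein, radiation = radiation))
}

#' @noRd
as_layer_stack <- function(x) {
  if (inherits(x, "symmetric_bilayer")) expand_bilayer(x)
  else if (inherits(x, "layer_stack")) x
  else stop("expected a `symmetric_bilayer` or `layer_stack`", call. = FALSE)
}

# (1/2) int_-1^1 |rho_c(q mu)|^2 I_p(q sqrt(1-mu^2), tau) dmu for each q,
# with an order-doubling convergence check on the quadrature.
#' @noRd
protein_term_mu_average <- function(stack_con, p, q, tau, n_mu = 64, mu_tol = 1e-4) {
  if (all(stack_con$sld == 0) || p$phi_p == 0) return(rep(0, length(q)))
  # I_p depends on q_xy only: evaluate once on a fine grid and interpolate,
  # so the doubling check does not redo the Hankel quadrature.
  q_xy_max <- max(q)
  q_xy_grid <- seq(0, q_xy_max, length.out = 512)
  ip_grid <- inplane_intensity(q_xy_grid, p, tau)
  ip_fun <- stats::approxfun(q_xy_grid, ip_grid, rule = 2)
  eval_order <- function(n) {
    gl <- gl_nodes(n, 0, 1)  # integrand even in mu
    vapply(q, function(qi) {
      amp2 <- Mod(slab_amplitude(stack_con, qi * gl$x, reference_sld = 0))^2
      sum(gl$w * amp2 * ip_fun(qi * sqrt(pmax(1 - gl$x^2, 0))))
    }, numeric(1))
  }
  i1 <- eval_order(n_mu)
  i2 <- eval_order(2 * n_mu)
  scale_ref <- max(abs(i2))
  if (scale_ref > 0) {
    rel <- max(abs(i2 - i1)) / scale_ref
    if (rel > mu_tol) {
      stop(sprintf(
        "mu quadrature did not converge (relative change %.3g on order doubling %d -> %d)",
        rel, n_mu, 2 * n_mu), call. = FALSE)
    }
  }
  i2
}
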