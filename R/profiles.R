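# Membrane SLD profiles: layer stacks, symmetric bilayers, 1D Fourier
# amplitudes and protein-corrected SLD replacements.
#
# Units are fixed package-wide: lengths in Angstrom (A), scattering vectors in
# 1/A, scattering length densities (SLDs) in 1/A^2, times in ns, diffusion
# coefficients in A^2/ns.

#' Multi-layer membrane SLD profile
#'
#' A piecewise-constant scattering length density profile along the membrane
#' normal `z`: `length(sld)` layers delimited by `length(sld) + 1` strictly
#' increasing boundaries, embedded in an infinite solvent of SLD
#' `solvent_sld`. Layers whose SLD equals the solvent SLD ("bogus" layers) are
#' allowed at either end; they carry no scattering contrast but let a protein
#' inclusion protrude beyond the chemically distinct part of the membrane.
#'
#' @param boundaries Numeric vector of layer boundaries along `z` in A,
#'   strictly increasing.
#' @param sld Numeric vector of per-layer SLDs in 1/A^2, one per interval
#'   between consecutive boundaries.
#' @param solvent_sld Solvent SLD in 1/A^2.
#' @return An object of class `layer_stack`.
#' @examples
#' layer_stack(c(-21.3, -16.3, 16.3, 21.3),
#'             c(1.87e-6, -0.07e-6, 1.87e-6), 6.37e-6)
#' @export
layer_stack <- function(boundaries, sld, solvent_sld) {
  boundaries <- as.numeric(boundaries)
  sld <- as.numeric(sld)
  solvent_sld <- as.numeric(solvent_sld)
  if (length(solvent_sld) != 1L) stop("`solvent_sld` must be a single value", call. = FALSE)
  stopifnot_finite(boundaries, "boundaries")
  stopifnot_finite(sld, "sld")
  stopifnot_finite(solvent_sld, "solvent_sld")
  if (length(boundaries) >= 2L && any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be strictly increasing", call. = FALSE)
  }
  if (length(sld) != max(length(boundaries) - 1L, 0L)) {
    stop("need exactly one SLD per layer (length(boundaries) - 1)", call. = FALSE)
  }
  structure(
    list(boundaries = boundaries, sld = sld, solvent_sld = solvent_sld),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  n <- length(x$sld)
  cat(sprintf("<layer_stack> %d layer(s), solvent SLD %.4g 1/A^2\n", n, x$solvent_sld))
  if (n > 0) {
    df <- data.frame(
      z_lo = x$boundaries[-(n + 1)],
      z_hi = x$boundaries[-1],
      sld = x$sld
    )
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Number of layers in a stack
#' @param stack A [layer_stack()].
#' @return Integer layer count.
#' @export
n_layers <- function(stack) length(stack$sld)

#' Symmetric lipid bilayer specification
#'
#' Describes a bilayer of amphiphilic molecules with a hydrophobic chain of
#' half-thickness `l_c` per leaflet and hydrophilic heads of thickness `l_h`,
#' optionally flanked by solvated layers of thickness `l_s` (e.g. protruding
#' solvated protein parts). Expands to a symmetric 6-layer [layer_stack()]
#' spanning `[-(l_c + l_h + l_s), +(l_c + l_h + l_s)]`, with `z = 0` at the
#' bilayer midplane.
#'
#' @param l_c Chain half-layer thickness per leaflet in A (the chain region
#'   spans `[-l_c, l_c]`).
#' @param l_h Head layer thickness in A.
#' @param l_s Solvated outer layer thickness in A (0 drops these layers).
#' @param rho_c,rho_h,rho_s SLDs of the chain, head and solvated layers in
#'   1/A^2. `rho_s` defaults to the solvent SLD.
#' @param rho_w Solvent SLD in 1/A^2.
#' @return An object of class `symmetric_bilayer`.
#' @examples
#' symmetric_bilayer(l_c = 16.3, l_h = 5.0,
#'                   rho_c = -0.07e-6, rho_h = 1.87e-6, rho_w = 6.37e-6)
#' @export
symmetric_bilayer <- function(l_c, l_h, l_s = 0, rho_c, rho_h, rho_s = rho_w, rho_w) {
  for (nm in c("l_c", "l_h", "l_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single nonnegative thickness in A", nm), call. = FALSE)
    }
  }
  for (nm in c("rho_c", "rho_h", "rho_s", "rho_w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite SLD in 1/A^2", nm), call. = FALSE)
    }
  }
  structure(
    list(l_c = l_c, l_h = l_h, l_s = l_s,
         rho_c = rho_c, rho_h = rho_h, rho_s = rho_s, rho_w = rho_w),
    class = "symmetric_bilayer"
  )
}

#' @export
print.symmetric_bilayer <- function(x, ...) {
  cat(sprintf(
    "<symmetric_bilayer> l_c=%.3g l_h=%.3g l_s=%.3g A; total thickness %.4g A\n",
    x$l_c, x$l_h, x$l_s, 2 * (x$l_c + x$l_h + x$l_s)
  ))
  invisible(x)
}

#' Expand a symmetric bilayer into a layer stack
#'
#' Builds the symmetric stack solvent | S | H | C | C | H | S | solvent with
#' `z = 0` at the midplane. Zero-thickness layers are dropped, so with
#' `l_s = 0` the result has 4 interior layers (or 2 when `l_h = 0`), and the
#' fully degenerate case yields a solvent-only (empty) stack.
#'
#' @param b A [symmetric_bilayer()].
#' @return A [layer_stack()].
#' @export
expand_bilayer <- function(b) {
  stopifnot(inherits(b, "symmetric_bilayer"))
  # bottom to top: S | H | C | C | H | S, one chain layer per leaflet
  thick <- c(b$l_s, b$l_h, b$l_c, b$l_c, b$l_h, b$l_s)
  sld <- c(b$rho_s, b$rho_h, b$rho_c, b$rho_c, b$rho_h, b$rho_s)
  keep <- thick > 0
  thick <- thick[keep]
  sld <- sld[keep]
  if (length(thick) == 0L) {
    return(layer_stack(numeric(0), numeric(0), b$rho_w))
  }
  boundaries <- cumsum(c(-(b$l_c + b$l_h + b$l_s), thick))
  layer_stack(boundaries, sld, b$rho_w)
}

#' 1D Fourier amplitude of a layer-stack SLD profile
#'
#' Computes `rho(q_z) = integral over the stack of (rho(z) - reference) *
#' exp(i q_z z) dz` in closed form (one sinc-type term per layer). The
#' integral runs over the finite extent of the stack only; `reference_sld = 0`
#' gives the profile contrasted with void, and `reference_sld =
#' stack$solvent_sld` the profile contrasted with the solvent (in which case
#' the solvent outside the stack contributes nothing by construction).
#'
#' @param stack A [layer_stack()].
#' @param q_z Numeric vector of scattering vectors in 1/A (0 allowed).
#' @param reference_sld SLD subtracted before transforming, in 1/A^2; either a
#'   number, `"void"` (0) or `"solvent"`.
#' @return Complex vector, one amplitude (units 1/A) per `q_z`. Purely real
#'   (up to rounding) for profiles symmetric about `z = 0`.
#' @export
slab_amplitude <- function(stack, q_z, reference_sld = "solvent") {
  stopifnot(inherits(stack, "layer_stack"))
  ref <- resolve_reference_sld(stack, reference_sld)
  q_z <- as.numeric(q_z)
  stopifnot_finite(q_z, "q_z")
  n <- length(stack$sld)
  out <- complex(real = rep(0, length(q_z)), imaginary = rep(0, length(q_z)))
  if (n == 0L) return(out)
  drho <- stack$sld - ref
  a_lo <- stack$boundaries[-(n + 1)]
  a_hi <- stack$boundaries[-1]
  small <- abs(q_z) < 1e-12
  if (any(small)) {
    out[small] <- sum(drho * (a_hi - a_lo)) + 0i
  }
  if (any(!small)) {
    q <- q_z[!small]
    acc <- complex(real = rep(0, length(q)), imaginary = rep(0, length(q)))
    for (k in seq_len(n)) {
      acc <- acc + drho[k] * (exp(1i * q * a_hi[k]) - exp(1i * q * a_lo[k])) / (1i * q)
    }
    out[!small] <- acc
  }
  out
}

#' @noRd
resolve_reference_sld <- function(stack, reference_sld) {
  if (is.character(reference_sld)) {
    reference_sld <- match.arg(reference_sld, c("solvent", "void"))
    if (reference_sld == "solvent") stack$solvent_sld else 0
  } else {
    as.numeric(reference_sld)
  }
}

#' Protein inclusion specification
#'
#' Describes transmembrane protein inclusions as cylinders normal to the
#' membrane plane, with a circular (radius `r_p`) or randomly oriented
#' elliptical (semi-axes `a >= b`) cross-section, a per-layer SLD, a surface
#' number density, an in-plane statistical model and an in-plane diffusion
#' coefficient.
#'
#' Exactly one of `theta_p` (number of proteins per A^2 of membrane plane) or
#' `phi_p` (area fraction covered by protein cylinders) must be given; the
#' other is derived through the lateral model's coverage relation (see
#' [phi_from_theta()]).
#'
#' @param r_p Disc radius in A (circular cross-section), or `NULL` when
#'   `a`/`b` are given.
#' @param a,b Ellipse semi-axes in A with `a >= b > 0` (randomly oriented
#'   elliptical cross-section), or `NULL` for a disc.
#' @param rho_p Protein SLD in 1/A^2: a scalar (broadcast to every membrane
#'   layer) or one value per layer of the stack it will be combined with
#'   (e.g. a lower-contrast value for solvated protruding parts).
#' @param theta_p Number of proteins per A^2.
#' @param phi_p Protein area (volume) fraction in `[0, 1)`.
#' @param lateral_model `"boolean"` (overlapping discs on a Poisson process)
#'   or `"harddisc"` (non-overlapping, low-density structure factor).
#' @param d_p In-plane diffusion coefficient in A^2/ns (0 = static).
#' @param r_hd Hard-disc interaction radius in A used by the structure factor;
#'   defaults to `r_p` for discs and to the semi-major axis `a` for ellipses.
#' @return An object of class `protein_spec` with derived fields `area`
#'   (cross-section area A_p in A^2), `theta_p` and `phi_p`.
#' @examples
#' protein_spec(r_p = 21.4, rho_p = 1.685e-6, phi_p = 0.23)
#' @export
protein_spec <- function(r_p = NULL, a = NULL, b = NULL, rho_p,
                         theta_p = NULL, phi_p = NULL,
                         lateral_model = c("boolean", "harddisc"),
                         d_p = 0, r_hd = NULL) {
  lateral_model <- match.arg(lateral_model)
  if (is.null(r_p) == is.null(a)) {
    stop("give either `r_p` (disc) or `a` and `b` (ellipse)", call. = FALSE)
  }
  if (!is.null(r_p)) {
    if (!is.numeric(r_p) || length(r_p) != 1L || r_p <= 0) {
      stop("`r_p` must be a single positive radius in A", call. = FALSE)
    }
    shape <- list(type = "disc", r_p = r_p)
    area <- pi * r_p^2
    if (is.null(r_hd)) r_hd <- r_p
  } else {
    if (is.null(b)) stop("an ellipse needs both `a` and `b`", call. = FALSE)
    if (!(is.numeric(a) && is.numeric(b) && a >= b && b > 0)) {
      stop("ellipse semi-axes must satisfy a >= b > 0", call. = FALSE)
    }
    shape <- list(type = "ellipse", a = a, b = b)
    area <- pi * a * b
    if (is.null(r_hd)) r_hd <- a
  }
  if (is.null(theta_p) == is.null(phi_p)) {
    stop("give exactly one of `theta_p` or `phi_p`", call. = FALSE)
  }
  if (is.null(theta_p)) {
    if (!is.numeric(phi_p) || length(phi_p) != 1L || phi_p < 0 || phi_p >= 1) {
      stop("`phi_p` must be in [0, 1)", call. = FALSE)
    }
    theta_p <- theta_from_phi(phi_p, area, lateral_model)
  } else {
    if (!is.numeric(theta_p) || length(theta_p) != 1L || theta_p < 0) {
      stop("`theta_p` must be a nonnegative surface density", call. = FALSE)
    }
    phi_p <- phi_from_theta(theta_p, area, lateral_model)
  }
  if (phi_p >= 1) stop("derived `phi_p` must be below 1", call. = FALSE)
  if (lateral_model == "harddisc" && phi_p >= 0.5) {
    warning("hard-disc structure factor used outside its low-density regime (phi_p >= 0.5)",
            call. = FALSE)
  }
  if (!is.numeric(d_p) || length(d_p) != 1L || d_p < 0) {
    stop("`d_p` must be a single nonnegative diffusion coefficient", call. = FALSE)
  }
  stopifnot_finite(rho_p, "rho_p")
  structure(
    list(shape = shape, area = area, rho_p = as.numeric(rho_p),
         theta_p = theta_p, phi_p = phi_p,
         lateral_model = lateral_model, d_p = d_p, r_hd = r_hd),
    class = "protein_spec"
  )
}

#' @export
print.protein_spec <- function(x, ...) {
  sh <- if (x$shape$type == "disc") {
    sprintf("disc R_p=%.3g A", x$shape$r_p)
  } else {
    sprintf("ellipse a=%.3g b=%.3g A", x$shape$a, x$shape$b)
  }
  cat(sprintf(
    "<protein_spec> %s, A_p=%.4g A^2, theta_p=%.4g /A^2, phi_p=%.4g, %s model, D_p=%.3g A^2/ns\n",
    sh, x$area, x$theta_p, x$phi_p, x$lateral_model, x$d_p
  ))
  invisible(x)
}

#' Coverage relations between surface density and area fraction
#'
#' For the Boolean (overlapping) model the covered area fraction is
#' `phi_p = 1 - exp(-theta_p * A_p)`; for the hard-disc (non-overlapping)
#' model it is linear, `phi_p = theta_p * A_p`. The two agree to first order
#' in `theta_p * A_p`.
#'
#' @param theta_p Proteins per A^2 (nonnegative).
#' @param a_p Cross-section area in A^2 (positive).
#' @param model `"boolean"` or `"harddisc"`.
#' @return `phi_from_theta()`: the covered area fraction.
#' @export
phi_from_theta <- function(theta_p, a_p, model = c("boolean", "harddisc")) {
  model <- match.arg(model)
  if (any(theta_p < 0)) stop("`theta_p` must be nonnegative", call. = FALSE)
  if (any(a_p <= 0)) stop("`a_p` must be positive", call. = FALSE)
  if (model == "boolean") 1 - exp(-theta_p * a_p) else theta_p * a_p
}

#' @rdname phi_from_theta
#' @param phi_p Covered area fraction in `[0, 1)` (must stay below 1 for the
#'   Boolean inverse).
#' @return `theta_from_phi()`: the surface number density.
#' @export
theta_from_phi <- function(phi_p, a_p, model = c("boolean", "harddisc")) {
  model <- match.arg(model)
  if (any(phi_p < 0) || any(phi_p >= 1)) {
    stop("`phi_p` must be in [0, 1)", call. = FALSE)
  }
  if (any(a_p <= 0)) stop("`a_p` must be positive", call. = FALSE)
  if (model == "boolean") -log(1 - phi_p) / a_p else phi_p / a_p
}

#' Protein-corrected layer SLDs
#'
#' Replaces each layer SLD `rho_n` either by the protein-weighted average
#' `(1 - phi_p) rho_n + phi_p rho_p_n` (`mode = "average"`: the profile seen
#' outside the protein cylinders plus their mean contribution) or by the
#' contrast with the protein `rho_n - rho_p_n` (`mode = "contrast"`: the
#' profile that multiplies the in-plane protein correlation). The layer
#' geometry is unchanged. In `"average"` mode the solvent SLD is unchanged
#' (the cylinders outside the membrane are filled with solvent); in
#' `"contrast"` mode the returned stack has solvent SLD 0, the contrast
#' profile vanishing identically outside the membrane.
#'
#' @param stack A [layer_stack()].
#' @param p A [protein_spec()]; its scalar `rho_p` is broadcast to all layers,
#'   or must supply one value per layer.
#' @param mode `"average"` or `"contrast"`.
#' @return A [layer_stack()] with modified SLDs.
#' @export
protein_corrected_slds <- function(stack, p, mode = c("average", "contrast")) {
  stopifnot(inherits(stack, "layer_stack"), inherits(p, "protein_spec"))
  mode <- match.arg(mode)
  n <- n_layers(stack)
  rho_p <- p$rho_p
  if (length(rho_p) == 1L) {
    rho_p <- rep(rho_p, n)
  } else if (length(rho_p) != n) {
    stop(sprintf("protein has %d per-layer SLD(s) but the stack has %d layer(s)",
                 length(p$rho_p), n), call. = FALSE)
  }
  if (mode == "average") {
    layer_stack(stack$boundaries,
                (1 - p$phi_p) * stack$sld + p$phi_p * rho_p,
                stack$solvent_sld)
  } else {
    layer_stack(stack$boundaries, stack$sld - rho_p, 0)
  }
}
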