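# Gaussian fluctuating-membrane model: the rigid layer stack is displaced
# vertically by a laterally correlated, unit-variance Gaussian height field W
# scaled by l_alpha, with space-time covariance g_W(r_xy, tau). Everything
# (layer occupation probabilities, correlation functions, elastic and
# inelastic intensities) follows from the clipped-Gaussian statistics of the
# displaced stack.

#' Gaussian membrane fluctuation parameters
#'
#' @param l_alpha Root-mean-square vertical displacement of the membrane in A
#'   (`l_alpha = 0` recovers the static slab model).
#' @param l_xy Lateral size of the deformations in A (positive).
#' @param d Wave-packet diffusion coefficient in A^2/ns (`d = 0` freezes the
#'   fluctuation pattern).
#' @return An object of class `gaussian_membrane`.
#' @examples
#' gaussian_membrane(l_alpha = 23, l_xy = 63, d = 1.85)
#' @export
gaussian_membrane <- function(l_alpha, l_xy, d = 0) {
  if (!is.numeric(l_alpha) || length(l_alpha) != 1L || l_alpha < 0) {
    stop("`l_alpha` must be a single nonnegative length", call. = FALSE)
  }
  if (!is.numeric(l_xy) || length(l_xy) != 1L || l_xy <= 0) {
    stop("`l_xy` must be a single positive length", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop("`d` must be a single nonnegative diffusion coefficient", call. = FALSE)
  }
  structure(list(l_alpha = l_alpha, l_xy = l_xy, d = d), class = "gaussian_membrane")
}

#' @export
print.gaussian_membrane <- function(x, ...) {
  cat(sprintf("<gaussian_membrane> l_alpha=%.3g A, l_xy=%.3g A, D=%.3g A^2/ns",
              x$l_alpha, x$l_xy, x$d))
  if (x$d > 0) cat(sprintf(" (tau_c = l_xy^2/(4 D) = %.4g ns)", x$l_xy^2 / (4 * x$d)))
  cat("\n")
  invisible(x)
}

#' Space-time covariance of the height field
#'
#' Normalized covariance of the unit-variance height field: randomly
#' diffusing Gaussian wave packets of size `l_xy` give
#' `g_W(r, tau) = (1 + D tau / l_xy^2)^-1 *
#'   exp[-r^2 / (4 l_xy^2 (1 + D tau / l_xy^2))]`.
#' `g_W(0, 0) = 1`; at `tau = 0` the covariance is Gaussian in `r` with
#' lateral scale `l_xy`; diffusion broadens the correlation and decays its
#' amplitude on the time scale `l_xy^2 / D`. Each lateral Fourier mode `k`
#' decorrelates as `exp(-D k^2 tau)`.
#'
#' @param r_xy In-plane separation(s) in A.
#' @param tau Lag time in ns (nonnegative).
#' @param g A [gaussian_membrane()].
#' @return Dimensionless covariance values in `(0, 1]`.
#' @export
gw_covariance <- function(r_xy, tau, g) {
  stopifnot(inherits(g, "gaussian_membrane"))
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  s <- 1 + g$d * tau / g$l_xy^2
  exp(-r_xy^2 / (4 * g$l_xy^2 * s)) / s
}

# Isotropic 2D spectral density of g_W(., 0): S(k) = 4 pi l_xy^2 exp(-k^2 l_xy^2),
# normalized so that int S(k) d^2k / (2 pi)^2 = 1.
#' @noRd
gw_spectral_density <- function(k, g) {
  4 * pi * g$l_xy^2 * exp(-k^2 * g$l_xy^2)
}

# z-boundaries of the stack extended by the two semi-infinite solvent layers,
# and the matching SLD contrasts (solvent-subtracted -> solvent rows are 0).
#' @noRd
stack_regions <- function(stack) {
  list(lower = c(-Inf, stack$boundaries),
       upper = c(stack$boundaries, Inf),
       drho = c(0, stack$sld - stack$solvent_sld, 0))
}

#' Layer occupation probabilities of the fluctuating membrane
#'
#' With the stack displaced rigidly by `h = l_alpha W`, a point at height `z`
#' lies in layer `n` when `z - h` falls inside that layer; the one-point
#' probabilities are therefore differences of normal CDFs,
#' `p_n(z) = Phi((z - a_(n-1)) / l_alpha) - Phi((z - a_n) / l_alpha)`.
#' The two semi-infinite solvent regions below and above the stack are
#' included as the first and last columns, so each row sums to 1.
#'
#' @param stack A [layer_stack()].
#' @param g A [gaussian_membrane()].
#' @param z Heights in A.
#' @return Matrix of probabilities, `length(z)` rows and `n_layers + 2`
#'   columns (`solvent_below`, the layers in order, `solvent_above`).
#' @export
layer_probabilities <- function(stack, g, z) {
  stopifnot(inherits(stack, "layer_stack"), inherits(g, "gaussian_membrane"))
  reg <- stack_regions(stack)
  nreg <- length(reg$drho)
  out <- matrix(0, length(z), nreg)
  if (g$l_alpha == 0) {
    for (j in seq_len(nreg)) {
      out[, j] <- as.numeric(z > reg$lower[j] & z <= reg$upper[j])
    }
  } else {
    for (j in seq_len(nreg)) {
      out[, j] <- stats::pnorm((z - reg$lower[j]) / g$l_alpha) -
        stats::pnorm((z - reg$upper[j]) / g$l_alpha)
    }
  }
  colnames(out) <- c("solvent_below", paste0("layer_", seq_len(nreg - 2)), "solvent_above")
  out
}

#' Two-point layer occupation probabilities
#'
#' Joint probability that a point at height `z1` lies in layer `n` while a
#' point at height `z2`, laterally separated by `r_xy` and observed a time
#' `tau` later, lies in layer `m`. The two vertical displacements are
#' bivariate normal with standard deviation `l_alpha` and correlation
#' `g_W(r_xy, tau)`; the joint probabilities are bivariate-normal rectangle
#' probabilities. Solvent regions are included as in
#' [layer_probabilities()], so the matrix sums to 1.
#'
#' @inheritParams layer_probabilities
#' @param z1,z2 Heights in A (scalars).
#' @param r_xy Lateral separation in A (scalar).
#' @param tau Lag time in ns (scalar).
#' @return Square matrix of joint probabilities, `(n_layers + 2)` on each
#'   side.
#' @export
layer_pair_probabilities <- function(stack, g, z1, z2, r_xy, tau = 0) {
  stopifnot(inherits(stack, "layer_stack"), inherits(g, "gaussian_membrane"))
  reg <- stack_regions(stack)
  nreg <- length(reg$drho)
  p1 <- layer_probabilities(stack, g, z1)[1, ]
  p2 <- layer_probabilities(stack, g, z2)[1, ]
  rho <- gw_covariance(r_xy, tau, g)
  out <- matrix(0, nreg, nreg, dimnames = list(names(p1), names(p2)))
  if (g$l_alpha == 0) {
    out <- outer(p1, p2)  # deterministic: indicators factorize
    return(out)
  }
  for (jn in seq_len(nreg)) {
    for (jm in seq_len(nreg)) {
      # h1 in (z1 - upper_n, z1 - lower_n], h2 likewise
      out[jn, jm] <- bvn_rect(z1 - reg$upper[jn], z1 - reg$lower[jn],
                              z2 - reg$upper[jm], z2 - reg$lower[jm],
                              rho = rho, sd = g$l_alpha)
    }
  }
  out
}

# default z-quadrature grid: spacing <= min(layer thickness, l_alpha)/4,
# extent +-(stack half-width + 5 l_alpha)
#' @noRd
gaussian_z_grid <- function(stack, g) {
  half <- max(abs(range(stack$boundaries)))
  ext <- half + 5 * g$l_alpha
  thick <- diff(stack$boundaries)
  h <- min(c(thick / 4, if (g$l_alpha > 0) g$l_alpha / 4, ext / 50))
  h <- max(h, ext / 8000)  # guard against degenerate l_alpha
  seq(-ext, ext, by = h)
}

#' Average SLD profile of the fluctuating membrane
#'
#' `⟨rho⟩(z) - rho_solvent = sum_n (rho_n - rho_solvent) p_n(z)`: the slab
#' profile convolved with the normal displacement law of standard deviation
#' `l_alpha`.
#'
#' @inheritParams layer_probabilities
#' @return Numeric vector of solvent-contrasted mean SLDs at `z`.
#' @export
mean_sld_profile <- function(stack, g, z) {
  reg <- stack_regions(stack)
  drop(layer_probabilities(stack, g, z) %*% reg$drho)
}

#' Space-time correlation function of the fluctuating membrane
#'
#' Computes, per unit membrane area and with solvent-contrasted SLDs, the two
#' contributions to the SLD correlation function:
#' the average-structure term
#' `C_avg(r_z) = int ⟨rho⟩(z) ⟨rho⟩(z + r_z) dz` (self-convolution of the
#' mean profile, time independent), and the fluctuation term
#' `C_fluct(r_z, r_xy, tau) = sum_nm drho_n drho_m int dz
#' [P_nm(z, z + r_z; r_xy, tau) - p_n(z) p_m(z + r_z)]`,
#' evaluated by trapezoid z-quadrature on a grid extending 5 `l_alpha`
#' beyond the stack.
#'
#' @inheritParams layer_probabilities
#' @param r_z Vertical separations in A.
#' @param r_xy Lateral separations in A.
#' @param tau Lag time in ns (scalar).
#' @return A list with `c_avg` (vector along `r_z`, units 1/A^3) and
#'   `c_fluct` (matrix `length(r_z)` x `length(r_xy)`).
#' @export
membrane_correlation <- function(stack, g, r_z, r_xy, tau = 0) {
  stopifnot(inherits(stack, "layer_stack"), inherits(g, "gaussian_membrane"))
  z <- gaussian_z_grid(stack, g)
  wz <- trapz_weights(z)
  reg <- stack_regions(stack)
  drho <- reg$drho
  active <- which(drho != 0)
  mprof <- mean_sld_profile(stack, g, z)
  mprof_fun <- stats::approxfun(z, mprof, yleft = 0, yright = 0)
  c_avg <- vapply(r_z, function(rz) sum(wz * mprof * mprof_fun(z + rz)), numeric(1))
  c_fluct <- matrix(0, length(r_z), length(r_xy))
  if (g$l_alpha > 0 && length(active) > 0) {
    p_z <- layer_probabilities(stack, g, z)
    for (ir in seq_along(r_xy)) {
      rho_w <- gw_covariance(r_xy[ir], tau, g)
      for (iz in seq_along(r_z)) {
        z2 <- z + r_z[iz]
        p_z2 <- layer_probabilities(stack, g, z2)
        acc <- 0
        for (jn in active) {
          for (jm in active) {
            pnm <- bvn_rect(z - reg$upper[jn], z - reg$lower[jn],
                            z2 - reg$upper[jm], z2 - reg$lower[jm],
                            rho = rho_w, sd = g$l_alpha)
            acc <- acc + drho[jn] * drho[jm] *
              sum(wz * (pnm - p_z[, jn] * p_z2[, jm]))
          }
        }
        c_fluct[iz, ir] <- acc
      }
    }
  }
  list(c_avg = c_avg, c_fluct = c_fluct, r_z = r_z, r_xy = r_xy, tau = tau)
}

# ---------------------------------------------------------------------------
# Reciprocal-space machinery.
#
# The clipped-profile statistics admit an exact Hermite (Mehler) expansion:
# with F the solvent-contrasted slab profile and (h1, h2) bivariate normal
# with sd l_alpha and correlation gw,
#   Cov[F(z - h1), F(z' - h2)] summed over z admits the r_z-Fourier transform
#   |F(q_z)|^2 exp(-q_z^2 l_alpha^2) sum_(k>=1) (q_z l_alpha)^(2k)/k! gw^k.
# Each term's lateral Hankel transform is closed-form for powers of the
# Gaussian covariance, giving a fast, quadrature-free fluctuation intensity.
# ---------------------------------------------------------------------------

#' @noRd
hermite_k_max <- function(x_max) {
  ceiling(x_max + 12 * sqrt(x_max + 1) + 15)
}

# Fluctuation intensity of the bare membrane at one scattering vector q:
# (integral over mu in [0,1]) |F(q mu)|^2 e^{-x} sum_k x^k/k! * Ghat_k(q_xy)
# with x = (q mu l_alpha)^2 and
# Ghat_k(q_xy) = (4 pi l_xy^2 / k) s^(1-k) exp(-q_xy^2 l_xy^2 s / k).
#' @noRd
gaussian_fluct_intensity <- function(stack, g, q, tau = 0, n_mu = 64) {
  if (g$l_alpha == 0) return(rep(0, length(q)))
  gl <- gl_nodes(n_mu, 0, 1)
  s <- 1 + g$d * tau / g$l_xy^2
  vapply(q, function(qi) {
    k_max <- hermite_k_max((qi * g$l_alpha)^2)
    k <- seq_len(k_max)
    amp2 <- Mod(slab_amplitude(stack, qi * gl$x, reference_sld = "solvent"))^2
    x <- (qi * gl$x * g$l_alpha)^2
    q_xy2 <- qi^2 * pmax(1 - gl$x^2, 0)
    # poisson_w[k, mu] = e^{-x} x^k / k!
    poisson_w <- vapply(x, function(xi) stats::dpois(k, xi), numeric(k_max))
    ghat <- (4 * pi * g$l_xy^2 / k) * s^(1 - k) *
      exp(-outer(1 / k, q_xy2 * g$l_xy^2 * s))  # k x mu
    colSums(poisson_w * ghat) -> series  # per-mu sum over k
    sum(gl$w * amp2 * series)
  }, numeric(1))
}

#' Elastic/inelastic intensity of the Gaussian membrane
#'
#' Per-unit-area intensity of the fluctuating membrane (no proteins): the
#' average-structure term is the slab intensity of the mean profile
#' (`|rho(q)|^2 exp(-q^2 l_alpha^2)`, times `2 pi / q^2`), and the
#' fluctuation term is evaluated through the Hermite expansion of the
#' clipped-profile covariance, rotationally averaged over the membrane
#' orientation. The fluctuation term is a variance and is nonnegative, so
#' the total is bounded below by the average-structure term; for
#' `l_alpha -> 0` the total reduces to [slab_intensity()].
#'
#' @param stack A [layer_stack()] or [symmetric_bilayer()].
#' @param g A [gaussian_membrane()].
#' @param q Positive scattering vector grid in 1/A.
#' @param tau Lag time in ns.
#' @param radiation Radiation label for the returned curve.
#' @param n_mu Gauss-Legendre order of the orientation average.
#' @return A [scattering_curve()] with attributes `average` and `fluct`
#'   holding the two per-term intensity vectors (`i = average + fluct`).
#' @export
gaussian_intensity <- function(stack, g, q, tau = 0,
                               radiation = c("neutron", "xray"), n_mu = 64) {
  radiation <- match.arg(radiation)
  stack <- as_layer_stack(stack)
  stopifnot(inherits(g, "gaussian_membrane"))
  q <- as.numeric(q)
  if (any(q <= 0)) stop("`q` must be strictly positive", call. = FALSE)
  amp2 <- Mod(slab_amplitude(stack, q, reference_sld = "solvent"))^2
  i_avg <- 2 * pi * amp2 * exp(-q^2 * g$l_alpha^2) / q^2
  # integrand even in mu: (1/2) int_-1^1 dmu = int_0^1 dmu
  i_fluct <- gaussian_fluct_intensity(stack, g, q, tau, n_mu)
  out <- scattering_curve(q, i_avg + i_fluct, radiation = radiation)
  attr(out, "average") <- i_avg
  attr(out, "fluct") <- i_fluct
  out
}

#' Normalized NSE curve of the (protein-laden) Gaussian membrane
#'
#' Intermediate scattering function `I(q, tau) / I(q, 0)` of the fluctuating
#' membrane. With proteins present, their neutron contrast is weak and they
#' enter only through the protein-corrected *average* layer SLDs; the
#' membrane term of the composed correlation function then fully determines
#' the NSE signal. The curve is monotone non-increasing in `tau` and decays
#' towards the plateau `I_average / I(q, 0)` once the wave packets have
#' diffused beyond their own size (`tau >> l_xy^2 / D`).
#'
#' @param stack A [layer_stack()] or [symmetric_bilayer()].
#' @param g A [gaussian_membrane()].
#' @param p Optional [protein_spec()]; when given, layer SLDs are replaced by
#'   their protein-corrected averages.
#' @param q Scattering vectors in 1/A.
#' @param tau Correlation times in ns (0 is added for normalization if
#'   absent).
#' @return An [isf_surface()] with attribute `plateau` (per-q large-tau
#'   limit).
#' @export
nse_curve <- function(stack, g, p = NULL, q, tau) {
  stack <- as_layer_stack(stack)
  stopifnot(inherits(g, "gaussian_membrane"))
  if (!is.null(p)) stack <- protein_corrected_slds(stack, p, "average")
  tau <- sort(unique(c(0, as.numeric(tau))))
  grid <- expand.grid(q = as.numeric(q), tau = tau)
  itau <- matrix(NA_real_, length(q), length(tau))
  for (j in seq_along(tau)) {
    cur <- gaussian_intensity(stack, g, q, tau = tau[j])
    itau[, j] <- cur$i
    if (j == 1) i0 <- cur$i
  }
  isf <- sweep(itau, 1, i0, "/")
  plateau <- 2 * pi * Mod(slab_amplitude(stack, q, "solvent"))^2 *
    exp(-q^2 * g$l_alpha^2) / q^2 / i0
  out <- isf_surface(grid$q, grid$tau, as.vector(isf))
  attr(out, "plateau") <- plateau
  out
}

#' Membrane roughness factor
#'
#' Mean ratio of the true membrane area to its projected area,
#' `E[sqrt(1 + |grad h|^2)]`. For the Gaussian covariance the per-axis slope
#' variance is `l_alpha^2 / (2 l_xy^2)`, so `|grad h|^2` is exponentially
#' distributed with mean `m = l_alpha^2 / l_xy^2` and the expectation is a
#' one-dimensional integral evaluated numerically. Equals 1 for a flat
#' membrane and increases with `l_alpha / l_xy`.
#'
#' @param g A [gaussian_membrane()].
#' @return Dimensionless roughness factor `>= 1`.
#' @export
roughness_factor <- function(g) {
  stopifnot(inherits(g, "gaussian_membrane"))
  if (g$l_alpha == 0) return(1)
  m <- g$l_alpha^2 / g$l_xy^2
  stats::integrate(function(v) sqrt(1 + v) * exp(-v / m) / m,
                   0, Inf, rel.tol = 1e-10)$value
}
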