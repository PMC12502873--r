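# The central construction: combine a membrane correlation model with an
# independent in-plane protein model. With statistically independent membrane
# and protein structures, the SLD correlation function of the composite is
#
#   C_rho(r, tau) = C_a(r, tau) + C_p(r_xy, tau) * C_c(r, tau)
#
# where C_a and C_c are the membrane correlations computed with the
# protein-corrected *average* and *contrast* layer SLDs, and C_p is the
# in-plane correlation of the protein cylinder phase.

#' Compose membrane and protein correlation functions
#'
#' Real-space composition rule for membranes with included proteins:
#' `C_rho = C_a + C_p * C_c`, applied on a common `(r_z, r_xy)` grid. The
#' membrane correlations must have been computed with the protein-corrected
#' average (`c_avg`) and contrast (`c_contrast`) SLDs respectively; `c_p` is
#' the in-plane protein correlation sampled on the same `r_xy` grid. The
#' protein term is linear in `c_p`, and the composite reduces to the bare
#' average-SLD membrane whenever `c_p` or the contrast correlation vanishes.
#'
#' @param c_avg Membrane correlation with average SLDs: matrix
#'   (`length(r_z)` x `length(r_xy)`) or vector along `r_z` (laterally
#'   uniform membrane, recycled across `r_xy`).
#' @param c_contrast Membrane correlation with contrast SLDs, same
#'   conventions as `c_avg`.
#' @param c_p In-plane protein correlation, one value per `r_xy`.
#' @return Matrix `length(r_z)` x `length(r_xy)` of composite correlations.
#' @export
correlation_with_proteins <- function(c_avg, c_contrast, c_p) {
  c_p <- as.numeric(c_p)
  n_xy <- length(c_p)
  to_mat <- function(x, name) {
    if (is.matrix(x)) {
      if (ncol(x) != n_xy) {
        stop(sprintf("`%s` has %d column(s) but `c_p` has %d value(s)",
                     name, ncol(x), n_xy), call. = FALSE)
      }
      x
    } else {
      matrix(rep(as.numeric(x), n_xy), length(x), n_xy)
    }
  }
  ca <- to_mat(c_avg, "c_avg")
  cc <- to_mat(c_contrast, "c_contrast")
  if (!all(dim(ca) == dim(cc))) {
    stop("`c_avg` and `c_contrast` grids do not match", call. = FALSE)
  }
  ca + sweep(cc, 2, c_p, `*`)
}

# ---------------------------------------------------------------------------
# Reciprocal-space evaluation for the Gaussian membrane path.
#
# The protein term needs the lateral Hankel transforms
#   H_k(q_xy) = int 2 pi r J0(q_xy r) C_p(r, tau) g_W(r, tau)^k dr,  k >= 0,
# (k = 0 is the plain in-plane intensity I_p). They are evaluated once on a
# q_xy grid by a single Bessel-matrix product and interpolated afterwards.
# ---------------------------------------------------------------------------

#' @noRd
protein_hankel_table <- function(p, g, tau, k_max, q_xy_grid, n_r = 2048) {
  r_max <- max(8 * g$l_xy + 6 * sqrt(2 * g$d * tau),
               max(inplane_r_grid(p, tau)))
  # quantize the radial extent so the Bessel matrix is reusable across
  # nearby l_xy values (e.g. optimizer iterations); only adds margin
  r_max <- 128 * ceiling(r_max / 128)
  r <- seq(0, r_max, length.out = n_r)
  cp <- boolean_correlation(r, p, tau)
  gw <- gw_covariance(r, tau, g)
  # columns k = 0 .. k_max of C_p * g^k
  mat <- cp * outer(gw, 0:k_max, `^`)
  key <- sprintf("bess0_%g_%d_%d_%g", r_max, n_r, length(q_xy_grid), max(q_xy_grid))
  bess <- .memsas_env[[key]]
  if (is.null(bess)) {
    bess <- outer(q_xy_grid, r, function(qq, rr) besselJ(qq * rr, 0))
    .memsas_env[[key]] <- bess
  }
  w <- trapz_weights(r) * 2 * pi * r
  bess %*% (w * mat)  # length(q_xy_grid) x (k_max + 1)
}

# closed-form lateral transforms of g_W^k (k >= 1) for the bare fluctuation
# term: Ghat_k(q_xy) = (4 pi l_xy^2 / k) s^(1-k) exp(-q_xy^2 l_xy^2 s / k)
#' @noRd
gw_power_hankel <- function(g, tau, k, q_xy) {
  s <- 1 + g$d * tau / g$l_xy^2
  m <- exp(-outer(q_xy^2 * g$l_xy^2 * s, 1 / k))  # q rows, k columns
  sweep(m, 2, (4 * pi * g$l_xy^2 / k) * s^(1 - k), `*`)
}

# protein term of the Gaussian-membrane intensity (per unit area), by
# orientation average of |rho_c(q mu)|^2 e^{-x} sum_k x^k/k! H_k(q_xy)
#' @noRd
gaussian_protein_term <- function(stack_con, p, g, q, tau = 0, n_mu = 64) {
  if (all(stack_con$sld == 0) || p$phi_p == 0) return(rep(0, length(q)))
  if (p$lateral_model != "boolean") {
    stop("the Gaussian-membrane protein term requires the Boolean lateral model ",
         "(a real-space in-plane correlation function)", call. = FALSE)
  }
  k_max <- hermite_k_max((max(q) * g$l_alpha)^2)
  q_xy_grid <- seq(0, max(q), length.out = 512)
  H <- protein_hankel_table(p, g, tau, k_max, q_xy_grid)
  gl <- gl_nodes(n_mu, 0, 1)
  dq <- q_xy_grid[2] - q_xy_grid[1]
  vapply(q, function(qi) {
    amp2 <- Mod(slab_amplitude(stack_con, qi * gl$x, reference_sld = 0))^2
    x <- (qi * gl$x * g$l_alpha)^2
    q_xy <- qi * sqrt(pmax(1 - gl$x^2, 0))
    # linear interpolation indices into the H table, shared by all k
    pos <- pmin(pmax(q_xy / dq, 0), length(q_xy_grid) - 1 - 1e-9)
    i0 <- floor(pos) + 1
    tfrac <- pos - (i0 - 1)
    kk <- 0:(ncol(H) - 1)
    series <- vapply(seq_along(gl$x), function(j) {
      hrow <- (1 - tfrac[j]) * H[i0[j], ] + tfrac[j] * H[i0[j] + 1, ]
      sum(stats::dpois(kk, x[j]) * hrow)
    }, numeric(1))
    sum(gl$w * amp2 * series)
  }, numeric(1))
}

#' Membrane intensity with protein inclusions (slab or Gaussian membrane)
#'
#' Evaluates the composed model's rotationally averaged per-unit-area
#' intensity for either membrane model, decomposed into the membrane
#' (average-SLD) term and the protein (contrast x in-plane) term.
#' The slab path works entirely in reciprocal space
#' ([slab_intensity_with_proteins()]); the Gaussian path combines the
#' Hermite-expanded fluctuation statistics with the lateral Hankel
#' transforms of `C_p * g_W^k`. The two paths coincide when `l_alpha = 0`.
#'
#' @param model `"slab"` or `"gaussian"`.
#' @param b A [symmetric_bilayer()] or [layer_stack()].
#' @param g A [gaussian_membrane()] (required for the Gaussian path; ignored
#'   for the slab path).
#' @param p A [protein_spec()].
#' @param q Positive scattering vector grid in 1/A.
#' @param tau Lag time in ns.
#' @param radiation Radiation label for the returned curves.
#' @param n_mu Gauss-Legendre order of the orientation average.
#' @return A list with [scattering_curve()] components `total`, `membrane`
#'   and `protein` (`total = membrane + protein` exactly).
#' @export
intensity_with_proteins <- function(model = c("slab", "gaussian"), b, g = NULL, p,
                                    q, tau = 0, radiation = c("neutron", "xray"),
                                    n_mu = 64) {
  model <- match.arg(model)
  radiation <- match.arg(radiation)
  if (model == "slab") {
    return(slab_intensity_with_proteins(b, p, q, tau, radiation, n_mu))
  }
  stack <- as_layer_stack(b)
  if (is.null(g)) stop("the Gaussian path needs `g`", call. = FALSE)
  stopifnot(inherits(g, "gaussian_membrane"), inherits(p, "protein_spec"))
  q <- as.numeric(q)
  if (any(q <= 0)) stop("`q` must be strictly positive", call. = FALSE)
  stack_avg <- protein_corrected_slds(stack, p, "average")
  stack_con <- protein_corrected_slds(stack, p, "contrast")
  membrane <- gaussian_intensity(stack_avg, g, q, tau, radiation, n_mu)
  i_protein <- gaussian_protein_term(stack_con, p, g, q, tau, n_mu)
  total <- scattering_curve(q, membrane$i + i_protein, radiation = radiation)
  list(total = total,
       membrane = scattering_curve(q, membrane$i, radiation = radiation),
       protein = scattering_curve(q, i_protein, radiation = radiation))
}
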