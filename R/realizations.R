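# Stochastic simulator: voxelized space(-time) realizations of the membrane
# model (height field + Boolean protein discs) and an FFT-based numerical
# scattering oracle for cross-checking the analytic intensities.

# Run expr with a local RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @noRd
# fft mode ordering: 0, 1, ..., n/2, -(n/2 - 1), ..., -1 (times 2 pi / L)
fft_freqs <- function(n, l_box) {
  2 * pi / l_box * c(0:(n / 2), -((n / 2 - 1):1))[1:n]
}

#' Sample periodic Gaussian height fields
#'
#' Spectral synthesis of the membrane height field `h = l_alpha W` on a
#' periodic `n x n` grid over a box of side `l_box`: independent Fourier
#' modes with variance proportional to the spectral density
#' `S(k) = l_alpha^2 4 pi l_xy^2 exp(-k^2 l_xy^2)` of the packet covariance.
#' For a time sequence, each mode evolves as a stationary Ornstein-Uhlenbeck
#' process with decay rate `D k^2`, reproducing the diffusive decorrelation
#' `exp(-D k^2 tau)` of [gw_covariance()]. Fully reproducible from `seed`
#' (the caller's RNG state is untouched).
#'
#' @param g A [gaussian_membrane()].
#' @param l_box Box side in A; should be at least `8 l_xy` (a warning is
#'   emitted otherwise, as the periodic box then truncates the covariance).
#' @param n Grid points per side (a power of two).
#' @param seed Integer seed.
#' @param times Sorted times in ns at which to return the field.
#' @return A list with `fields` (list of `n x n` matrices, one per time),
#'   `times`, `l_box`, `n` and the grid spacing `dx`.
#' @export
sample_height_field <- function(g, l_box, n, seed, times = 0) {
  stopifnot(inherits(g, "gaussian_membrane"))
  if (n < 4 || bitwAnd(n, n - 1L) != 0) stop("`n` must be a power of two", call. = FALSE)
  if (l_box < 8 * g$l_xy) {
    warning("`l_box` below 8 l_xy: the periodic box truncates the lateral covariance",
            call. = FALSE)
  }
  times <- as.numeric(times)
  if (is.unsorted(times) || any(times < 0)) {
    stop("`times` must be sorted and nonnegative", call. = FALSE)
  }
  k1 <- fft_freqs(n, l_box)
  k2 <- outer(k1^2, k1^2, `+`)
  amp <- (n / l_box) * sqrt(g$l_alpha^2 * gw_spectral_density(sqrt(k2), g))
  spec_of_noise <- function() stats::fft(matrix(stats::rnorm(n * n), n, n)) * amp
  fields <- with_seed(seed, {
    H <- spec_of_noise()
    out <- vector("list", length(times))
    t_prev <- times[1]
    for (j in seq_along(times)) {
      if (j > 1) {
        dt <- times[j] - t_prev
        if (dt > 0) {
          decay <- exp(-g$d * k2 * dt)
          H <- H * decay + spec_of_noise() * sqrt(1 - decay^2)
        }
        t_prev <- times[j]
      }
      out[[j]] <- Re(stats::fft(H, inverse = TRUE)) / n^2
    }
    out
  })
  list(fields = fields, times = times, l_box = l_box, n = n, dx = l_box / n)
}

#' Sample Boolean protein disc centres
#'
#' Poisson number of centres (mean `theta_p l_box^2`) at uniform positions in
#' the periodic box; for later times each centre performs an independent 2D
#' Brownian motion with diffusion coefficient `d_p` (per-axis step variance
#' `2 d_p dt`), wrapped periodically. Elliptical cross-sections get one fixed
#' uniform orientation per grain.
#'
#' @param p A [protein_spec()] with `lateral_model = "boolean"`.
#' @param l_box Box side in A.
#' @param seed Integer seed.
#' @param times Sorted times in ns.
#' @return A list with `centres` (list of `N x 2` matrices, one per time),
#'   `angles` (per-grain orientation, radians), `times` and `l_box`.
#' @export
sample_boolean_discs <- function(p, l_box, seed, times = 0) {
  stopifnot(inherits(p, "protein_spec"))
  if (p$lateral_model != "boolean") {
    stop("disc sampling implements the Boolean (overlapping) model only", call. = FALSE)
  }
  times <- as.numeric(times)
  if (is.unsorted(times) || any(times < 0)) {
    stop("`times` must be sorted and nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    n_p <- stats::rpois(1, p$theta_p * l_box^2)
    xy <- matrix(stats::runif(2 * n_p, 0, l_box), ncol = 2)
    angles <- stats::runif(n_p, 0, pi)
    centres <- vector("list", length(times))
    centres[[1]] <- xy
    if (length(times) > 1) {
      for (j in 2:length(times)) {
        dt <- times[j] - times[j - 1]
        if (dt > 0 && p$d_p > 0 && n_p > 0) {
          xy <- xy + matrix(stats::rnorm(2 * n_p, sd = sqrt(2 * p$d_p * dt)), ncol = 2)
          xy <- xy %% l_box
        }
        centres[[j]] <- xy
      }
    }
    list(centres = centres, angles = angles, times = times, l_box = l_box)
  })
}

# lateral occupancy mask (n x n logical) of the protein phase
#' @noRd
protein_mask <- function(p, centres, angles, l_box, n) {
  mask <- matrix(FALSE, n, n)
  if (is.null(centres) || nrow(centres) == 0) return(mask)
  dx <- l_box / n
  xg <- (seq_len(n) - 0.5) * dx
  half <- if (p$shape$type == "disc") p$shape$r_p else p$shape$a
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    ix <- which(pmin(abs(xg - cx), l_box - abs(xg - cx)) <= half)
    iy <- which(pmin(abs(xg - cy), l_box - abs(xg - cy)) <= half)
    if (!length(ix) || !length(iy)) next
    ddx <- xg[ix] - cx; ddx <- ddx - l_box * round(ddx / l_box)
    ddy <- xg[iy] - cy; ddy <- ddy - l_box * round(ddy / l_box)
    if (p$shape$type == "disc") {
      sub <- outer(ddx^2, ddy^2, `+`) <= p$shape$r_p^2
    } else {
      ca <- cos(angles[i]); sa <- sin(angles[i])
      u <- outer(ddx * ca, ddy * sa, `+`)   # rotated coordinates
      v <- outer(-ddx * sa, ddy * ca, `+`)
      sub <- (u / p$shape$a)^2 + (v / p$shape$b)^2 <= 1
    }
    mask[ix, iy] <- mask[ix, iy] | sub
  }
  mask
}

# cumulative integral C(z) = int_-inf^z of the piecewise-constant contrast
# profile defined by `boundaries` and per-layer values `drho` (0 outside);
# returns a vectorized closure (piecewise linear, closed form)
#' @noRd
profile_cumint <- function(boundaries, drho) {
  nl <- length(drho)
  if (nl == 0) return(function(z) rep(0, length(z)))
  a_lo <- boundaries[-(nl + 1)]
  a_hi <- boundaries[-1]
  cum0 <- c(0, cumsum(drho * (a_hi - a_lo)))
  function(z) {
    j <- findInterval(z, boundaries)  # 0 .. nl + 1
    inside <- j >= 1 & j <= nl
    out <- numeric(length(z))
    out[j > nl] <- cum0[nl + 1]
    if (any(inside)) {
      ji <- j[inside]
      out[inside] <- cum0[ji] + drho[ji] * (z[inside] - a_lo[ji])
    }
    out
  }
}

#' Voxelize one realization of the membrane model
#'
#' Builds the solvent-contrasted SLD on a 3D voxel grid: the layer stack is
#' displaced vertically by the height field, and inside the protein phase the
#' per-layer membrane SLDs are replaced by the per-layer protein SLDs
#' (solvent above and below the displaced stack in both phases). Each voxel
#' stores the exact volume average of the displaced profile over its vertical
#' extent (partial-volume voxelization), so the only z-discretization effect
#' on the FFT amplitude is the analytic box-filter factor `sinc(q_z dz / 2)`.
#'
#' @param stack A [layer_stack()] or [symmetric_bilayer()].
#' @param height `n x n` height matrix in A (`NULL` for a flat slab).
#' @param coverage `n x n` protein coverage fractions in `[0, 1]` (`NULL`
#'   for no proteins); voxel SLDs mix the two phases linearly, which is
#'   exact for the scattering amplitude.
#' @param p [protein_spec()] supplying the per-layer protein SLDs (required
#'   when `coverage` is given).
#' @param z_lim Half-extent of the z box in A.
#' @param dz Vertical voxel size in A; must resolve the thinnest layer
#'   (`dz <= min layer thickness / 2`, else an error).
#' @param n Lateral grid points per side.
#' @return 3D array `n x n x nz` of solvent-contrasted SLDs, with attributes
#'   `dz` and `z_lim`.
#' @export
voxelize_realization <- function(stack, height = NULL, coverage = NULL, p = NULL,
                                 z_lim, dz, n) {
  stack <- as_layer_stack(stack)
  if (n_layers(stack) > 0 && dz > min(diff(stack$boundaries)) / 2) {
    stop("vertical voxel size `dz` exceeds half the thinnest layer (under-resolved profile)",
         call. = FALSE)
  }
  nz <- 2 * ceiling(z_lim / dz)
  zg <- (seq_len(nz) - 0.5 - nz / 2) * dz
  drho_m <- stack$sld - stack$solvent_sld
  cum_m <- profile_cumint(stack$boundaries, drho_m)
  cum_p <- NULL
  if (!is.null(coverage)) {
    if (is.null(p)) stop("`p` is required when protein coverage is given", call. = FALSE)
    rho_p <- p$rho_p
    if (length(rho_p) == 1L) rho_p <- rep(rho_p, n_layers(stack))
    cum_p <- profile_cumint(stack$boundaries, rho_p - stack$solvent_sld)
  }
  if (is.null(height)) height <- matrix(0, n, n)
  hv <- as.vector(height)
  cv <- if (is.null(coverage)) NULL else as.vector(coverage)
  vox <- array(0, c(n, n, nz))
  for (iz in seq_len(nz)) {
    zlo <- zg[iz] - dz / 2 - hv
    zhi <- zg[iz] + dz / 2 - hv
    vals <- (cum_m(zhi) - cum_m(zlo)) / dz
    if (!is.null(cv)) {
      vals_p <- (cum_p(zhi) - cum_p(zlo)) / dz
      vals <- (1 - cv) * vals + cv * vals_p
    }
    vox[, , iz] <- matrix(vals, n, n)
  }
  attr(vox, "dz") <- dz
  attr(vox, "z_lim") <- z_lim
  vox
}

#' Lateral protein coverage fractions on the voxel grid
#'
#' Rasterizes the Boolean grains onto a grid supersampled by `factor` and
#' block-averages it down to `n x n` coverage fractions.
#'
#' @param p A [protein_spec()].
#' @param centres `N x 2` matrix of grain centres in A.
#' @param angles Per-grain orientations in radians (ellipses).
#' @param l_box Box side in A.
#' @param n Target lateral grid points per side.
#' @param factor Integer supersampling factor.
#' @return `n x n` matrix of coverage fractions in `[0, 1]`.
#' @export
protein_coverage <- function(p, centres, angles, l_box, n, factor = 4) {
  fine <- protein_mask(p, centres, angles, l_box, n * factor)
  if (factor == 1) return(fine + 0)
  # block-average factor x factor cells
  m <- matrix(0, n, n)
  for (i in seq_len(factor)) {
    for (j in seq_len(factor)) {
      m <- m + fine[seq(i, n * factor, by = factor), seq(j, n * factor, by = factor)]
    }
  }
  m / factor^2
}

#' FFT scattering intensity of a voxelized realization
#'
#' 3D FFT of the voxel SLD array, squared modulus normalized per unit
#' projected membrane area (`|A(q)|^2 / l_box^2` with `A` the Riemann-sum
#' Fourier amplitude), binned into isotropic `q` shells. When an analytic
#' 3D mode-intensity function is supplied it is averaged over exactly the
#' same discrete modes, which removes all shell-binning bias from the
#' comparison.
#'
#' @param vox Voxel array from [voxelize_realization()].
#' @param l_box Lateral box side in A.
#' @param q_edges Increasing shell edges in 1/A.
#' @param analytic Optional function `f(q_z, q_xy)` returning the model's 3D
#'   mode intensity (per unit area), co-averaged over the same modes.
#' @return A data frame with `q` (mean mode modulus per shell), `i`
#'   (mean FFT intensity), `n_modes`, and `i_analytic` when requested.
#' @export
fft_intensity <- function(vox, l_box, q_edges, analytic = NULL) {
  n <- dim(vox)[1]
  nz <- dim(vox)[3]
  dz <- attr(vox, "dz")
  dx <- l_box / n
  lz <- nz * dz
  amp <- stats::fft(vox) * dx * dx * dz
  i3 <- Mod(amp)^2 / l_box^2
  kxy <- fft_freqs(n, l_box)
  kz <- fft_freqs(nz, lz)
  q_xy2 <- outer(kxy^2, kxy^2, `+`)
  qmod <- sqrt(outer(as.vector(q_xy2), kz^2, `+`))
  sel <- qmod >= q_edges[1] & qmod < q_edges[length(q_edges)]
  sel[1, 1] <- FALSE  # exclude the q = 0 mode
  nb <- length(q_edges) - 1L
  bin <- factor(findInterval(qmod[sel], q_edges), levels = seq_len(nb))
  ivals <- as.vector(i3)[sel]
  qvals <- qmod[sel]
  out <- data.frame(
    q = as.vector(tapply(qvals, bin, mean)),
    i = as.vector(tapply(ivals, bin, mean)),
    n_modes = as.vector(tapply(ivals, bin, function(v) length(v)))
  )
  if (!is.null(analytic)) {
    ia <- if (is.array(analytic)) {
      analytic[sel]
    } else {
      qxy_modes <- matrix(rep(as.vector(sqrt(q_xy2)), nz), n * n, nz)[sel]
      qz_modes <- matrix(rep(kz, each = n * n), n * n, nz)[sel]
      analytic(qz_modes, qxy_modes)
    }
    out$i_analytic <- as.vector(tapply(ia, bin, mean))
  }
  out[!is.na(out$q), , drop = FALSE]
}

#' Analytic 3D mode intensity of the composed model
#'
#' Returns a function `f(q_z, q_xy)` giving the model's 3D intensity (per
#' unit projected area) at discrete periodic-box modes, for use as the
#' `analytic` co-average in [fft_intensity()]. The laterally uniform
#' (average-structure) part lives on the `q_xy = 0` modes with weight
#' `l_box^2 |rho_a(q_z)|^2 exp(-q_z^2 l_alpha^2)`; the fluctuation and
#' protein parts are smooth in `q_xy`.
#'
#' @param stack A [layer_stack()] or [symmetric_bilayer()].
#' @param g A [gaussian_membrane()] or `NULL` for the static slab.
#' @param p A [protein_spec()] or `NULL`.
#' @param l_box Lateral box side in A (weight of the on-axis delta modes).
#' @param tau Lag time in ns.
#' @param q_xy_max Upper bound of lateral mode moduli that will be queried.
#' @param q_max Largest total mode modulus that will be queried in 1/A (sets
#'   the Hermite series order).
#' @return A vectorized function of `(q_z, q_xy)`.
#' @export
analytic_mode_intensity <- function(stack, g = NULL, p = NULL, l_box,
                                    tau = 0, q_xy_max = 1, q_max = 0.6) {
  stack <- as_layer_stack(stack)
  if (is.null(g)) g <- gaussian_membrane(0, 1, 0)
  stack_avg <- if (is.null(p)) stack else protein_corrected_slds(stack, p, "average")
  stack_con <- if (is.null(p)) NULL else protein_corrected_slds(stack, p, "contrast")
  la <- g$l_alpha
  k_max <- if (la > 0) hermite_k_max((q_max * la)^2) else 0
  q_grid <- seq(0, q_xy_max, length.out = 1024)
  H <- if (!is.null(stack_con) && any(stack_con$sld != 0)) {
    protein_hankel_table(p, g, tau, max(k_max, 0), q_grid)
  } else NULL
  G <- if (la > 0) gw_power_hankel(g, tau, seq_len(k_max), q_grid) else NULL
  interp_cols <- function(tab, q_xy, col_idx) {
    dq <- q_grid[2] - q_grid[1]
    pos <- pmin(pmax(q_xy / dq, 0), length(q_grid) - 1 - 1e-9)
    i0 <- floor(pos) + 1
    tf <- pos - (i0 - 1)
    (1 - tf) * tab[cbind(i0, col_idx)] + tf * tab[cbind(i0 + 1, col_idx)]
  }
  function(q_z, q_xy) {
    amp2a <- Mod(slab_amplitude(stack_avg, q_z, "solvent"))^2
    dw <- exp(-q_z^2 * la^2)
    out <- ifelse(q_xy < 1e-12, l_box^2 * amp2a * dw, 0)
    x <- (q_z * la)^2
    if (!is.null(G)) {
      for (k in seq_len(k_max)) {
        wk <- stats::dpois(k, x)
        live <- wk > 1e-18
        if (!any(live)) next
        out[live] <- out[live] + amp2a[live] * wk[live] *
          interp_cols(G, q_xy[live], rep(k, sum(live)))
      }
    }
    if (!is.null(H)) {
      amp2c <- Mod(slab_amplitude(stack_con, q_z, 0))^2
      for (k in 0:(ncol(H) - 1)) {
        wk <- stats::dpois(k, x)
        live <- wk > 1e-18 & amp2c > 0
        if (!any(live)) next
        out[live] <- out[live] + amp2c[live] * wk[live] *
          interp_cols(H, q_xy[live], rep(k + 1, sum(live)))
      }
    }
    out
  }
}

#' Export a sampled field as a flat binary array with a JSON sidecar
#'
#' Writes the matrix (or 3D array) as little-endian doubles in
#' column-major order, plus a `<path>.json` sidecar recording dimensions,
#' grid geometry and provenance, so the array can be reread from any
#' language.
#'
#' @param field Numeric matrix or array (e.g. a height field from
#'   [sample_height_field()], or a voxel array).
#' @param path Output path for the binary payload.
#' @param meta Named list of extra metadata for the sidecar.
#' @return The path, invisibly.
#' @export
write_realization <- function(field, path, meta = list()) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(as.numeric(field)), con, size = 8, endian = "little")
  sidecar <- c(list(dtype = "float64", endian = "little",
                    order = "column-major", dim = dim(field)), meta)
  write_atomic(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               paste0(path, ".json"))
  invisible(path)
}

# Exact finite-box analytic 3D mode intensity for the Gaussian membrane:
# the synthesized lattice field has covariance c(r) = (1/L^2) sum_k S(k)
# exp(i k r) exactly, so for each q_z plane the lateral spectrum of the
# clipped-profile statistics is the 2D DFT of
#   exp(-q_z^2 (sigma^2 - c(r))) - exp(-q_z^2 sigma^2)        (fluctuations)
#   C_p(r) exp(-q_z^2 (sigma^2 - c(r)))                        (protein term)
# with sigma^2 = c(0). This removes the continuum-vs-lattice discretization
# bias from oracle comparisons (the lateral spectrum is only ~1 mode
# spacing wide at l_xy ~ L / 8).
#' @noRd
lattice_mode_i3 <- function(stack, g, p, l_box, n, nz, dz, tau = 0, q_max = 0.6,
                            coverage_factor = 4) {
  if (is.null(g)) g <- gaussian_membrane(0, 1, 0)
  stack_avg <- if (is.null(p)) stack else protein_corrected_slds(stack, p, "average")
  stack_con <- if (is.null(p)) NULL else protein_corrected_slds(stack, p, "contrast")
  k1 <- fft_freqs(n, l_box)
  dx <- l_box / n
  if (g$l_alpha > 0) {
    kmat2 <- outer(k1^2, k1^2, `+`)
    svals <- g$l_alpha^2 * gw_spectral_density(sqrt(kmat2), g)
    cmat <- Re(stats::fft(svals, inverse = TRUE)) / l_box^2
  } else {
    cmat <- matrix(0, n, n)
  }
  sigma2 <- cmat[1, 1]
  kz <- fft_freqs(nz, nz * dz)
  # min-image lattice distances for C_p
  rr <- pmin(abs((seq_len(n) - 1) * dx), l_box - abs((seq_len(n) - 1) * dx))
  rmat <- sqrt(outer(rr^2, rr^2, `+`))
  cp_mat <- if (is.null(stack_con) || all(stack_con$sld == 0)) NULL else {
    matrix(boolean_correlation(as.vector(rmat), p, tau), n, n)
  }
  # lateral filter of the supersampled block-averaged coverage field:
  # per axis, the mean of `coverage_factor` point samples across one cell
  cover_w2 <- if (is.null(cp_mat)) NULL else {
    f <- coverage_factor
    dker <- function(k) {
      out <- rep(1, length(k))
      nonz <- k != 0
      out[nonz] <- sin(k[nonz] * dx / 2) / (f * sin(k[nonz] * dx / (2 * f)))
      out
    }
    outer(dker(k1)^2, dker(k1)^2)
  }
  i3 <- array(0, c(n, n, nz))
  amp2a <- Mod(slab_amplitude(stack_avg, kz, "solvent"))^2
  amp2c <- if (is.null(stack_con)) NULL else Mod(slab_amplitude(stack_con, kz, 0))^2
  for (iz in seq_len(nz)) {
    if (abs(kz[iz]) > q_max) next
    x <- kz[iz]^2
    ew <- exp(-x * (sigma2 - cmat))
    plane <- amp2a[iz] * Re(stats::fft(ew - exp(-x * sigma2))) * dx^2
    plane[1, 1] <- plane[1, 1] + amp2a[iz] * exp(-x * sigma2) * l_box^2
    if (!is.null(cp_mat)) {
      plane <- plane + amp2c[iz] * cover_w2 * Re(stats::fft(cp_mat * ew)) * dx^2
    }
    i3[, , iz] <- plane
  }
  i3
}

#' Seed-averaged FFT intensity oracle
#'
#' Generates `n_seeds` independent realizations (height field and/or Boolean
#' discs), voxelizes each, and averages their FFT shell intensities;
#' standard errors are estimated from the seed-to-seed scatter. All
#' randomness derives from `seed` (one sub-seed per realization).
#'
#' @param b A [symmetric_bilayer()] or [layer_stack()].
#' @param g A [gaussian_membrane()] or `NULL` (static slab).
#' @param p A [protein_spec()] (Boolean model) or `NULL`.
#' @param l_box Lateral box side in A.
#' @param n Lateral grid points per side (power of two).
#' @param dz Vertical voxel size in A.
#' @param z_pad Extra solvent padding beyond the stack and `5 l_alpha`, in A.
#' @param q_edges Shell edges in 1/A.
#' @param n_seeds Number of independent realizations.
#' @param seed Master integer seed.
#' @param analytic Logical: co-average the analytic 3D mode intensity.
#' @return A data frame with `q`, `i` (seed mean), `se` (standard error),
#'   `n_modes`, and `i_analytic` when requested.
#' @export
voxelize_and_fft_intensity <- function(b, g = NULL, p = NULL, l_box, n, dz = 1,
                                       z_pad = 10, q_edges, n_seeds = 8, seed = 1,
                                       analytic = TRUE) {
  stack <- as_layer_stack(b)
  la <- if (is.null(g)) 0 else g$l_alpha
  half <- if (n_layers(stack) > 0) max(abs(range(stack$boundaries))) else 5
  z_lim <- half + 5 * la + z_pad
  nz <- 2 * ceiling(z_lim / dz)
  zsinc2 <- function(q_z) {
    # z box-filter of the partial-volume voxelization
    s <- rep(1, length(q_z))
    nonz <- q_z != 0
    s[nonz] <- (sin(q_z[nonz] * dz / 2) / (q_z[nonz] * dz / 2))^2
    s
  }
  afun <- if (!analytic) {
    NULL
  } else if ((!is.null(g) && g$l_alpha > 0) || !is.null(p)) {
    # exact lattice-field analytic (3D array over the box modes)
    i3a <- lattice_mode_i3(stack, g, p, l_box, n, nz, dz,
                           q_max = max(q_edges) * 1.01)
    kz <- fft_freqs(nz, nz * dz)
    sweep(i3a, 3, zsinc2(kz), `*`)
  } else {
    afun0 <- analytic_mode_intensity(stack, g, p, l_box,
                                     q_xy_max = max(q_edges) * 1.01,
                                     q_max = max(q_edges) * 1.01)
    function(q_z, q_xy) afun0(q_z, q_xy) * zsinc2(q_z)
  }
  acc <- NULL
  for (j in seq_len(n_seeds)) {
    sj <- seed * 1000L + j
    height <- if (!is.null(g) && g$l_alpha > 0) {
      sample_height_field(g, l_box, n, seed = sj)$fields[[1]]
    } else NULL
    cov <- if (!is.null(p)) {
      d <- sample_boolean_discs(p, l_box, seed = sj + 500L)
      protein_coverage(p, d$centres[[1]], d$angles, l_box, n)
    } else NULL
    vox <- voxelize_realization(stack, height, cov, p, z_lim = z_lim, dz = dz, n = n)
    res <- fft_intensity(vox, l_box, q_edges, analytic = afun)
    if (is.null(acc)) {
      acc <- res
      acc$i_sum <- res$i
      acc$i_sq <- res$i^2
    } else {
      acc$i_sum <- acc$i_sum + res$i
      acc$i_sq <- acc$i_sq + res$i^2
    }
  }
  acc$i <- acc$i_sum / n_seeds
  acc$se <- sqrt(pmax(acc$i_sq / n_seeds - acc$i^2, 0) / max(n_seeds - 1, 1))
  acc$i_sum <- NULL
  acc$i_sq <- NULL
  acc
}
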