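# Gaussian fluctuating-membrane model: covariance, layer probabilities,
# correlation functions, intensities, NSE curves and the roughness factor.

g_rbc <- gaussian_membrane(23, 63, 1.85)

test_that("height-field covariance has the stated normalization and limits", {
  expect_equal(gw_covariance(0, 0, g_rbc), 1)
  # static limit: D = 0 makes g_W tau-independent
  g0 <- gaussian_membrane(23, 63, 0)
  r <- c(0, 20, 63, 150)
  expect_equal(gw_covariance(r, 500, g0), gw_covariance(r, 0, g0))
  # Gaussian in r at tau = 0 with lateral scale l_xy
  expect_equal(gw_covariance(r, 0, g_rbc), exp(-r^2 / (4 * 63^2)))
  # diffusive broadening: amplitude decays, correlation widens
  c_late <- gw_covariance(r, 1000, g_rbc)
  expect_lt(c_late[1], 1)
  expect_gt(c_late[4] / c_late[1], gw_covariance(150, 0, g_rbc))
  expect_error(gw_covariance(10, -1, g_rbc), "nonnegative")
})

test_that("one- and two-point layer probabilities are proper distributions", {
  st <- expand_bilayer(rbc_bilayer("neutron"))
  z <- c(-40, -10, 0, 15, 40)
  lp <- layer_probabilities(st, g_rbc, z)
  expect_equal(rowSums(lp), rep(1, length(z)))
  expect_true(all(lp >= 0))
  # l_alpha -> 0: indicator of the layer containing z
  g_flat <- gaussian_membrane(0, 63, 0)
  lp0 <- layer_probabilities(st, g_flat, c(-30, -18, 0, 18, 30))
  expect_equal(unname(lp0[1, "solvent_below"]), 1)
  expect_equal(unname(lp0[2, "layer_1"]), 1)   # head layer
  expect_equal(unname(lp0[3, "layer_2"] + lp0[3, "layer_3"]), 1)  # chain region
  expect_equal(unname(lp0[5, "solvent_above"]), 1)

  # joint distribution sums to 1 (solvent included) at several configurations
  for (cfg in list(c(5, -3, 40, 10), c(-25, 30, 5, 0), c(0, 0, 500, 100))) {
    pp <- layer_pair_probabilities(st, g_rbc, cfg[1], cfg[2], cfg[3], cfg[4])
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    expect_true(all(pp >= -1e-12))
  }
  # full decorrelation: P_nm -> p_n p_m
  pp_far <- layer_pair_probabilities(st, g_rbc, 5, -3, 1e6, 0)
  p1 <- layer_probabilities(st, g_rbc, 5)[1, ]
  p2 <- layer_probabilities(st, g_rbc, -3)[1, ]
  expect_equal(pp_far, outer(p1, p2), tolerance = 1e-7)
  # perfect correlation at coincident points: diagonal equals p_n
  pp0 <- layer_pair_probabilities(st, g_rbc, 5, 5, 0, 0)
  expect_equal(diag(pp0), p1, tolerance = 1e-8)
  expect_lt(max(abs(pp0 - diag(diag(pp0)))), 1e-8)
})

test_that("membrane correlation matches direct single-point oracles", {
  st <- expand_bilayer(rbc_bilayer("neutron"))
  mc <- membrane_correlation(st, g_rbc, r_z = 0, r_xy = 0, tau = 0)
  # oracle: variance profile integral from the one-point probabilities
  z <- seq(-160, 160, by = 0.25)
  reg <- memsas:::stack_regions(st)
  p <- layer_probabilities(st, g_rbc, z)
  m1 <- drop(p %*% reg$drho)
  m2 <- drop(p %*% reg$drho^2)
  expect_equal(mc$c_avg[1], sum(m1^2) * 0.25, tolerance = 1e-5)
  expect_equal(mc$c_fluct[1, 1], sum((m2 - m1^2)) * 0.25, tolerance = 1e-5)

  # l_alpha -> 0: fluctuations vanish, average term equals slab self-convolution
  g_flat <- gaussian_membrane(0, 63, 0)
  mc0 <- membrane_correlation(st, g_flat, r_z = c(0, 10), r_xy = c(0, 50))
  expect_identical(max(abs(mc0$c_fluct)), 0)
  drho <- st$sld - st$solvent_sld
  slab_selfconv <- function(rz) {
    f <- function(z) {
      idx <- findInterval(z, st$boundaries)
      ifelse(idx >= 1 & idx <= 4, drho[pmax(idx, 1)], 0)
    }
    zg <- seq(-30, 30, by = 0.01)
    sum(f(zg) * f(zg + rz)) * 0.01
  }
  expect_equal(mc0$c_avg, c(slab_selfconv(0), slab_selfconv(10)), tolerance = 0.02)

  # lateral decorrelation kills the fluctuation term
  mcf <- membrane_correlation(st, g_rbc, r_z = 0, r_xy = c(0, 1e5))
  expect_lt(abs(mcf$c_fluct[1, 2]), 1e-10 * abs(mcf$c_fluct[1, 1]))
})

test_that("reciprocal-space fluctuation term matches the real-space transform", {
  # cross-validate the Hermite-series intensity against a brute-force
  # Fourier-Hankel transform of membrane_correlation on a small grid
  st <- expand_bilayer(rbc_bilayer("neutron", l_c = 8, l_h = 4))
  g <- gaussian_membrane(6, 40, 0)
  qi <- 0.12
  i_series <- memsas:::gaussian_fluct_intensity(st, g, qi, tau = 0, n_mu = 48)
  # real-space oracle: C_fluct on (r_z, r_xy), then cos-transform in r_z,
  # J0-Hankel in r_xy, and mu rotational average
  r_z <- seq(0, 64, by = 4)
  r_xy <- seq(0, 160, by = 8)
  mc <- membrane_correlation(st, g, r_z, r_xy)
  gl <- pracma::gaussLegendre(24, 0, 1)
  wz <- memsas:::trapz_weights(r_z)
  wx <- memsas:::trapz_weights(r_xy) * 2 * pi * r_xy
  oracle <- sum(gl$w * vapply(gl$x, function(mu) {
    qz <- qi * mu
    qxy <- qi * sqrt(1 - mu^2)
    # C_fluct is even in r_z: full-line cos transform = 2 x positive half
    fz <- drop(crossprod(mc$c_fluct, 2 * cos(qz * r_z) * wz))  # per r_xy
    sum(fz * besselJ(qxy * r_xy, 0) * wx)
  }, numeric(1)))
  expect_equal(i_series, oracle, tolerance = 0.02)
})

test_that("gaussian intensity limits: slab recovery, term ordering, smoothness", {
  b <- rbc_bilayer("neutron")
  st <- expand_bilayer(b)
  q <- fit_q_grid(50)
  # l_alpha -> 0 equals the slab intensity well within 0.5%
  gi0 <- gaussian_intensity(st, gaussian_membrane(0, 63, 0), q)
  expect_equal(gi0$i, slab_intensity(st, q)$i, tolerance = 1e-12)
  # total is bounded below by the average-structure term
  gi <- gaussian_intensity(st, g_rbc, q)
  expect_true(all(gi$i >= attr(gi, "average")))
  expect_true(all(attr(gi, "fluct") >= 0))
  expect_equal(gi$i, attr(gi, "average") + attr(gi, "fluct"))
  # smooth curve: no sign flips in the log-slope beyond numerical dust
  expect_true(all(is.finite(log(gi$i))))
})

test_that("NSE curves are normalized, monotone and plateau correctly", {
  b <- rbc_bilayer("neutron")
  p <- rbc_protein("neutron")
  taus <- c(0, 1, 5, 20, 80, 320, 1280, 2e6)
  sur <- nse_curve(b, g_rbc, p, q = c(0.036, 0.071, 0.109), tau = taus)
  expect_true(all(sur$isf[sur$tau == 0] == 1))
  # monotone non-increasing in tau at each q
  for (qv in unique(sur$q)) {
    isf_q <- sur$isf[sur$q == qv][order(sur$tau[sur$q == qv])]
    expect_true(all(diff(isf_q) <= 1e-12))
  }
  expect_true(all(sur$isf > 0 & sur$isf <= 1))
  # plateau equals the average-structure share of the tau = 0 intensity
  plateau <- attr(sur, "plateau")
  st_avg <- protein_corrected_slds(expand_bilayer(b), p, "average")
  gi0 <- gaussian_intensity(st_avg, g_rbc, c(0.036, 0.071, 0.109), tau = 0)
  expect_equal(plateau, attr(gi0, "average") / gi0$i, tolerance = 1e-9)
  # the fluctuation term dies off slowly (~1/sqrt(tau)); at tau = 2e6 ns
  # (~3700 correlation times) the curve sits on the plateau to ~1e-2
  isf_late <- sur$isf[sur$tau == 2e6]
  expect_lt(max(abs(isf_late - plateau)), 0.02)
  expect_true(all(isf_late >= plateau - 1e-9))

  # D = 0: static structure, constant 1
  sur0 <- nse_curve(b, gaussian_membrane(23, 63, 0), p,
                    q = 0.071, tau = c(0, 50, 500))
  expect_equal(sur0$isf, rep(1, 3), tolerance = 1e-12)
})

test_that("roughness factor: unit flat limit, monotone growth, RBC value", {
  expect_equal(roughness_factor(gaussian_membrane(0, 63, 0)), 1)
  vals <- vapply(c(5, 15, 23, 40), function(la) {
    roughness_factor(gaussian_membrane(la, 63, 0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 1))
  # sampling cross-check: |grad h|^2 ~ exponential with mean (l_alpha/l_xy)^2
  set.seed(4)
  m <- (23 / 63)^2
  v <- stats::rexp(2e5, rate = 1 / m)
  mc <- mean(sqrt(1 + v))
  r_rbc <- roughness_factor(g_rbc)
  expect_equal(r_rbc, mc, tolerance = 5e-3)
  # fitted RBC fluctuations give a modest area excess, on the order of the
  # reported ~1.2 (the precise value depends on the lateral-scale convention)
  expect_gt(r_rbc, 1.04)
  expect_lt(r_rbc, 1.35)
})

test_that("realization-sampled field statistics match g_W in space and time", {
  g <- gaussian_membrane(23, 63, 1.85)
  n <- 64; L <- 512
  lag_cells <- c(4, 8, 16)   # 32, 64, 128 A at dx = 8
  dx <- L / n
  taus <- c(0, 400, 1600)
  acc_sp <- matrix(0, length(taus), length(lag_cells))
  acc_var <- 0
  n_seeds <- 48
  for (s in seq_len(n_seeds)) {
    hf <- sample_height_field(g, L, n, seed = 1000 + s, times = taus)
    h0 <- hf$fields[[1]]
    acc_var <- acc_var + mean(h0^2)
    for (jt in seq_along(taus)) {
      ht <- hf$fields[[jt]]
      for (jl in seq_along(lag_cells)) {
        m <- lag_cells[jl]
        acc_sp[jt, jl] <- acc_sp[jt, jl] + mean(h0 * ht[c((m + 1):n, 1:m), ])
      }
    }
  }
  # variance within ~3 x the (correlated-field) standard error
  expect_equal(acc_var / n_seeds, 23^2, tolerance = 0.12)
  emp <- acc_sp / n_seeds / 23^2
  ref <- outer(taus, lag_cells * dx, function(tt, rr) gw_covariance(rr, tt, g))
  expect_equal(emp, ref, tolerance = 0.15)
  # determinism: same seed, bit-identical fields
  h1 <- sample_height_field(g, L, n, seed = 7)$fields[[1]]
  h2 <- sample_height_field(g, L, n, seed = 7)$fields[[1]]
  expect_identical(h1, h2)
  expect_warning(sample_height_field(g, 256, 32, seed = 1), "8 l_xy")
})
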