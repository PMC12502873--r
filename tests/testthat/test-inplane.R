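# In-plane protein statistics: form factors, covariograms, hard-disc
# structure factor, Boolean correlation, Hankel intensities.

test_that("disc form factor matches the Bessel series and its known points", {
  expect_equal(disc_form_factor(0, 21.4), 1)
  # value at q R = 1: [2 J1(1)]^2 computed from the power series
  expect_equal(disc_form_factor(1 / 21.4, 21.4), (2 * j1_series(1))^2,
               tolerance = 1e-10)
  expect_equal((2 * j1_series(1))^2, 0.7746, tolerance = 1e-4)
  # first zero of J1 located with the series oracle
  root <- uniroot(j1_series, c(3, 4.5), tol = 1e-12)$root
  expect_equal(root, 3.8317, tolerance = 1e-4)
  expect_lt(disc_form_factor(root / 21.4, 21.4), 1e-12)
})

test_that("ellipse form factor and covariogram reduce to the disc case", {
  q <- seq(0, 0.4, length.out = 30)
  expect_equal(ellipse_form_factor(q, 21.4, 21.4), disc_form_factor(q, 21.4),
               tolerance = 1e-12)
  r <- seq(0, 50, length.out = 20)
  expect_equal(ellipse_covariogram(r, 21.4, 21.4), disc_covariogram(r, 21.4),
               tolerance = 1e-10)
})

test_that("covariograms have the exact areas and Monte-Carlo overlap", {
  r_p <- 21.4
  expect_equal(disc_covariogram(0, r_p), pi * r_p^2)
  expect_equal(disc_covariogram(2 * r_p, r_p), 0)
  expect_gt(disc_covariogram(2 * r_p - 1e-9, r_p), 0)
  # K(R)/R^2 = 2 (pi/3 - sqrt(3)/4), cross-checked by MC point counting
  expect_equal(disc_covariogram(r_p, r_p) / r_p^2, 2 * (pi / 3 - sqrt(3) / 4),
               tolerance = 1e-12)
  mc <- mc_lens_area(r_p, r_p, n = 4e5)
  se <- pi * r_p^2 * sqrt(0.39 * 0.61 / 4e5)
  expect_lt(abs(disc_covariogram(r_p, r_p) - mc), 4 * se)

  # dimer ellipse: K(0) = pi a b; MC overlap of two congruent ellipses at
  # distance r with a shared random orientation
  a <- 52.5; b <- 15.5
  expect_equal(ellipse_covariogram(0, a, b), pi * a * b, tolerance = 1e-9)
  set.seed(7)
  n_mc <- 3e5
  for (d in c(20, 60)) {
    beta <- runif(n_mc, 0, pi)   # orientation of the pair
    th <- runif(n_mc, 0, 2 * pi)
    rad <- sqrt(runif(n_mc))
    x <- a * rad * cos(th); y <- b * rad * sin(th)  # points in ellipse 1
    # displacement by d along a random direction, in ellipse frame
    dx <- d * cos(beta); dy <- d * sin(beta)
    inside <- ((x - dx) / a)^2 + ((y - dy) / b)^2 <= 1
    mc_est <- pi * a * b * mean(inside)
    mc_se <- pi * a * b * sd(inside) / sqrt(n_mc)
    expect_lt(abs(ellipse_covariogram(d, a, b) - mc_est), 4 * mc_se + 1e-9)
  }
})

test_that("time-smeared covariogram equals the Gaussian-displacement convolution", {
  r_p <- 10; d_p <- 2; tau <- 5
  # brute-force 2D convolution oracle on a grid
  kfun <- function(r) disc_covariogram(r, r_p)
  sig <- sqrt(2 * d_p * tau)
  conv_oracle <- function(r0) {
    xg <- seq(-4 * sig - 2 * r_p, 4 * sig + 2 * r_p, length.out = 301)
    dxg <- xg[2] - xg[1]
    gr <- expand.grid(x = xg, y = xg)
    w <- exp(-(gr$x^2 + gr$y^2) / (2 * sig^2)) / (2 * pi * sig^2)
    sum(w * kfun(sqrt((r0 - gr$x)^2 + gr$y^2))) * dxg^2
  }
  for (r0 in c(0, 15, 30)) {
    expect_lt(abs(disc_covariogram(r0, r_p, tau, d_p) - conv_oracle(r0)),
              2e-3 * pi * r_p^2)
  }
  # total mass is conserved by the displacement convolution
  r <- seq(0, 120, length.out = 3000)
  wts <- 2 * pi * r * c(diff(r)[1] / 2, (diff(r)[-1] + diff(r)[-2999]) / 2,
                        diff(r)[2999] / 2)
  expect_equal(sum(wts * disc_covariogram(r, r_p, tau, d_p)),
               (pi * r_p^2)^2, tolerance = 1e-3)
})

test_that("hard-disc structure factor obeys its limiting contracts", {
  q <- seq(1e-4, 3, length.out = 200)
  expect_equal(harddisc_structure_factor(q, 21.4, 0), rep(1, 200))
  for (phi in c(0.05, 0.15, 0.3)) {
    s <- harddisc_structure_factor(q, 21.4, phi)
    expect_lt(s[1], 1)                      # compressibility suppression
    expect_equal(s[1], 1 / (1 + 4 * phi), tolerance = 1e-4)
  }
  expect_equal(harddisc_structure_factor(50 / 21.4, 21.4, 0.23), 1,
               tolerance = 0.01)
})

test_that("Boolean correlation has the exact variance, support and dilute limit", {
  p <- rbc_protein(phi_p = 0.25)
  expect_equal(boolean_correlation(0, p), 0.25 * 0.75, tolerance = 1e-12)
  expect_equal(boolean_correlation(c(2 * 21.4, 50, 100), p), rep(0, 3))
  # dilute limit: C_p = theta K (1 - 1.5 theta A + O((theta A)^2))
  a_p <- pi * 21.4^2
  devs <- vapply(c(0.01, 0.005, 0.0025), function(x) {
    pd <- protein_spec(r_p = 21.4, rho_p = 0, theta_p = x / a_p)
    r <- seq(0, 2 * 21.4, length.out = 50)
    max(abs(boolean_correlation(r, pd) - pd$theta_p * disc_covariogram(r, 21.4))) / x
  }, numeric(1))
  # deviation scales linearly with theta A, coefficient 1.5 (series-exact)
  expect_equal(devs, c(0.01, 0.005, 0.0025) * 1.5, tolerance = 0.02)
})

test_that("in-plane intensity: dilute Boolean matches the bare form factor", {
  a_p <- pi * 21.4^2
  x <- 0.01
  pd <- protein_spec(r_p = 21.4, rho_p = 0, theta_p = x / a_p)
  q <- seq(0, 10 / 21.4, length.out = 80)
  ip <- inplane_intensity(q, pd)
  ref <- pd$theta_p * a_p^2 * disc_form_factor(q, 21.4)
  # global deviation ~1.8 * theta A of the reference peak (overlap corrections)
  dev <- max(abs(ip - ref)) / max(ref)
  expect_lt(dev, 2.2 * x)
  expect_gt(dev, 1.2 * x)
  # and the normalized patterns coincide much more closely
  expect_lt(max(abs(ip / ip[1] - ref / ref[1])), 0.6 * x)
})

test_that("Boolean intensity is a valid spectrum with Parseval consistency", {
  p <- rbc_protein(phi_p = 0.23)
  q <- seq(0, 0.6, length.out = 120)
  ip <- inplane_intensity(q, p)
  expect_true(all(ip > -1e-8 * max(ip)))     # nonnegative spectrum
  # I_p(q -> 0) = int 2 pi r C_p dr
  r <- seq(0, 6 * 2 * 21.4, length.out = 4000)
  wts <- r * 2 * pi * memsas:::trapz_weights(r)
  expect_equal(ip[1], sum(wts * boolean_correlation(r, p)), tolerance = 1e-4)
  # large-q decay
  expect_lt(inplane_intensity(5, p) / ip[1], 1e-4)
})

test_that("time decay: Boolean correlation vanishes uniformly at long times", {
  p <- rbc_protein(phi_p = 0.23, d_p = 5)
  r <- seq(0, 80, length.out = 30)
  c0 <- boolean_correlation(r, p, tau = 0)
  c1 <- boolean_correlation(r, p, tau = 50)
  c2 <- boolean_correlation(r, p, tau = 2000)
  expect_lt(max(c2), 0.02 * max(c0))
  expect_lt(max(c2), max(c1))
  # hard-disc path refuses dynamic requests
  phd <- rbc_protein(lateral_model = "harddisc", d_p = 5)
  expect_error(inplane_intensity(0.1, phd, tau = 10), "time dependence|Boolean")
})
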