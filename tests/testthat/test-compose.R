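# Composition of membrane and protein models: the correlation-function
# combinator and the two intensity evaluation paths.

test_that("correlation combinator: identity, linearity, grid checks", {
  r_z <- seq(0, 40, by = 5)
  r_xy <- seq(0, 100, by = 20)
  c_avg <- outer(exp(-r_z / 20), exp(-r_xy / 50))
  c_con <- outer(cos(r_z / 15), exp(-r_xy / 30))
  c_p <- 0.2 * exp(-r_xy / 40)

  out <- correlation_with_proteins(c_avg, c_con, c_p)
  expect_equal(out, c_avg + sweep(c_con, 2, c_p, `*`))
  # C_p = 0 (phi_p = 0 or 1) and zero contrast both reduce to the bare term
  expect_equal(correlation_with_proteins(c_avg, c_con, numeric(length(r_xy))), c_avg)
  expect_equal(correlation_with_proteins(c_avg, 0 * c_con, c_p), c_avg)
  # linearity in C_p: doubling C_p doubles the protein part exactly
  out2 <- correlation_with_proteins(c_avg, c_con, 2 * c_p)
  expect_equal(out2 - c_avg, 2 * (out - c_avg))
  # vector (laterally uniform) membrane input is recycled across r_xy
  v <- exp(-r_z / 10)
  outv <- correlation_with_proteins(v, v, c_p)
  expect_equal(dim(outv), c(length(r_z), length(r_xy)))
  expect_equal(outv[, 1], v + c_p[1] * v)
  expect_error(correlation_with_proteins(c_avg, c_con[1:3, ], c_p), "grids")
  expect_error(correlation_with_proteins(c_avg, c_con, c_p[1:2]), "column")
})

test_that("composed correlation matches a sampled 2D field oracle", {
  # brute force: sample membrane height field and Boolean discs on a plane,
  # build the composite SLD field rho = (1 - chi) rho_m(z - h) + chi rho_p,
  # and compare its empirical two-point statistics with the composed formula
  b <- rbc_bilayer("xray", l_c = 10, l_h = 5)
  st <- expand_bilayer(b)
  g <- gaussian_membrane(8, 40, 0)
  p <- rbc_protein("xray", phi_p = 0.23, r_p = 12)
  st_avg <- protein_corrected_slds(st, p, "average")
  st_con <- protein_corrected_slds(st, p, "contrast")

  L <- 512; n <- 128
  dx <- L / n
  lag_cells <- c(0, 1, 2, 5)            # lateral lags: 0, 4, 8, 20 A
  z_pairs <- rbind(c(2, 2), c(2, 12), c(-8, 6))
  n_seeds <- 40
  reg <- memsas:::stack_regions(st)
  # protein phase: per-layer protein SLD contrast (solvent outside the stack)
  drho_p <- c(0, rep(p$rho_p, n_layers(st)) - st$solvent_sld, 0)
  layer_of <- function(zv) findInterval(zv, st$boundaries) + 1L
  per_seed <- array(0, c(n_seeds, nrow(z_pairs), length(lag_cells)))
  for (s in seq_len(n_seeds)) {
    h <- sample_height_field(g, L, n, seed = 3000 + s)$fields[[1]]
    d <- sample_boolean_discs(p, L, seed = 7000 + s)
    chi <- memsas:::protein_mask(p, d$centres[[1]], d$angles, L, n)
    for (jz in seq_len(nrow(z_pairs))) {
      z1 <- z_pairs[jz, 1]; z2 <- z_pairs[jz, 2]
      rho1 <- ifelse(chi, drho_p[layer_of(z1 - h)], reg$drho[layer_of(z1 - h)])
      rho2 <- ifelse(chi, drho_p[layer_of(z2 - h)], reg$drho[layer_of(z2 - h)])
      for (jl in seq_along(lag_cells)) {
        m <- lag_cells[jl]
        shifted <- if (m == 0) rho2 else rho2[c((m + 1):n, 1:m), ]
        per_seed[s, jz, jl] <- mean(rho1 * shifted)
      }
    }
  }
  emp <- apply(per_seed, c(2, 3), mean)
  emp_se <- apply(per_seed, c(2, 3), stats::sd) / sqrt(n_seeds)

  # composed prediction per z-pair (two-point, not z-integrated):
  # E[rho1 rho2](r) = C_avg_pt(z1, z2, r) + C_p(r) C_con_pt(z1, z2, r)
  pt_corr <- function(stack, z1, z2, r) {
    rg <- memsas:::stack_regions(stack)
    pp <- layer_pair_probabilities(stack, g, z1, z2, r, 0)
    drop(rg$drho %*% pp %*% rg$drho)
  }
  pred <- emp * 0
  for (jz in seq_len(nrow(z_pairs))) {
    for (jl in seq_along(lag_cells)) {
      r <- lag_cells[jl] * dx
      pred[jz, jl] <- pt_corr(st_avg, z_pairs[jz, 1], z_pairs[jz, 2], r) +
        boolean_correlation(r, p) * pt_corr(st_con, z_pairs[jz, 1], z_pairs[jz, 2], r)
    }
  }
  # every entry agrees within 4 empirical standard errors (plus numerical dust)
  expect_true(all(abs(emp - pred) < 4 * emp_se + 1e-16))
})

test_that("gaussian path with l_alpha -> 0 equals the slab path", {
  b <- rbc_bilayer("xray")
  p <- rbc_protein("xray", phi_p = 0.23)
  q <- fit_q_grid(40)
  g0 <- gaussian_membrane(0, 63, 0)
  res_g <- intensity_with_proteins("gaussian", b, g0, p, q, radiation = "xray")
  res_s <- intensity_with_proteins("slab", b, g = NULL, p, q, radiation = "xray")
  expect_equal(res_g$membrane$i, res_s$membrane$i, tolerance = 1e-10)
  expect_equal(res_g$protein$i, res_s$protein$i, tolerance = 5e-3)
  expect_equal(res_g$total$i, res_s$total$i, tolerance = 5e-3)
})

test_that("composition identity holds on both paths to 1e-10 relative", {
  b <- rbc_bilayer("neutron")
  st <- expand_bilayer(b)
  q <- fit_q_grid(30)
  p_id <- protein_spec(r_p = 21.4, rho_p = st$sld, phi_p = 0.23)
  bare_slab <- slab_intensity(st, q)$i
  res_s <- intensity_with_proteins("slab", b, NULL, p_id, q)
  expect_equal(res_s$total$i, bare_slab, tolerance = 1e-10)
  g <- gaussian_membrane(23, 63, 0)
  bare_g <- gaussian_intensity(st, g, q)$i
  res_g <- intensity_with_proteins("gaussian", b, g, p_id, q)
  expect_equal(res_g$total$i, bare_g, tolerance = 1e-10)
})

test_that("protein term scales linearly with the contrast correlation", {
  # doubling the contrast SLDs quadruples the protein intensity term
  # (|rho_c|^2), while C_p linearity is exercised through tau decay
  b <- rbc_bilayer("xray")
  q <- fit_q_grid(25)
  p <- rbc_protein("xray", phi_p = 0.23)
  res <- intensity_with_proteins("slab", b, NULL, p, q, radiation = "xray")
  st <- expand_bilayer(b)
  st_con <- protein_corrected_slds(st, p, "contrast")
  st_con2 <- layer_stack(st_con$boundaries, 2 * st_con$sld, 0)
  i2 <- memsas:::protein_term_mu_average(st_con2, p, q, tau = 0)
  expect_equal(i2, 4 * res$protein$i, tolerance = 1e-10)
})
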