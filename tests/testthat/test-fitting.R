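# Weighted least-squares fitting of elastic curves and NSE surfaces.

test_that("noiseless slab data are recovered to optimizer tolerance", {
  res <- make_fixtures("slab_sans", dir = file.path(tempdir(), "fx_exact"),
                       noise = 0, seed = 1)
  d <- read_sas_ascii(file.path(tempdir(), "fx_exact", "slab_sans.dat"), "neutron")
  fit <- fit_elastic(d, "slab", start = list(l_c = 13, l_h = 7),
                     protein = list(r_p = 21.4, phi_p = 0.23),
                     n_starts = 2, seed = 1)
  expect_equal(unname(fit$par[["l_c"]]), 16.3, tolerance = 1e-5)
  expect_equal(unname(fit$par[["l_h"]]), 5.0, tolerance = 1e-5)
  expect_equal(fit$total_thickness, 42.6, tolerance = 1e-4)
  expect_equal(fit$scale, 1, tolerance = 1e-5)
  # objective decreases monotonically along the optimizer trace
  expect_true(all(diff(fit$deviance_trace) <= 1e-12 * fit$deviance_trace[1]))
})

test_that("joint SANS+SAXS fits share geometry and weight by sigma", {
  dir <- file.path(tempdir(), "fx_joint")
  make_fixtures("slab_sans", dir = dir, noise = 0.02, seed = 31)
  make_fixtures("slab_saxs", dir = dir, noise = 0.02, seed = 32)
  ds <- list(read_sas_ascii(file.path(dir, "slab_sans.dat"), "neutron"),
             read_sas_ascii(file.path(dir, "slab_saxs.dat"), "xray"))
  fit <- fit_elastic(ds, "slab", start = list(l_c = 14, l_h = 6),
                     protein = list(r_p = 21.4, phi_p = 0.23),
                     n_starts = 2, seed = 3)
  expect_lt(abs(fit$par[["l_c"]] - 16.3), 0.1)
  expect_lt(abs(fit$par[["l_h"]] - 5.0), 0.1)
  expect_true(all(is.finite(fit$se)))
  expect_lt(fit$chi2_red, 1.4)
  expect_gt(fit$chi2_red, 0.6)
  # fitted curves returned per dataset on the masked grids
  expect_length(fit$fitted, 2)
  expect_equal(attr(fit$fitted[[2]], "radiation"), "xray")
})

test_that("Boolean and hard-disc fits give very similar thicknesses", {
  dir <- file.path(tempdir(), "fx_models")
  make_fixtures("slab_sans", dir = dir, noise = 0.02, seed = 41)
  d <- read_sas_ascii(file.path(dir, "slab_sans.dat"), "neutron")
  fits <- lapply(c("boolean", "harddisc"), function(m) {
    fit_elastic(d, "slab", start = list(l_c = 14, l_h = 6),
                protein = list(r_p = 21.4, phi_p = 0.23, lateral_model = m),
                n_starts = 2, seed = 4)
  })
  expect_lt(abs(fits[[1]]$par[["l_c"]] - fits[[2]]$par[["l_c"]]), 0.5)
  expect_lt(abs(fits[[1]]$par[["l_h"]] - fits[[2]]$par[["l_h"]]), 0.5)
})

test_that("gaussian membrane parameters are recovered within 10% from 2% noise", {
  dir <- file.path(tempdir(), "fx_gauss")
  make_fixtures("gaussian_joint", dir = dir, noise = 0.02, seed = 21)
  ds <- list(read_sas_ascii(file.path(dir, "gaussian_neutron.dat"), "neutron"),
             read_sas_ascii(file.path(dir, "gaussian_xray.dat"), "xray"))
  fit <- fit_elastic(ds, "gaussian", start = list(l_alpha = 18, l_xy = 75),
                     fixed = list(l_c = 16.3, l_h = 5.0),
                     protein = list(r_p = 21.4, phi_p = 0.23),
                     n_starts = 1, seed = 2)
  expect_lt(abs(fit$par[["l_alpha"]] / 23 - 1), 0.10)
  expect_lt(abs(fit$par[["l_xy"]] / 63 - 1), 0.10)
  # dynamics: one-parameter NSE fit at the fitted-structure truth
  make_fixtures("nse", dir = dir, noise = 0.02, seed = 22)
  sur <- read_nse_table(file.path(dir, "nse.dat"))
  fitd <- fit_nse(sur, rbc_bilayer("neutron"), gaussian_membrane(23, 63),
                  rbc_protein("neutron"), d_start = 0.8)
  expect_lt(abs(fitd$d / 1.85 - 1), 0.10)
})

test_that("fit window masking and degenerate inputs raise errors", {
  d <- scattering_curve(c(0.01, 0.02, 0.05), c(1, 0.5, 0.1))
  expect_error(fit_elastic(d, "slab", q_range = c(0.2, 0.5)), "q_range")
  expect_error(fit_elastic(d, "gaussian", start = list(l_c = 10, l_h = 5)),
               "l_alpha")
  expect_error(fit_elastic(d, "slab", start = list(bogus = 1)), "among")
})

test_that("noiseless NSE surface returns D to optimizer tolerance", {
  dir <- file.path(tempdir(), "fx_nse0")
  make_fixtures("nse", dir = dir, noise = 0, seed = 2)
  sur <- read_nse_table(file.path(dir, "nse.dat"))
  fit <- fit_nse(sur, rbc_bilayer("neutron"), gaussian_membrane(23, 63),
                 rbc_protein("neutron"), d_start = 0.4)
  expect_equal(fit$d, 1.85, tolerance = 1e-6)
  expect_equal(fit$tau_c, 63^2 / (4 * 1.85), tolerance = 1e-6)
  expect_match(fit$tau_c_formula, "l_xy\\^2 / \\(4 D\\)")
})

test_that("a D = 0 truth is recovered as statistically indistinguishable from 0", {
  dir <- file.path(tempdir(), "fx_nse_static")
  make_fixtures("nse", dir = dir, truth = list(d = 0), noise = 0.02, seed = 8)
  sur <- read_nse_table(file.path(dir, "nse.dat"))
  fit <- fit_nse(sur, rbc_bilayer("neutron"), gaussian_membrane(23, 63),
                 rbc_protein("neutron"), d_start = 0.5)
  expect_lt(fit$d, 3 * max(fit$d_se, 1e-3))
  # surfaces without tau > 0 rows are rejected
  sur0 <- isf_surface(c(0.036, 0.071), c(0, 0), c(1, 1))
  expect_error(fit_nse(sur0, rbc_bilayer("neutron"), gaussian_membrane(23, 63)),
               "tau > 0")
})

test_that("fit reports serialize to JSON with the key quantities", {
  dir <- file.path(tempdir(), "fx_rep")
  make_fixtures("nse", dir = dir, noise = 0.05, seed = 12)
  sur <- read_nse_table(file.path(dir, "nse.dat"))
  fit <- fit_nse(sur, rbc_bilayer("neutron"), gaussian_membrane(23, 63),
                 rbc_protein("neutron"))
  path <- file.path(dir, "report.json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$parameters$d, fit$d, tolerance = 1e-12)
  expect_true(!is.null(rep$tau_c_formula))
  expect_true(!is.null(rep$chi2_red))
})
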