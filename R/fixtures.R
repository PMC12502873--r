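# Synthetic fixture generator: model curves with multiplicative Gaussian
# noise, standing in for the experimental SANS/SAXS/NSE datasets.

#' @noRd
fixture_truth_defaults <- function() {
  list(
    l_c = 16.3, l_h = 5.0, l_s = 0,          # slab geometry, A
    l_alpha = 23, l_xy = 63, d = 1.85,       # fluctuations, A and A^2/ns
    phi_p = 0.23, r_p = 21.4,                # band 3-like inclusions
    lateral_model = "boolean", d_p = 0,
    q_min = 8e-3, q_max = 0.5, n_q = 100,    # elastic grid, 1/A
    nse_q = c(0.036, 0.071, 0.109),          # NSE q values, 1/A
    nse_tau = c(0, exp(seq(log(0.5), log(200), length.out = 17)))  # ns
  )
}

#' Generate synthetic scattering fixtures
#'
#' Writes model-generated datasets with multiplicative Gaussian noise at the
#' stated level, plus a JSON sidecar recording the exact truth parameters.
#' Scenarios: `"slab_sans"` and `"slab_saxs"` (single elastic curve from the
#' static slab + protein model), `"gaussian_joint"` (SANS and SAXS curves
#' from the Gaussian membrane + protein model), `"nse"` (normalized ISF
#' table of the Gaussian membrane with protein-corrected average SLDs).
#' Default truth values are the red-blood-cell membrane parameters
#' (`l_c = 16.3`, `l_h = 5.0` A, `l_alpha = 23`, `l_xy = 63` A,
#' `D = 1.85` A^2/ns, `phi_p = 0.23`, `r_p = 21.4` A, SLD tables of
#' [rbc_sld_table()]). Fully reproducible from `seed`.
#'
#' @param scenario One of `"slab_sans"`, `"slab_saxs"`, `"gaussian_joint"`,
#'   `"nse"`.
#' @param dir Output directory (created if needed).
#' @param truth Named list overriding the default truth parameters.
#' @param noise Relative noise level (multiplicative Gaussian; also the
#'   reported `sigma / I`).
#' @param seed Integer seed.
#' @return Invisibly, a list with `files` (paths written), `truth` and the
#'   noise-free model values.
#' @export
make_fixtures <- function(scenario = c("slab_sans", "slab_saxs", "gaussian_joint", "nse"),
                          dir, truth = list(), noise = 0.02, seed = 1) {
  scenario <- match.arg(scenario)
  tr <- utils::modifyList(fixture_truth_defaults(), truth)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  q <- exp(seq(log(tr$q_min), log(tr$q_max), length.out = tr$n_q))
  mk_objects <- function(radiation) {
    slds <- rbc_sld_table(radiation)
    b <- symmetric_bilayer(tr$l_c, tr$l_h, tr$l_s, rho_c = slds$rho_c,
                           rho_h = slds$rho_h, rho_w = slds$rho_w)
    p <- if (tr$phi_p > 0) {
      protein_spec(r_p = tr$r_p, rho_p = slds$rho_p, phi_p = tr$phi_p,
                   lateral_model = tr$lateral_model, d_p = tr$d_p)
    } else NULL
    list(b = b, p = p)
  }
  noisy <- function(i, sub_seed) {
    if (noise == 0) return(i)
    with_seed(seed * 100L + sub_seed, i * (1 + noise * stats::rnorm(length(i))))
  }
  files <- character(0)
  model_values <- list()
  hdr_common <- list(scenario = scenario, seed = seed, noise = noise,
                     l_c_A = tr$l_c, l_h_A = tr$l_h, phi_p = tr$phi_p,
                     r_p_A = tr$r_p, lateral_model = tr$lateral_model)

  write_elastic <- function(radiation, i_model, tag, sub_seed) {
    iv <- noisy(i_model, sub_seed)
    crv <- scattering_curve(q, iv, sigma = if (noise > 0) noise * abs(i_model),
                            radiation = radiation)
    f <- file.path(dir, paste0(tag, ".dat"))
    write_sas_ascii(crv, f, header = hdr_common)
    files <<- c(files, f)
    model_values[[tag]] <<- i_model
  }

  if (scenario %in% c("slab_sans", "slab_saxs")) {
    radiation <- if (scenario == "slab_sans") "neutron" else "xray"
    obj <- mk_objects(radiation)
    im <- if (is.null(obj$p)) {
      slab_intensity(expand_bilayer(obj$b), q, radiation)$i
    } else {
      slab_intensity_with_proteins(obj$b, obj$p, q, radiation = radiation)$total$i
    }
    write_elastic(radiation, im, scenario, 1L)
  } else if (scenario == "gaussian_joint") {
    g <- gaussian_membrane(tr$l_alpha, tr$l_xy, tr$d)
    for (jj in seq_along(c("neutron", "xray"))) {
      radiation <- c("neutron", "xray")[jj]
      obj <- mk_objects(radiation)
      im <- if (is.null(obj$p)) {
        gaussian_intensity(obj$b, g, q, radiation = radiation)$i
      } else {
        intensity_with_proteins("gaussian", obj$b, g, obj$p, q,
                                radiation = radiation)$total$i
      }
      write_elastic(radiation, im, paste0("gaussian_", radiation), jj)
    }
  } else {  # nse
    g <- gaussian_membrane(tr$l_alpha, tr$l_xy, tr$d)
    obj <- mk_objects("neutron")
    sur <- nse_curve(obj$b, g, p = obj$p, q = tr$nse_q, tau = tr$nse_tau)
    isf_noisy <- noisy(sur$isf, 7L)
    isf_noisy[sur$tau == 0] <- 1  # the measured ISF is normalized at tau = 0
    out <- isf_surface(sur$q, sur$tau, isf_noisy,
                       sigma = if (noise > 0) pmax(noise * abs(sur$isf), 1e-6))
    f <- file.path(dir, "nse.dat")
    write_nse_table(out, f, header = c(hdr_common,
                                       list(l_alpha_A = tr$l_alpha,
                                            l_xy_A = tr$l_xy, d_A2ns = tr$d)))
    files <- c(files, f)
    model_values$nse <- sur$isf
  }
  sidecar <- file.path(dir, paste0(scenario, "_truth.json"))
  write_atomic(jsonlite::toJSON(list(scenario = scenario, truth = tr,
                                     noise = noise, seed = seed),
                                auto_unbox = TRUE, digits = NA, pretty = TRUE),
               sidecar)
  files <- c(files, sidecar)
  invisible(list(files = files, truth = tr, model = model_values))
}
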