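# Weighted least-squares fitting of elastic curves (slab or Gaussian
# membrane, single or joint multi-radiation datasets) and of NSE surfaces
# (one-parameter diffusion fit).

#' Scattering-length-density tables per radiation
#'
#' Convenience container for the per-radiation SLD values entering a joint
#' SAXS/SANS fit: lipid chains, lipid heads, solvent and protein.
#'
#' @param rho_c,rho_h,rho_w,rho_p SLDs in 1/A^2.
#' @return A named list of class `sld_table`.
#' @examples
#' # red-blood-cell membrane values in heavy water
#' sld_table(rho_c = -0.07e-6, rho_h = 1.87e-6, rho_w = 6.37e-6, rho_p = 1.685e-6)
#' @export
sld_table <- function(rho_c, rho_h, rho_w, rho_p) {
  out <- list(rho_c = rho_c, rho_h = rho_h, rho_w = rho_w, rho_p = rho_p)
  lapply(out, stopifnot_finite, "sld")
  structure(out, class = "sld_table")
}

#' Reference SLD tables for red-blood-cell membranes in heavy water
#'
#' Literature SLD values for the average lipid chain and head regions of
#' red-blood-cell membranes, the D2O solvent, and the band 3 protein, for
#' neutrons and X-rays.
#'
#' @param radiation `"neutron"` or `"xray"`.
#' @return An [sld_table()].
#' @export
rbc_sld_table <- function(radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  if (radiation == "neutron") {
    sld_table(rho_c = -0.07e-6, rho_h = 1.87e-6, rho_w = 6.37e-6, rho_p = 1.685e-6)
  } else {
    sld_table(rho_c = 8.1e-6, rho_h = 14.2e-6, rho_w = 9.37e-6, rho_p = 12.062e-6)
  }
}

# assemble bilayer + protein objects for one radiation from the parameter set
#' @noRd
build_model_objects <- function(par, slds, protein) {
  b <- symmetric_bilayer(l_c = par[["l_c"]], l_h = par[["l_h"]],
                         l_s = if ("l_s" %in% names(par)) par[["l_s"]] else 0,
                         rho_c = slds$rho_c, rho_h = slds$rho_h,
                         rho_w = slds$rho_w)
  p <- if (is.null(protein)) NULL else {
    protein_spec(r_p = protein$r_p, a = protein$a, b = protein$b,
                 rho_p = slds$rho_p, phi_p = protein$phi_p,
                 lateral_model = protein$lateral_model, d_p = protein$d_p)
  }
  list(bilayer = b, protein = p)
}

# fast slab+protein model evaluator with the in-plane intensity cached
#' @noRd
slab_model_intensity <- function(par, slds, protein, q, ip_cache, gl) {
  obj <- build_model_objects(par, slds, protein)
  stack <- expand_bilayer(obj$bilayer)
  if (is.null(obj$protein)) return(slab_intensity(stack, q)$i)
  stack_avg <- protein_corrected_slds(stack, obj$protein, "average")
  stack_con <- protein_corrected_slds(stack, obj$protein, "contrast")
  i_mem <- slab_intensity(stack_avg, q)$i
  ip_fun <- ip_cache(obj$protein)
  i_prot <- vapply(q, function(qi) {
    amp2 <- Mod(slab_amplitude(stack_con, qi * gl$x, reference_sld = 0))^2
    sum(gl$w * amp2 * ip_fun(qi * sqrt(pmax(1 - gl$x^2, 0))))
  }, numeric(1))
  i_mem + i_prot
}

#' @noRd
gaussian_model_intensity <- function(par, slds, protein, q, n_mu = 32) {
  obj <- build_model_objects(par, slds, protein)
  g <- gaussian_membrane(par[["l_alpha"]], par[["l_xy"]],
                         if ("d" %in% names(par)) par[["d"]] else 0)
  if (is.null(obj$protein)) {
    return(gaussian_intensity(obj$bilayer, g, q, n_mu = n_mu)$i)
  }
  intensity_with_proteins("gaussian", obj$bilayer, g, obj$protein, q,
                          n_mu = n_mu)$total$i
}

#' Fit the membrane model to elastic scattering curves
#'
#' Weighted least-squares fit of the slab or Gaussian membrane model (with
#' optional protein inclusions) to one or more reduced elastic curves.
#' Geometric parameters are shared across datasets (joint fit); each dataset
#' gets its own free intensity scale and, optionally, a flat background.
#' Residuals are weighted by `1/sigma` when uncertainties are present and by
#' `1/I_obs` otherwise. The optimizer is bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with positivity bounds on all lengths, restarted
#' from `n_starts` seeded perturbations of `start` to guard against local
#' minima.
#'
#' @param datasets A [scattering_curve()] or list of them (the `radiation`
#'   attribute selects the SLD table per dataset).
#' @param model `"slab"` or `"gaussian"`.
#' @param start Named list of starting values for the free geometric
#'   parameters among `l_c`, `l_h`, `l_alpha`, `l_xy` (A).
#' @param fixed Named list of fixed geometric parameters (defaults:
#'   `l_s = 0`; for the Gaussian model any of `l_alpha`, `l_xy` not in
#'   `start`).
#' @param sld_tables Named list of [sld_table()]s by radiation (defaults to
#'   [rbc_sld_table()] for each radiation present).
#' @param protein `NULL`, or a list with `r_p` (or `a`/`b`), `phi_p`,
#'   `lateral_model`, `d_p` describing the (fixed) protein inclusions; the
#'   protein SLD comes from the per-radiation table.
#' @param q_range Fit window in 1/A (default the instrument fit range
#'   `8e-3` to `0.5`).
#' @param background Logical: include a free flat background per dataset.
#' @param n_starts Number of seeded multi-starts.
#' @param seed Integer seed for the start perturbations.
#' @return An object of class `memsas_fit`: a list with `par` (named
#'   estimates), `se` (curvature-based standard errors), `chi2`, `dof`,
#'   `chi2_red`, `total_thickness` (`2 (l_c + l_h)`, with its standard
#'   error), per-dataset `scale`/`background`, and the fitted curves.
#' @export
fit_elastic <- function(datasets, model = c("slab", "gaussian"),
                        start = list(l_c = 15, l_h = 5),
                        fixed = list(),
                        sld_tables = NULL,
                        protein = NULL,
                        q_range = c(8e-3, 0.5),
                        background = TRUE,
                        n_starts = 5, seed = 1) {
  model <- match.arg(model)
  if (inherits(datasets, "scattering_curve")) datasets <- list(datasets)
  if (!length(datasets)) stop("need at least one dataset", call. = FALSE)
  if (!is.null(protein)) {
    defaults <- list(r_p = NULL, a = NULL, b = NULL, phi_p = 0.23,
                     lateral_model = "boolean", d_p = 0)
    protein <- utils::modifyList(defaults, protein)
  }
  rads <- vapply(datasets, function(d) attr(d, "radiation"), character(1))
  if (is.null(sld_tables)) {
    sld_tables <- lapply(unique(rads), rbc_sld_table)
    names(sld_tables) <- unique(rads)
  }
  # mask to the fit window
  datasets <- lapply(datasets, function(d) {
    keep <- d$q >= q_range[1] & d$q <= q_range[2]
    if (!any(keep)) stop("a dataset has no points inside `q_range`", call. = FALSE)
    scattering_curve(d$q[keep], d$i[keep],
                     if ("sigma" %in% names(d)) d$sigma[keep],
                     radiation = attr(d, "radiation"))
  })
  geo_names <- names(start)
  ok_names <- c("l_c", "l_h", "l_s", "l_alpha", "l_xy")
  if (!all(geo_names %in% ok_names)) {
    stop("free parameters must be among: ", paste(ok_names, collapse = ", "),
         call. = FALSE)
  }
  fixed_full <- utils::modifyList(list(l_s = 0), fixed)
  if (model == "gaussian") {
    for (nm in c("l_alpha", "l_xy")) {
      if (!nm %in% geo_names && is.null(fixed_full[[nm]])) {
        stop(sprintf("gaussian model needs `%s` in `start` or `fixed`", nm),
             call. = FALSE)
      }
    }
  }

  gl <- gl_nodes(96, 0, 1)
  ip_env <- new.env(parent = emptyenv())
  ip_cache <- function(p) {
    key <- paste0(attr(p, "radiation"), p$lateral_model, p$phi_p, p$area, p$r_hd)
    f <- ip_env[[key]]
    if (is.null(f)) {
      qg <- seq(0, q_range[2] * 1.0001, length.out = 512)
      f <- stats::approxfun(qg, inplane_intensity(qg, p), rule = 2)
      ip_env[[key]] <- f
    }
    f
  }

  model_i <- function(geo, d, rad) {
    par <- c(as.list(geo), fixed_full[setdiff(names(fixed_full), names(geo))])
    if (model == "slab") {
      slab_model_intensity(par, sld_tables[[rad]], protein, d$q, ip_cache, gl)
    } else {
      gaussian_model_intensity(par, sld_tables[[rad]], protein, d$q)
    }
  }

  nd <- length(datasets)
  wts <- lapply(datasets, function(d) {
    if ("sigma" %in% names(d)) 1 / d$sigma else 1 / pmax(abs(d$i), .Machine$double.xmin)
  })

  # Per-dataset scale (and flat background) enter the model linearly and are
  # profiled out analytically at every evaluation by weighted least squares,
  # leaving only the geometric parameters to the nonlinear optimizer.
  profile_linear <- function(im, d, w) {
    if (background) {
      X <- cbind(im, 1)
      A <- crossprod(X * w)
      bvec <- crossprod(X * w, d$i * w)
      ab <- tryCatch(solve(A, bvec), error = function(e) c(sum(w^2 * im * d$i) /
                                                             sum(w^2 * im^2), 0))
      c(scale = ab[1], bg = ab[2])
    } else {
      c(scale = sum(w^2 * im * d$i) / sum(w^2 * im^2), bg = 0)
    }
  }
  resid_fun <- function(theta) {
    geo <- stats::setNames(theta, geo_names)
    unlist(lapply(seq_len(nd), function(j) {
      d <- datasets[[j]]
      im <- model_i(geo, d, rads[j])
      if (!all(is.finite(im))) stop("model intensity is non-finite", call. = FALSE)
      sb <- profile_linear(im, d, wts[[j]])
      (sb[1] * im + sb[2] - d$i) * wts[[j]]
    }))
  }

  theta0 <- unlist(start)
  lower <- rep(1e-3, length(geo_names))
  upper <- rep(Inf, length(theta0))

  run_one <- function(th0) {
    minpack.lm::nls.lm(par = th0, fn = resid_fun, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-12,
                                                            ptol = 1e-10))
  }
  fits <- with_seed(seed, {
    starts <- list(theta0)
    if (n_starts > 1) {
      for (s in seq_len(n_starts - 1)) {
        pert <- theta0
        ng <- length(geo_names)
        pert[seq_len(ng)] <- pert[seq_len(ng)] * exp(stats::rnorm(ng, sd = 0.2))
        starts[[s + 1]] <- pert
      }
    }
    lapply(starts, function(th) tryCatch(run_one(th), error = function(e) NULL))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all optimizer starts failed", call. = FALSE)
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  best <- fits[[which.min(dev)]]

  theta <- best$par
  geo <- stats::setNames(theta, geo_names)
  n_obs <- sum(vapply(datasets, nrow, integer(1)))
  dof <- n_obs - length(theta) - nd * (1L + as.integer(background))
  chi2 <- best$deviance
  # curvature-based covariance: chi2_red * (J'J)^-1, with Jacobi scaling
  # (scale/background curvatures differ from the lengths by many decades)
  cov <- tryCatch({
    h <- best$hessian
    d <- 1 / sqrt(pmax(diag(h), .Machine$double.xmin))
    hs <- h * tcrossprod(d)
    chi2 / max(dof, 1) * (solve(hs) * tcrossprod(d))
  }, error = function(e) NULL)
  se_all <- if (is.null(cov)) rep(NA_real_, length(theta)) else sqrt(pmax(diag(cov), 0))
  se_geo <- stats::setNames(se_all[seq_along(geo_names)], geo_names)

  par_full <- utils::modifyList(fixed_full, as.list(geo))
  thick <- if (all(c("l_c", "l_h") %in% names(par_full))) {
    2 * (par_full$l_c + par_full$l_h)
  } else NA_real_
  thick_se <- if (!is.null(cov) && all(c("l_c", "l_h") %in% geo_names)) {
    ic <- match(c("l_c", "l_h"), geo_names)
    2 * sqrt(sum(cov[ic, ic]))
  } else NA_real_

  scales <- numeric(nd)
  bgs <- numeric(nd)
  curves <- lapply(seq_len(nd), function(j) {
    d <- datasets[[j]]
    im <- model_i(geo, d, rads[j])
    sb <- profile_linear(im, d, wts[[j]])
    scales[j] <<- sb[1]
    bgs[j] <<- sb[2]
    scattering_curve(d$q, sb[1] * im + sb[2], radiation = rads[j])
  })
  structure(list(
    model = model, par = geo, se = se_geo, fixed = fixed_full,
    scale = scales,
    background = bgs,
    chi2 = chi2, dof = dof, chi2_red = chi2 / max(dof, 1),
    total_thickness = thick, total_thickness_se = thick_se,
    radiations = rads, fitted = curves, data = datasets,
    deviance_trace = best$rsstrace, info = best$info, message = best$message,
    hessian = best$hessian
  ), class = "memsas_fit")
}

#' @export
print.memsas_fit <- function(x, ...) {
  cat(sprintf("<memsas_fit> %s model, chi2/dof = %.4g (%d dof)\n",
              x$model, x$chi2_red, x$dof))
  for (nm in names(x$par)) {
    cat(sprintf("  %-8s = %8.4g +- %.3g A\n", nm, x$par[[nm]], x$se[[nm]]))
  }
  if (!is.null(x$total_thickness) && is.finite(x$total_thickness)) {
    cat(sprintf("  total thickness 2(l_c + l_h) = %.4g A\n", x$total_thickness))
  }
  if (!is.null(x$d)) {
    cat(sprintf("  D = %.4g +- %.3g A^2/ns; tau_c = l_xy^2/(4 D) = %.4g ns\n",
                x$d, x$d_se, x$tau_c))
  }
  invisible(x)
}

#' Fit the membrane diffusion coefficient to an NSE surface
#'
#' One-parameter weighted least-squares fit of the normalized intermediate
#' scattering function of the Gaussian membrane model over the full
#' `(q, tau)` surface. All structural parameters (layer thicknesses, SLDs,
#' `l_alpha`, `l_xy`, protein fraction) are fixed, typically to the values
#' from an elastic fit; only the wave-packet diffusion coefficient `D` is
#' free. The report includes the derived correlation time
#' `tau_c = l_xy^2 / (4 D)` (the time for a packet of size `l_xy` to diffuse
#' over its own size; the factor 4 is the 2D mean-square-displacement rate).
#'
#' @param surface An [isf_surface()] with at least one `tau > 0` point.
#' @param b A [symmetric_bilayer()] or [layer_stack()] (structural truth).
#' @param g A [gaussian_membrane()] carrying the fixed `l_alpha`, `l_xy`
#'   (its `d` is ignored).
#' @param p Optional [protein_spec()]; enters through the average SLDs only.
#' @param d_start Starting value for `D` in A^2/ns.
#' @return An object of class `memsas_fit` with elements `d`, `d_se`,
#'   `tau_c`, `tau_c_formula`, `chi2`, `dof`, `chi2_red` and the fitted
#'   surface.
#' @export
fit_nse <- function(surface, b, g, p = NULL, d_start = 1) {
  stopifnot(inherits(surface, "isf_surface"), inherits(g, "gaussian_membrane"))
  if (!any(surface$tau > 0)) {
    stop("the NSE surface has no tau > 0 points; nothing constrains D", call. = FALSE)
  }
  stack <- as_layer_stack(b)
  if (!is.null(p)) stack <- protein_corrected_slds(stack, p, "average")
  qs <- sort(unique(surface$q))
  taus <- sort(unique(surface$tau))
  w <- if ("sigma" %in% names(surface)) 1 / surface$sigma else rep(1, nrow(surface))
  model_isf <- function(d) {
    gd <- gaussian_membrane(g$l_alpha, g$l_xy, d)
    sur <- nse_curve(stack, gd, p = NULL, q = qs, tau = taus)
    key <- paste(sur$q, sur$tau)
    stats::setNames(sur$isf, key)[paste(surface$q, surface$tau)]
  }
  resid_fun <- function(theta) (model_isf(theta[1]) - surface$isf) * w
  fit <- minpack.lm::nls.lm(par = d_start, fn = resid_fun, lower = 0,
                            control = minpack.lm::nls.lm.control(maxiter = 100,
                                                                 ftol = 1e-12))
  dof <- nrow(surface) - 1
  chi2 <- fit$deviance
  d_se <- tryCatch(sqrt(chi2 / max(dof, 1) / fit$hessian[1, 1]), error = function(e) NA_real_)
  d_hat <- fit$par[1]
  structure(list(
    model = "gaussian-nse", par = c(d = d_hat), se = c(d = d_se),
    d = d_hat, d_se = d_se,
    tau_c = if (d_hat > 0) g$l_xy^2 / (4 * d_hat) else Inf,
    tau_c_formula = "tau_c = l_xy^2 / (4 D)",
    chi2 = chi2, dof = dof, chi2_red = chi2 / max(dof, 1),
    fitted_isf = model_isf(d_hat), data = surface,
    deviance_trace = fit$rsstrace, info = fit$info, message = fit$message
  ), class = "memsas_fit")
}

#' Export a fit report as JSON
#'
#' @param fit A `memsas_fit`.
#' @param path Output path; written atomically.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "memsas_fit"))
  rep <- list(
    software = paste0("memsas ", as.character(utils::packageVersion("memsas"))),
    model = fit$model,
    parameters = as.list(fit$par),
    uncertainties = as.list(fit$se),
    fixed = fit$fixed,
    chi2 = fit$chi2, dof = fit$dof, chi2_red = fit$chi2_red
  )
  if (!is.null(fit$tau_c)) {
    rep$tau_c_ns <- fit$tau_c
    rep$tau_c_formula <- fit$tau_c_formula
  }
  if (!is.null(fit$total_thickness) && is.finite(fit$total_thickness)) {
    rep$total_thickness_A <- fit$total_thickness
  }
  if (!is.null(fit$scale)) {
    rep$scale <- fit$scale
    rep$background <- fit$background
    rep$radiations <- fit$radiations
  }
  write_atomic(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE),
               path)
  invisible(path)
}
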