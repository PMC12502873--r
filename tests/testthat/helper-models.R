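# Shared model builders and small independent oracles used across tests.

rbc_bilayer <- function(radiation = "neutron", l_c = 16.3, l_h = 5.0, l_s = 0) {
  s <- rbc_sld_table(radiation)
  symmetric_bilayer(l_c = l_c, l_h = l_h, l_s = l_s,
                    rho_c = s$rho_c, rho_h = s$rho_h, rho_w = s$rho_w)
}

rbc_protein <- function(radiation = "neutron", phi_p = 0.23, r_p = 21.4,
                        lateral_model = "boolean", d_p = 0) {
  s <- rbc_sld_table(radiation)
  protein_spec(r_p = r_p, rho_p = s$rho_p, phi_p = phi_p,
               lateral_model = lateral_model, d_p = d_p)
}

fit_q_grid <- function(n = 100, q_min = 8e-3, q_max = 0.5) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

# Bessel J1 by its power series (independent of base besselJ)
j1_series <- function(x, n_terms = 40) {
  k <- 0:(n_terms - 1)
  vapply(x, function(xi) {
    sum((-1)^k / (factorial(k) * factorial(k + 1)) * (xi / 2)^(2 * k + 1))
  }, numeric(1))
}

# Monte-Carlo intersection area of two discs of radius r at centre distance d:
# sample points in one disc, count how many fall in the other
mc_lens_area <- function(d, r, n = 2e5, seed = 42) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rad <- r * sqrt(runif(n))
  x <- rad * cos(th)
  y <- rad * sin(th)
  pi * r^2 * mean((x - d)^2 + y^2 <= r^2)
}

# numerical quadrature of the slab amplitude (oracle for slab_amplitude);
# integrates layer by layer so each integrand is smooth
quad_amplitude <- function(stack, q, reference_sld) {
  n <- length(stack$sld)
  re <- 0; im <- 0
  for (j in seq_len(n)) {
    dr <- stack$sld[j] - reference_sld
    if (dr == 0) next
    lo <- stack$boundaries[j]; hi <- stack$boundaries[j + 1]
    quad <- function(f) {
      tryCatch(stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-20)$value,
               error = function(e) stats::integrate(f, lo, hi, rel.tol = 1e-10)$value)
    }
    re <- re + quad(function(z) dr * cos(q * z))
    im <- im + quad(function(z) dr * sin(q * z))
  }
  complex(real = re, imaginary = im)
}

# random valid layer stack for property tests
random_stack <- function(n_layers = sample(1:5, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  boundaries <- sort(runif(n_layers + 1, -40, 40))
  while (any(diff(boundaries) < 0.5)) {
    boundaries <- sort(runif(n_layers + 1, -40, 40))
  }
  layer_stack(boundaries, runif(n_layers, -5e-6, 15e-6), runif(1, 0, 1e-5))
}
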