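# ASCII readers and writers for reduced scattering data and YAML model
# configuration files. All writes are atomic (temp file + rename).

#' @noRd
read_numeric_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("'%s' contains no data rows", path), call. = FALSE)
  rows <- lapply(lines, function(l) {
    suppressWarnings(as.numeric(strsplit(l, "[,[:space:]]+")[[1]]))
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    stop(sprintf("'%s' has rows with differing column counts", path), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a reduced small-angle scattering curve from ASCII
#'
#' Parses whitespace- or comma-delimited columns `q [1/A]`, `I` and
#' optionally `sigma`; lines starting with `#` are comments. Rows containing
#' non-finite values are dropped (with a logged count).
#'
#' @param path File path.
#' @param radiation `"neutron"` or `"xray"`.
#' @return A [scattering_curve()].
#' @export
read_sas_ascii <- function(path, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  m <- read_numeric_table(path)
  if (ncol(m) < 2L) {
    stop(sprintf("'%s' needs at least 2 columns (q, I)", path), call. = FALSE)
  }
  finite <- rowSums(!is.finite(m)) == 0
  if (any(!finite)) {
    msg_info("dropped %d non-finite row(s) while reading '%s'", sum(!finite), path)
    m <- m[finite, , drop = FALSE]
  }
  if (!nrow(m)) stop(sprintf("'%s' has no finite data rows", path), call. = FALSE)
  if (nrow(m) > 1 && any(diff(m[, 1]) <= 0)) {
    stop(sprintf("'%s': q column must be strictly increasing", path), call. = FALSE)
  }
  scattering_curve(m[, 1], m[, 2],
                   sigma = if (ncol(m) >= 3L) m[, 3],
                   radiation = radiation)
}

#' Write a scattering curve as 3-column ASCII
#'
#' Writes `q`, `I` and `sigma` (filled with `NA`-free zeros omitted; when no
#' uncertainties are present only two columns are written), preceded by `#`
#' header lines recording the supplied parameter set.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param header Named list recorded as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_sas_ascii <- function(curve, path, header = list()) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c(
    sprintf("# memsas scattering curve (%s)", attr(curve, "radiation")),
    "# columns: q_invA intensity [sigma]",
    vapply(names(header), function(k) sprintf("# %s: %s", k, format(header[[k]])),
           character(1))
  )
  body <- if ("sigma" %in% names(curve)) {
    sprintf("%.10e %.10e %.10e", curve$q, curve$i, curve$sigma)
  } else {
    sprintf("%.10e %.10e", curve$q, curve$i)
  }
  write_atomic(c(hdr, body), path)
}

#' Read an NSE table from ASCII
#'
#' Parses columns `q [1/A]`, `tau [ns]`, `I(q,tau)/I(q,0)` and optionally
#' `sigma` into an [isf_surface()] on the union grid. Duplicate `(q, tau)`
#' rows are an error; `tau = 0` rows far from 1 trigger a warning.
#'
#' @param path File path.
#' @return An [isf_surface()].
#' @export
read_nse_table <- function(path) {
  m <- read_numeric_table(path)
  if (ncol(m) < 3L) {
    stop(sprintf("'%s' needs at least 3 columns (q, tau, isf)", path), call. = FALSE)
  }
  finite <- rowSums(!is.finite(m)) == 0
  if (any(!finite)) {
    msg_info("dropped %d non-finite row(s) while reading '%s'", sum(!finite), path)
    m <- m[finite, , drop = FALSE]
  }
  surf <- isf_surface(m[, 1], m[, 2], m[, 3],
                      sigma = if (ncol(m) >= 4L) m[, 4])
  # flag missing cells of the union grid
  full <- expand.grid(q = unique(surf$q), tau = unique(surf$tau))
  missing_n <- nrow(full) - nrow(surf)
  if (missing_n > 0) {
    msg_info("'%s': %d missing (q, tau) cell(s) on the union grid", path, missing_n)
  }
  surf
}

#' Write an NSE surface as 4-column ASCII
#'
#' @param surface An [isf_surface()].
#' @param path Output path.
#' @param header Named list recorded as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_nse_table <- function(surface, path, header = list()) {
  stopifnot(inherits(surface, "isf_surface"))
  hdr <- c(
    "# memsas NSE table",
    "# columns: q_invA tau_ns isf [sigma]",
    vapply(names(header), function(k) sprintf("# %s: %s", k, format(header[[k]])),
           character(1))
  )
  body <- if ("sigma" %in% names(surface)) {
    sprintf("%.8e %.8e %.10e %.10e", surface$q, surface$tau, surface$isf, surface$sigma)
  } else {
    sprintf("%.8e %.8e %.10e", surface$q, surface$tau, surface$isf)
  }
  write_atomic(c(hdr, body), path)
}

#' Write an in-plane correlation table as 2-column ASCII
#'
#' @param r_xy Separations in A.
#' @param c_p Correlation values (e.g. from [boolean_correlation()]).
#' @param path Output path.
#' @param header Named list recorded as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_correlation_table <- function(r_xy, c_p, path, header = list()) {
  stopifnot(length(r_xy) == length(c_p))
  hdr <- c("# memsas in-plane correlation table",
           "# columns: r_xy_A c_p",
           vapply(names(header), function(k) sprintf("# %s: %s", k, format(header[[k]])),
                  character(1)))
  write_atomic(c(hdr, sprintf("%.8e %.10e", r_xy, c_p)), path)
}

#' Read a model configuration file
#'
#' Reads a YAML key/value configuration with sections `membrane` (geometry,
#' in A), `membrane_sld`, `solvent`, `protein` and optionally `gaussian`,
#' with explicit units in the key names (`l_c_A`, `rho_c_invA2_neutron`,
#' `d_A2ns`, ...). See the packaged example
#' `system.file("extdata", "rbc_membrane.yaml", package = "memsas")`.
#'
#' @param path File path.
#' @return The parsed configuration list (class `memsas_config`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (sec in c("membrane", "membrane_sld", "solvent")) {
    if (is.null(cfg[[sec]])) {
      stop(sprintf("config '%s' lacks the [%s] section", path, sec), call. = FALSE)
    }
  }
  structure(cfg, class = "memsas_config")
}

#' Build model objects from a configuration
#'
#' @param cfg A `memsas_config` from [read_model_config()].
#' @param radiation `"neutron"` or `"xray"`.
#' @return `config_bilayer()`: a [symmetric_bilayer()];
#'   `config_protein()`: a [protein_spec()] or `NULL` when the config has no
#'   protein section; `config_gaussian()`: a [gaussian_membrane()] or `NULL`.
#' @export
config_bilayer <- function(cfg, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  m <- cfg$membrane; s <- cfg$membrane_sld; w <- cfg$solvent
  pick <- function(lst, stem) {
    v <- lst[[paste0(stem, "_", radiation)]]
    if (is.null(v)) v <- lst[[stem]]
    if (is.null(v)) stop(sprintf("config lacks '%s' for %s", stem, radiation),
                         call. = FALSE)
    v
  }
  symmetric_bilayer(
    l_c = m$l_c_A, l_h = m$l_h_A, l_s = if (is.null(m$l_s_A)) 0 else m$l_s_A,
    rho_c = pick(s, "rho_c_invA2"), rho_h = pick(s, "rho_h_invA2"),
    rho_s = if (is.null(s$rho_s_invA2)) pick(w, "rho_w_invA2") else s$rho_s_invA2,
    rho_w = pick(w, "rho_w_invA2")
  )
}

#' @rdname config_bilayer
#' @export
config_protein <- function(cfg, radiation = c("neutron", "xray")) {
  radiation <- match.arg(radiation)
  p <- cfg$protein
  if (is.null(p)) return(NULL)
  rho_p <- p[[paste0("rho_p_invA2_", radiation)]]
  if (is.null(rho_p)) rho_p <- p$rho_p_invA2
  protein_spec(
    r_p = p$r_p_A, a = p$a_A, b = p$b_A, rho_p = rho_p,
    theta_p = p$theta_p_invA2, phi_p = p$phi_p,
    lateral_model = if (is.null(p$lateral_model)) "boolean" else p$lateral_model,
    d_p = if (is.null(p$d_p_A2ns)) 0 else p$d_p_A2ns
  )
}

#' @rdname config_bilayer
#' @export
config_gaussian <- function(cfg, ...) {
  gsec <- cfg$gaussian
  if (is.null(gsec)) return(NULL)
  gaussian_membrane(l_alpha = gsec$l_alpha_A, l_xy = gsec$l_xy_A,
                    d = if (is.null(gsec$d_A2ns)) 0 else gsec$d_A2ns)
}
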