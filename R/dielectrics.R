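# Dispersive dielectric model of brain tissue: 4-term Cole-Cole relaxation,
# per-tissue property tables, and anisotropic admittivity tensor construction.

#' Vacuum permittivity (F/m)
#'
#' The value used throughout the package when converting relative
#' permittivity into admittivity. The rounded engineering constant is used
#' so that the shipped tissue table reproduces its published reference
#' values digit-for-digit.
#' @export
EPS0 <- 8.854e-12

#' Cole-Cole dispersion parameters
#'
#' Container for a 4-term Cole-Cole description of a dispersive dielectric:
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \sum_{n=1}^{4} \frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} +
#'   \frac{\sigma_i}{j\omega\varepsilon_0}}
#'
#' @param eps_inf high-frequency relative permittivity.
#' @param delta_eps numeric(4), relative permittivity increments (>= 0).
#' @param tau numeric(4), relaxation times in seconds (> 0).
#' @param alpha numeric(4), broadening exponents in `[0, 1)`.
#' @param sigma_ionic static ionic conductivity in S/m (>= 0).
#' @return an object of class `cole_cole_params`.
#' @export
cole_cole_params <- function(eps_inf, delta_eps, tau, alpha, sigma_ionic) {
  stopifnot(length(delta_eps) == 4L, length(tau) == 4L, length(alpha) == 4L)
  if (any(tau <= 0)) stop("all relaxation times tau must be > 0")
  if (any(delta_eps < 0)) stop("delta_eps must be >= 0")
  if (any(alpha < 0 | alpha >= 1)) stop("alpha must lie in [0, 1)")
  if (sigma_ionic < 0) stop("sigma_ionic must be >= 0")
  structure(list(eps_inf = eps_inf, delta_eps = as.numeric(delta_eps),
                 tau = as.numeric(tau), alpha = as.numeric(alpha),
                 sigma_ionic = sigma_ionic),
            class = "cole_cole_params")
}

#' Constant (non-dispersive) material
#'
#' @param name tissue label.
#' @param sigma conductivity, S/m.
#' @param eps_r relative permittivity.
#' @return an object of class `const_material`.
#' @export
const_material <- function(name, sigma, eps_r = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(name = name, sigma = sigma, eps_r = eps_r),
            class = "const_material")
}

# Gabriel-type 4-term Cole-Cole constants for brain tissues. These parameter
# sets are the standard literature description of tissue dispersion between
# Hz and GHz; only the first three terms matter below 1 MHz.
.cole_cole_library <- function() {
  list(
    grey_matter = cole_cole_params(
      eps_inf = 4,
      delta_eps = c(45, 400, 2.0e5, 4.5e7),
      tau = c(7.958e-12, 15.915e-9, 106.103e-6, 5.305e-3),
      alpha = c(0.10, 0.15, 0.22, 0.00),
      sigma_ionic = 0.02),
    white_matter = cole_cole_params(
      eps_inf = 4,
      delta_eps = c(32, 100, 4.0e4, 3.5e7),
      tau = c(7.958e-12, 7.958e-9, 53.052e-6, 7.958e-3),
      alpha = c(0.10, 0.10, 0.30, 0.02),
      sigma_ionic = 0.02),
    csf = cole_cole_params(
      eps_inf = 4,
      delta_eps = c(65, 40, 0, 0),
      tau = c(7.96e-12, 1.592e-9, 159.155e-6, 15.915e-3),
      alpha = c(0.10, 0.00, 0.00, 0.00),
      sigma_ionic = 2.0)
  )
}

#' Complex relative permittivity of a Cole-Cole material
#'
#' Evaluates the 4-term Cole-Cole model at frequency `f`. The real part is
#' the relative permittivity; the effective conductivity follows as
#' `sigma(w) = w * EPS0 * (-Im eps*)`.
#'
#' @param p a [cole_cole_params] object.
#' @param f frequency in Hz (> 0); vectorized.
#' @return complex relative permittivity, same length as `f`.
#' @export
complex_permittivity <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  if (any(f <= 0))
    stop("complex_permittivity requires f > 0; use dc_conductivity() at DC")
  w <- 2 * pi * f
  eps <- rep(p$eps_inf + 0i, length(f))
  for (n in 1:4) {
    eps <- eps + p$delta_eps[n] /
      (1 + (1i * w * p$tau[n])^(1 - p$alpha[n]))
  }
  eps + p$sigma_ionic / (1i * w * EPS0)
}

#' DC conductivity of a material
#' @param m a `cole_cole_params` or `const_material` object.
#' @return conductivity in S/m at f = 0.
#' @export
dc_conductivity <- function(m) {
  if (inherits(m, "cole_cole_params")) m$sigma_ionic
  else if (inherits(m, "const_material")) m$sigma
  else stop("unknown material type")
}

#' Effective conductivity and permittivity of a material at a frequency
#'
#' @param m a `cole_cole_params` or `const_material` object.
#' @param f frequency, Hz (>= 0).
#' @return list with `sigma` (S/m) and `eps_r` (dimensionless).
#' @export
material_sigma_eps <- function(m, f) {
  if (inherits(m, "const_material"))
    return(list(sigma = m$sigma, eps_r = m$eps_r))
  if (f <= 0) return(list(sigma = m$sigma_ionic, eps_r = 0))
  eps <- complex_permittivity(m, f)
  list(sigma = 2 * pi * f * EPS0 * (-Im(eps)), eps_r = Re(eps))
}

#' Build the default tissue table
#'
#' Maps tissue labels to dielectric descriptions. Grey matter, white matter
#' and CSF carry the embedded Cole-Cole constants. The fibrotic
#' encapsulation layer around the lead is modelled as grey matter with its
#' conductivity scaled by `encapsulation_scale` (default 0.5) and unchanged
#' permittivity. `unknown` defaults to grey matter.
#'
#' @param encapsulation_scale conductivity scale of the encapsulation layer
#'   relative to grey matter.
#' @param overrides named list; each entry either a `cole_cole_params` /
#'   `const_material` object or a list with `sigma` (and optional `eps_r`)
#'   defining a constant material.
#' @return an object of class `tissue_table`.
#' @export
tissue_table <- function(encapsulation_scale = 0.5, overrides = list()) {
  lib <- .cole_cole_library()
  tab <- list(grey_matter = lib$grey_matter,
              white_matter = lib$white_matter,
              csf = lib$csf,
              unknown = lib$grey_matter)
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (inherits(ov, "cole_cole_params") || inherits(ov, "const_material")) {
      tab[[nm]] <- ov
    } else if (is.list(ov) && !is.null(ov$sigma)) {
      tab[[nm]] <- const_material(nm, ov$sigma,
                                  if (is.null(ov$eps_r)) 1 else ov$eps_r)
    } else stop("invalid tissue override for label '", nm, "'")
  }
  structure(list(table = tab, encapsulation_scale = encapsulation_scale),
            class = "tissue_table")
}

#' Conductivity and relative permittivity for a tissue label
#'
#' @param table a [tissue_table].
#' @param label tissue label. `encapsulation` resolves to scaled grey
#'   matter unless overridden explicitly.
#' @param f frequency, Hz (>= 0; at 0 the ionic conductivity is returned
#'   and the permittivity term contributes nothing).
#' @param qs_mode if TRUE the permittivity is treated as zero in the
#'   admittivity (quasistatic formulation).
#' @return list with `sigma` (S/m) and `eps_r`.
#' @export
sigma_eps_at <- function(table, label, f, qs_mode = FALSE) {
  stopifnot(inherits(table, "tissue_table"))
  if (identical(label, "encapsulation") && is.null(table$table$encapsulation)) {
    se <- material_sigma_eps(table$table$grey_matter, f)
    se$sigma <- se$sigma * table$encapsulation_scale
  } else {
    m <- table$table[[label]]
    if (is.null(m))
      stop("unknown tissue label '", label, "'; known labels: ",
           paste(c(names(table$table), "encapsulation"), collapse = ", "))
    se <- material_sigma_eps(m, f)
  }
  if (qs_mode || f <= 0) se$eps_r <- 0
  se
}

#' Complex admittivity tensor
#'
#' Builds the cell-level complex admittivity `D * sigma + j w EPS0 eps_r I`.
#' The anisotropy weighting `D` applies to the conductive part only; the
#' permittivity stays isotropic.
#'
#' @param sigma conductivity, S/m.
#' @param eps_r relative permittivity.
#' @param f frequency, Hz.
#' @param D optional symmetric positive semi-definite 3x3 weighting matrix;
#'   `NULL` means isotropic (identity weighting).
#' @return complex symmetric 3x3 matrix.
#' @export
admittivity_tensor <- function(sigma, eps_r, f, D = NULL) {
  if (is.null(D)) D <- diag(3)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("anisotropy weighting D must be symmetric")
  D * sigma + 1i * 2 * pi * f * EPS0 * eps_r * diag(3)
}

#' Known labels of a tissue table
#' @param table a [tissue_table].
#' @return character vector of labels the table resolves.
#' @export
tissue_labels <- function(table) {
  unique(c(names(table$table), "encapsulation"))
}
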