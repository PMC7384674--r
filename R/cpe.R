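# Lumped constant-phase-element (CPE) model of the electrode-tissue
# interface (the non-Faradaic double layer) and the voltage-controlled
# boundary correction. The interface is assumed in series with the tissue;
# current-controlled fields are unaffected by it.

#' Constant-phase-element parameters
#'
#' Impedance model `Z_CPE = K_S / (j w)^alpha` of the electrode double
#' layer. `alpha = 0` is a pure resistor, `alpha = 1` an ideal capacitor.
#' `K_S` depends on contact geometry; [cpe_from_area] derives it from an
#' area-specific value.
#'
#' @param K_S scaling factor, Ohm * s^alpha (> 0).
#' @param alpha phase exponent in `[0, 1]`.
#' @return an object of class `cpe_params`.
#' @export
cpe_params <- function(K_S, alpha = 0.7) {
  if (K_S <= 0) stop("K_S must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(K_S = K_S, alpha = alpha), class = "cpe_params")
}

#' CPE parameters from an area-specific scaling factor
#'
#' @param K_S_area area-specific scaling factor, Ohm * m^2 * s^alpha.
#' @param area_mm2 contact area in mm^2.
#' @param alpha phase exponent.
#' @return a [cpe_params] object with `K_S = K_S_area / area`.
#' @export
cpe_from_area <- function(K_S_area, area_mm2, alpha = 0.7) {
  if (area_mm2 <= 0) stop("contact area must be > 0")
  cpe_params(K_S_area / (area_mm2 * 1e-6), alpha)
}

#' CPE impedance at a frequency
#'
#' @param p a [cpe_params] object.
#' @param f frequency, Hz (> 0); vectorized.
#' @return complex impedance, Ohm.
#' @export
cpe_impedance <- function(p, f) {
  stopifnot(inherits(p, "cpe_params"))
  if (any(f <= 0))
    stop("cpe_impedance requires f > 0 (treat DC as an open circuit for alpha > 0)")
  p$K_S / (1i * 2 * pi * f)^p$alpha
}

#' Corrected contact voltages under a series CPE model
#'
#' Series voltage divider: the two interface impedances and the tissue
#' impedance share the source voltage,
#' `V_CPEi = V_source * Z_CPEi / (Z_tissue + Z_CPE1 + Z_CPE2)`.
#' Each contact's Dirichlet value is reduced by the drop over its own CPE,
#' so the tissue retains `V_source * Z_tissue / Z_total`; the field problem
#' is then re-solved with the corrected boundary values.
#'
#' @param V_source source voltage (assigned between the two active
#'   contacts), V.
#' @param Z_tissue complex tissue impedance `V_source / J_source`, Ohm.
#' @param cpe1,cpe2 [cpe_params] of the two active contacts, or `NULL` for
#'   an ideal (zero-impedance) interface.
#' @param f frequency, Hz.
#' @param contact_values numeric(2), the uncorrected Dirichlet values of
#'   the two active contacts (default `c(V_source, 0)`).
#' @return list with `contact_values` (corrected Dirichlet pair),
#'   `V_tissue`, `V_cpe` (complex drops over the two CPEs).
#' @export
corrected_contact_voltages <- function(V_source, Z_tissue, cpe1, cpe2, f,
                                       contact_values = c(V_source, 0)) {
  Z1 <- if (is.null(cpe1)) 0 + 0i else cpe_impedance(cpe1, f)
  Z2 <- if (is.null(cpe2)) 0 + 0i else cpe_impedance(cpe2, f)
  Ztot <- Z_tissue + Z1 + Z2
  if (Mod(Ztot) == 0) stop("zero total impedance in CPE correction")
  V1 <- V_source * Z1 / Ztot
  V2 <- V_source * Z2 / Ztot
  list(contact_values = c(contact_values[1] - V1, contact_values[2] + V2),
       V_tissue = V_source * Z_tissue / Ztot,
       V_cpe = c(V1, V2))
}
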