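#' Material properties of a phantom constituent
#'
#' Bundles the acoustic and mechanical parameters of one agar mixture:
#' acoustic impedance (MRayl), speed of sound (m/s), bulk stiffness of the
#' pure material (N/mm) and ultrasonic attenuation (dB/cm) at a stated
#' reference frequency.
#'
#' @param acoustic_impedance Acoustic impedance in MRayl. Must be positive.
#' @param speed_of_sound Longitudinal speed of sound in m/s. Must be positive.
#' @param stiffness Indentation stiffness of a block made purely of this
#'   material, in N/mm. Must be positive.
#' @param attenuation One-way ultrasonic attenuation in dB/cm at
#'   `attenuation_ref_mhz`. Must be positive.
#' @param attenuation_ref_mhz Frequency (MHz) at which `attenuation` was
#'   measured; recorded alongside the value.
#' @return An object of class `material_props`.
#' @seealso [healthy_material()], [tumor_material()]
#' @export
#' @examples
#' material_props(1.59, 1457, 0.33)
material_props <- function(acoustic_impedance, speed_of_sound, stiffness,
                           attenuation = 1.25, attenuation_ref_mhz = 16) {
  vals <- c(acoustic_impedance = acoustic_impedance,
            speed_of_sound = speed_of_sound,
            stiffness = stiffness,
            attenuation = attenuation,
            attenuation_ref_mhz = attenuation_ref_mhz)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all material properties must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(acoustic_impedance = acoustic_impedance,
                 speed_of_sound = speed_of_sound,
                 stiffness = stiffness,
                 attenuation = attenuation,
                 attenuation_ref_mhz = attenuation_ref_mhz),
            class = "material_props")
}

#' Reference materials: healthy-tissue and tumor-mimicking agar
#'
#' Agar at 2 g/100 mL water mimics soft healthy tissue (1.59 MRayl,
#' 1457 m/s, 0.33 N/mm); agar at 8 g/100 mL mimics a stiff tumor nodule
#' (1.92 MRayl, 1534 m/s, 4.6 N/mm). Both use a one-way attenuation of
#' 1.25 dB/cm at 16 MHz.
#'
#' @return A `material_props` object.
#' @export
healthy_material <- function() {
  material_props(acoustic_impedance = 1.59, speed_of_sound = 1457,
                 stiffness = 0.33, attenuation = 1.25,
                 attenuation_ref_mhz = 16)
}

#' @rdname healthy_material
#' @export
tumor_material <- function() {
  material_props(acoustic_impedance = 1.92, speed_of_sound = 1534,
                 stiffness = 4.6, attenuation = 1.25,
                 attenuation_ref_mhz = 16)
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf(
    "material: Z = %.3g MRayl, c = %.4g m/s, k = %.3g N/mm, alpha = %.3g dB/cm @ %g MHz\n",
    x$acoustic_impedance, x$speed_of_sound, x$stiffness,
    x$attenuation, x$attenuation_ref_mhz))
  invisible(x)
}

#' Intensity reflection coefficient at a planar interface
#'
#' For normal incidence on a planar interface between media with acoustic
#' impedances Z1 and Z2, the fraction of incident intensity reflected is
#' `((Z2 - Z1) / (Z2 + Z1))^2`. It is symmetric in its arguments, lies in
#' \[0, 1) and is zero iff the impedances are equal. For the reference
#' healthy/tumor pair the value is about 0.0088 (< 1%), which is why the
#' echo reflected off the steel base plate dominates any echo reflected
#' directly off an inclusion.
#'
#' @param m1,m2 `material_props` objects or bare positive impedances (MRayl).
#' @return Dimensionless intensity fraction in \[0, 1).
#' @export
#' @examples
#' reflection_coefficient_intensity(healthy_material(), tumor_material())
reflection_coefficient_intensity <- function(m1, m2) {
  z <- function(m) if (inherits(m, "material_props")) m$acoustic_impedance else m
  z1 <- z(m1); z2 <- z(m2)
  if (!is.numeric(z1) || !is.numeric(z2) || length(z1) != 1L ||
      length(z2) != 1L || !is.finite(z1) || !is.finite(z2) ||
      z1 <= 0 || z2 <= 0) {
    stop("acoustic impedances must be single positive numbers", call. = FALSE)
  }
  ((z2 - z1) / (z2 + z1))^2
}
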