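#' Optical model parameters
#'
#' Underwater light is modelled with the Lambert-Beer law,
#' \eqn{I_z/I_0 = e^{-KZ}}, with the attenuation coefficient taken from
#' Secchi depth through the Poole-Atkins relation \eqn{K = c / SD}. The
#' classical constant is \eqn{c = 1.7}; sensitivity analyses commonly vary
#' it over 1.6-2.0. The maximum depth of colonization (MDC) of rooted
#' submerged plants is the depth still receiving a fixed fraction of
#' surface irradiance: about 0.20 for angiosperm-dominated communities and
#' 0.11 for charophytes.
#'
#' @param poole_atkins_k Dimensionless Poole-Atkins constant (default 1.7),
#'   so that `K = poole_atkins_k / secchi` in 1/m.
#' @param light_fraction_mdc Fraction of surface irradiance defining the
#'   MDC, in (0, 1); default 0.2 (angiosperms), alternative 0.11
#'   (charophytes).
#' @return A `light_params` list.
#' @export
#' @examples
#' p <- light_params()
#' attenuation_coefficient(1.0, p)       # 1.7 per metre
#' max_depth_colonization(0.57, p)       # ~0.54 m
#' percent_irradiance(2, 0.7, p)         # light fraction at 2 m depth
light_params <- function(poole_atkins_k = 1.7, light_fraction_mdc = 0.2) {
  if (poole_atkins_k <= 0) stop_domain("`poole_atkins_k` must be positive.")
  if (light_fraction_mdc <= 0 || light_fraction_mdc >= 1) {
    stop_domain("`light_fraction_mdc` must lie strictly between 0 and 1.")
  }
  structure(list(poole_atkins_k = poole_atkins_k,
                 light_fraction_mdc = light_fraction_mdc),
            class = "light_params")
}

check_secchi <- function(secchi) {
  if (any(!is.na(secchi) & secchi <= 0)) {
    stop_domain("Secchi depth must be positive.")
  }
  invisible(secchi)
}

#' Light attenuation coefficient from Secchi depth
#'
#' Poole-Atkins proxy `K = c / SD` (1/m), used because downwelling
#' irradiance is rarely profiled directly in field surveys.
#'
#' @param secchi Secchi depth in metres (> 0); vectorised.
#' @param params A [light_params()] object.
#' @return Attenuation coefficient K in 1/m.
#' @export
attenuation_coefficient <- function(secchi, params = light_params()) {
  check_secchi(secchi)
  params$poole_atkins_k / secchi
}

#' Maximum depth of colonization
#'
#' Depth at which irradiance has decayed to `light_fraction_mdc` of its
#' surface value: `MDC = -log(f) * SD / c`. Linear in Secchi depth; with
#' the defaults the slope is \eqn{-\ln(0.2)/1.7 \approx 0.9467} m of MDC
#' per m of Secchi depth.
#'
#' @inheritParams attenuation_coefficient
#' @return MDC in metres.
#' @export
max_depth_colonization <- function(secchi, params = light_params()) {
  check_secchi(secchi)
  -log(params$light_fraction_mdc) * secchi / params$poole_atkins_k
}

#' Fraction of surface irradiance at depth
#'
#' `exp(-c * depth / SD)`, in (0, 1]; 1 at the surface. Fractions are kept
#' on the 0-1 scale throughout; conversion to percent happens only in
#' reporting.
#'
#' @param depth Depth in metres (>= 0); vectorised, recycled against
#'   `secchi`.
#' @inheritParams attenuation_coefficient
#' @return Fraction of surface irradiance reaching `depth`.
#' @export
percent_irradiance <- function(depth, secchi, params = light_params()) {
  if (any(!is.na(depth) & depth < 0)) stop_domain("`depth` must be non-negative.")
  check_secchi(secchi)
  exp(-params$poole_atkins_k * depth / secchi)
}
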