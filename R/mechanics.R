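#' DNA mechanics and thermal constants
#'
#' Bundle of the physical constants entering the extensible worm-like-chain
#' (WLC) description of bare DNA: persistence length \eqn{A}, stretch modulus
#' \eqn{S}, thermal energy \eqn{k_B T} and the helical rise used to convert
#' base pairs to contour length.
#'
#' @param persistence_length Bending persistence length \eqn{A} in nm.
#'   Default 50 nm.
#' @param stretch_modulus Enthalpic stretch modulus \eqn{S} in pN.
#'   Default 1200 pN.
#' @param thermal_energy \eqn{k_B T} in pN nm. Default 4.10 pN nm
#'   (about 297 K); the working temperature is configurable here since
#'   energies are reported in \eqn{k_B T} units at output boundaries.
#' @param rise_per_bp Contour length per base pair in nm/bp. Default 0.34.
#'
#' @return An object of class `mechanics_params`.
#' @examples
#' mech <- mechanics_params()
#' wlc_extension(5, 680, mech)
#' @export
mechanics_params <- function(persistence_length = 50,
                             stretch_modulus = 1200,
                             thermal_energy = 4.10,
                             rise_per_bp = 0.34) {
  stopifnot(is.numeric(persistence_length), persistence_length > 0,
            is.numeric(stretch_modulus), stretch_modulus > 0,
            is.numeric(thermal_energy), thermal_energy > 0,
            is.numeric(rise_per_bp), rise_per_bp > 0)
  structure(list(persistence_length = persistence_length,
                 stretch_modulus = stretch_modulus,
                 thermal_energy = thermal_energy,
                 rise_per_bp = rise_per_bp),
            class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat("DNA mechanics: A =", x$persistence_length, "nm, S =",
      x$stretch_modulus, "pN, kBT =", x$thermal_energy,
      "pN nm, rise =", x$rise_per_bp, "nm/bp\n")
  invisible(x)
}

#' Extensible worm-like-chain extension
#'
#' High-force extensible WLC: \deqn{z(f, L) = L [1 - \frac{1}{2}
#' \sqrt{k_B T / (f A)} + f/S].} Valid above the entropic low-force regime;
#' the fitting routines exclude forces below 0.5 pN, and forces \eqn{\le 0}
#' are rejected here because the square-root term diverges.
#'
#' @param f Force in pN (vectorised); must be positive.
#' @param L Contour length in nm; must be non-negative.
#' @param mech A [mechanics_params()] object.
#' @return Extension in nm, linear in `L`.
#' @export
wlc_extension <- function(f, L, mech = mechanics_params()) {
  stopifnot(inherits(mech, "mechanics_params"))
  if (any(f <= 0)) stop("wlc_extension requires f > 0")
  if (any(L < 0)) stop("wlc_extension requires L >= 0")
  L * (1 - 0.5 * sqrt(mech$thermal_energy / (f * mech$persistence_length)) +
         f / mech$stretch_modulus)
}

#' Worm-like-chain stretching free energy
#'
#' Free energy of the extensible WLC obtained by integrating the extension
#' over force from 0 to `f`:
#' \deqn{G(f, L) = -L [f - \sqrt{f k_B T / A} + f^2 / (2S)],}
#' in pN nm, so that \eqn{-\partial G/\partial f} reproduces
#' [wlc_extension()].
#'
#' @inheritParams wlc_extension
#' @param f Force in pN (vectorised); must be non-negative.
#' @return Free energy in pN nm (non-positive).
#' @export
wlc_free_energy <- function(f, L, mech = mechanics_params()) {
  stopifnot(inherits(mech, "mechanics_params"))
  if (any(f < 0)) stop("wlc_free_energy requires f >= 0")
  if (any(L < 0)) stop("wlc_free_energy requires L >= 0")
  -L * (f - sqrt(f * mech$thermal_energy / mech$persistence_length) +
          f^2 / (2 * mech$stretch_modulus))
}

#' Hookean extension of a fiber-folded nucleosome
#'
#' Nucleosomes folded in a chromatin fiber respond linearly to force:
#' \eqn{z(f) = f/k + z_0}, with the stiffness `k` expressed per nucleosome
#' and `z0` the contour length per nucleosome of the folded fiber.
#'
#' @param f Force in pN, non-negative (vectorised).
#' @param k Fiber stiffness per nucleosome in pN/nm; must be positive.
#' @param z0 Fiber contour length per nucleosome in nm.
#' @return Extension per nucleosome in nm.
#' @export
fiber_extension <- function(f, k, z0) {
  if (any(f < 0)) stop("fiber_extension requires f >= 0")
  if (!is.numeric(k) || any(k <= 0)) stop("fiber_extension requires k > 0")
  f / k + z0
}

#' Free energy of the Hookean fiber element
#'
#' Integral of [fiber_extension()] over force:
#' \eqn{G(f) = -f^2/(2k) - f z_0}, in pN nm.
#'
#' @inheritParams fiber_extension
#' @return Free energy in pN nm.
#' @export
fiber_free_energy <- function(f, k, z0) {
  if (any(f < 0)) stop("fiber_free_energy requires f >= 0")
  if (!is.numeric(k) || any(k <= 0)) stop("fiber_free_energy requires k > 0")
  -f^2 / (2 * k) - f * z0
}
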