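#' Degradation-erosion parameters for the PLGA fiber phase
#'
#' Bundles the constants of the degradation model that drives the
#' time-dependent effective diffusivity of the polymer fiber phase:
#' exponential molecular-weight decay raises the solid-phase diffusivity,
#' while growing porosity mixes in the diffusivity of liquid-filled pores,
#' moderated by an intra-fiber pore/solid partitioning coefficient.
#'
#' @param Ds0 Solid-phase diffusivity at the initial molecular weight
#'   (um^2/s). Default 0.04, the fiber diffusivity of the RhB/Span-80
#'   complex in PLGA.
#' @param Dl Diffusivity in liquid-filled pores inside the fiber (um^2/s).
#'   Defaults to `Ds0` (neutral setting: pore growth alone does not
#'   accelerate transport beyond molecular-weight decay).
#' @param kappa Dimensionless pore/solid partitioning inside the fiber.
#'   Default 1 (no intra-fiber partitioning). Distinct from the
#'   fiber-surface partitioning `P` used at the fiber/surrounding interface.
#' @param alpha Dimensionless exponent linking solid diffusivity to relative
#'   molecular weight; default 1.714 (experimentally determined).
#' @param Mw0 Initial average molecular weight (g/mol). Default 50000.
#' @param kw Molecular-weight decay rate (1/s). Default 2.5e-7.
#' @param k Porosity growth rate (1/s). Default 2.5e-7.
#' @param phi0 Initial porosity (dimensionless in `[0, 1]`). Default 0.
#' @param enabled Logical; `FALSE` freezes the fiber diffusivity at its
#'   initial value `effective_diffusivity(params, 0)`.
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(Ds0 = 0.04, Dl = Ds0, kappa = 1,
                               alpha = 1.714, Mw0 = 5e4, kw = 2.5e-7,
                               k = 2.5e-7, phi0 = 0, enabled = TRUE) {
  stopifnot(
    is.numeric(Ds0), length(Ds0) == 1L, Ds0 > 0,
    is.numeric(Dl), length(Dl) == 1L, Dl > 0,
    is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
    is.numeric(alpha), length(alpha) == 1L,
    is.numeric(Mw0), length(Mw0) == 1L, Mw0 > 0,
    is.numeric(kw), length(kw) == 1L, kw >= 0,
    is.numeric(k), length(k) == 1L, k >= 0,
    is.numeric(phi0), length(phi0) == 1L, phi0 >= 0, phi0 <= 1,
    is.logical(enabled), length(enabled) == 1L
  )
  structure(
    list(Ds0 = Ds0, Dl = Dl, kappa = kappa, alpha = alpha, Mw0 = Mw0,
         kw = kw, k = k, phi0 = phi0, enabled = enabled),
    class = "degradation_params"
  )
}

#' @export
print.degradation_params <- function(x, ...) {
  cat("PLGA degradation parameters",
      if (!x$enabled) "(disabled)" else "", "\n")
  cat(sprintf("  Ds0 = %g um^2/s, Dl = %g um^2/s, kappa = %g, alpha = %g\n",
              x$Ds0, x$Dl, x$kappa, x$alpha))
  cat(sprintf("  Mw0 = %g g/mol, kw = %g 1/s, k = %g 1/s, phi0 = %g\n",
              x$Mw0, x$kw, x$k, x$phi0))
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("time 't' must be finite and >= 0 (seconds)", call. = FALSE)
  }
}

#' Molecular weight of the degrading polymer
#'
#' First-order decay `Mw(t) = Mw0 * exp(-kw * t)`.
#'
#' @param params A [degradation_params()] object.
#' @param t Time in seconds (vectorized), `t >= 0`.
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(params, t) {
  stopifnot(inherits(params, "degradation_params"))
  check_time(t)
  params$Mw0 * exp(-params$kw * t)
}

#' Porosity of the degrading fiber
#'
#' `phi(t) = phi0 + (1 - phi0) * (1 - exp(-k t))^2`, monotone nondecreasing
#' from `phi0` towards 1.
#'
#' @inheritParams molecular_weight
#' @return Porosity (dimensionless).
#' @export
porosity <- function(params, t) {
  stopifnot(inherits(params, "degradation_params"))
  check_time(t)
  e <- exp(-params$k * t)
  params$phi0 + (1 - params$phi0) * (1 - e)^2
}

#' Solid-phase diffusivity as a function of molecular weight
#'
#' `Ds = Ds0 * (Mw / Mw0)^(-alpha)`: diffusivity rises as chains shorten.
#'
#' @param params A [degradation_params()] object.
#' @param Mw Molecular weight in g/mol (vectorized), `Mw > 0`.
#' @return Diffusivity in um^2/s.
#' @export
solid_diffusivity <- function(params, Mw) {
  stopifnot(inherits(params, "degradation_params"))
  if (!is.numeric(Mw) || any(!is.finite(Mw)) || any(Mw <= 0)) {
    stop("'Mw' must be finite and > 0", call. = FALSE)
  }
  params$Ds0 * (Mw / params$Mw0)^(-params$alpha)
}

#' Effective fiber diffusivity under degradation and erosion
#'
#' Composes molecular-weight decay, porosity growth and pore/solid
#' partitioning into the effective fiber-phase diffusivity
#' `D(t) = ((1 - phi) Ds + kappa phi Dl) / (1 - phi + kappa phi)`.
#' With `enabled = FALSE` the value is frozen at `t = 0`.
#'
#' @inheritParams molecular_weight
#' @return Effective diffusivity in um^2/s.
#' @export
effective_diffusivity <- function(params, t) {
  stopifnot(inherits(params, "degradation_params"))
  check_time(t)
  if (!params$enabled) t <- rep(0, length(t))
  phi <- porosity(params, t)
  Ds <- solid_diffusivity(params, molecular_weight(params, t))
  den <- 1 - phi + params$kappa * phi
  if (any(den <= 0)) {
    stop("degenerate partitioning: denominator 1 - phi + kappa*phi <= 0",
         call. = FALSE)
  }
  ((1 - phi) * Ds + params$kappa * phi * params$Dl) / den
}
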