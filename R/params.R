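#' Dimensional biosensor parameters
#'
#' Bundle the dimensional quantities describing the enzyme film on a
#' micro-disk (modelled as a hemisphere of radius `r0` coated by a film
#' extending to `r1`). All quantities are in CGS-style units; only their
#' dimensionless combinations matter for the model, see
#' [to_dimensionless()].
#'
#' If the elementary rate constants `k1` (forward binding), `k_rev`
#' (reverse binding) and `kcat` are all supplied, the Michaelis constant
#' must satisfy `KM = (k_rev + kcat) / k1`; otherwise `KM` is taken at face
#' value. The peroxide concentration scale `CH_star` defaults to `CS_star`,
#' the unique choice under which the dimensionless peroxide balance keeps
#' the same reaction group as the substrate balance.
#'
#' @param DS substrate diffusion coefficient (cm^2/s).
#' @param DH hydrogen-peroxide diffusion coefficient (cm^2/s).
#' @param kcat catalytic rate constant (1/s).
#' @param CE enzyme concentration in the film (mol/cm^3).
#' @param KM Michaelis constant (mol/cm^3).
#' @param r0 electrode (hemisphere) radius (cm).
#' @param r1 outer film radius (cm); must exceed `r0`.
#' @param CS_star bulk substrate concentration (mol/cm^3).
#' @param CH_star peroxide concentration scale (mol/cm^3); defaults to
#'   `CS_star`.
#' @param k1,k_rev optional elementary rate constants; when both are given
#'   together with `kcat` they must be consistent with `KM`.
#'
#' @return An object of class `dimensional_params`.
#' @seealso [to_dimensionless()]
#' @export
#' @examples
#' p <- dimensional_params(DS = 1e-5, DH = 1e-5, kcat = 10, CE = 1e-7,
#'                         KM = 1e-6, r0 = 1e-3, r1 = 5e-3, CS_star = 1e-6)
#' to_dimensionless(p)
dimensional_params <- function(DS, DH, kcat, CE, KM, r0, r1, CS_star,
                               CH_star = CS_star, k1 = NULL, k_rev = NULL) {
  vals <- c(DS = DS, DH = DH, kcat = kcat, CE = CE, KM = KM,
            r0 = r0, r1 = r1, CS_star = CS_star, CH_star = CH_star)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dimensional parameters must be finite and strictly positive")
  }
  if (r1 <= r0) stop("film radius r1 must exceed electrode radius r0")
  if (!is.null(k1) && !is.null(k_rev)) {
    km_implied <- (k_rev + kcat) / k1
    if (abs(km_implied - KM) > 1e-12 * KM) {
      stop("KM inconsistent with (k_rev + kcat)/k1 beyond relative 1e-12")
    }
  }
  structure(list(DS = DS, DH = DH, kcat = kcat, CE = CE, KM = KM,
                 r0 = r0, r1 = r1, CS_star = CS_star, CH_star = CH_star,
                 k1 = k1, k_rev = k_rev),
            class = "dimensional_params")
}

#' Dimensionless model parameters
#'
#' The model is governed by four dimensionless groups: the Thiele-modulus-like
#' reaction--diffusion parameters `gamma_E` (substrate) and `gamma_S`
#' (peroxide), the saturation parameter `alpha = CS*/KM`, and the
#' film-to-electrode radius ratio `q = r1/r0`. The film occupies the
#' dimensionless radial interval `[1, q]`.
#'
#' @param gamma_E substrate reaction--diffusion parameter (> 0).
#' @param gamma_S peroxide reaction--diffusion parameter (> 0).
#' @param alpha saturation parameter (>= 0); `alpha = 0` is first-order
#'   kinetics, large `alpha` the saturated zero-order regime.
#' @param q radius ratio `r1/r0` (> 1).
#'
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(gamma_E = 30, gamma_S = 30, alpha = 100, q = 5)
model_params <- function(gamma_E, gamma_S, alpha, q) {
  stopifnot(is.finite(gamma_E), is.finite(gamma_S), is.finite(alpha),
            is.finite(q))
  if (gamma_E < 0 || gamma_S < 0) {
    stop("reaction-diffusion parameters must be nonnegative")
  }
  if (alpha < 0) stop("saturation parameter alpha must be nonnegative")
  if (q <= 1) stop("radius ratio q = r1/r0 must exceed 1")
  structure(list(gamma_E = gamma_E, gamma_S = gamma_S,
                 alpha = alpha, q = q),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "dimensionless model parameters: gamma_E = %g, gamma_S = %g, alpha = %g, q = %g\n",
    x$gamma_E, x$gamma_S, x$alpha, x$q))
  invisible(x)
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("dimensional biosensor parameters\n")
  cat(sprintf("  DS = %g, DH = %g cm^2/s; kcat = %g 1/s\n", x$DS, x$DH, x$kcat))
  cat(sprintf("  CE = %g, KM = %g, CS* = %g mol/cm^3\n", x$CE, x$KM, x$CS_star))
  cat(sprintf("  r0 = %g, r1 = %g cm (q = %g)\n", x$r0, x$r1, x$r1 / x$r0))
  invisible(x)
}

#' Nondimensionalize biosensor parameters
#'
#' Converts dimensional film parameters into the four dimensionless groups
#' driving the steady-state balances:
#' `alpha = CS*/KM`, `gamma_E = kcat*CE*r0^2/(DS*KM)`,
#' `gamma_S = kcat*CE*r0^2/(DH*KM)`, `q = r1/r0`. The ratio identity
#' `gamma_E/gamma_S = DH/DS` holds by construction.
#'
#' @param p a [dimensional_params()] object.
#' @return A [model_params()] object.
#' @export
to_dimensionless <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  model_params(
    gamma_E = p$kcat * p$CE * p$r0^2 / (p$DS * p$KM),
    gamma_S = p$kcat * p$CE * p$r0^2 / (p$DH * p$KM),
    alpha   = p$CS_star / p$KM,
    q       = p$r1 / p$r0
  )
}

#' Michaelis--Menten reaction term
#'
#' Evaluates the dimensionless rate `gamma * s / (1 + alpha * s)` appearing
#' in both steady-state balances. The term is monotone nondecreasing and
#' concave in `s`, and bounded above by `gamma/alpha` when `alpha > 0`.
#'
#' @param s dimensionless concentration(s), `s >= 0`.
#' @param gamma reaction--diffusion parameter (>= 0).
#' @param alpha saturation parameter (>= 0).
#' @return Rate value(s), same length as `s`.
#' @export
#' @examples
#' mm_rate(1, gamma = 30, alpha = 100)  # 30/101
mm_rate <- function(s, gamma, alpha) {
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("concentration s must be finite and nonnegative")
  }
  if (gamma < 0 || alpha < 0) stop("gamma and alpha must be nonnegative")
  gamma * s / (1 + alpha * s)
}
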