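#' Closed-form approximations to the film concentration profiles
#'
#' The literature offers low-order series approximations for the steady
#' profiles: a modified Adomian decomposition (MADM) pair, a homotopy
#' analysis (HAM) pair with a convergence-control parameter `h`, and a
#' homotopy perturbation (HPM) pair in its own scaled variables. They are
#' evaluated here exactly as published — including in parameter regimes
#' where they leave the physical range — so they can be compared honestly
#' against the reference solver.
#'
#' @name closed_forms
NULL

#' MADM approximation (quadratic in R)
#'
#' With `a = gamma_E/(1+alpha)` and `b = gamma_S/(1+alpha)`:
#' `S(R) = 1 + (a/3) q - (a/6) q^2 - (a/3) R + (a/6) R^2` and
#' `H(R) = -(b/6) q + (b/6)(1+q) R - (b/6) R^2`. Both satisfy the boundary
#' conditions exactly by construction; accuracy degrades quickly once
#' `gamma_E/(1+alpha)` is not small.
#'
#' @param params [model_params()].
#' @param grid a [radial_grid()].
#' @return A [concentration_profile()] with `S` and `H`, provenance
#'   `"madm"`.
#' @export
madm_profiles <- function(params, grid) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "radial_grid"))
  R <- grid$R
  q <- params$q
  a <- params$gamma_E / (1 + params$alpha)
  b <- params$gamma_S / (1 + params$alpha)
  S <- 1 + (a / 3) * q - (a / 6) * q^2 - (a / 3) * R + (a / 6) * R^2
  H <- -(b / 6) * q + (b / 6) * (1 + q) * R - (b / 6) * R^2
  concentration_profile(grid, S = S, H = H, params = params,
                        provenance = "madm")
}

#' HAM approximation (quadratic in R, convergence-control parameter h)
#'
#' With `a = gamma_E/(1+alpha)`, `b = gamma_S/(1+alpha)` and control
#' parameter `h` (conventionally negative, default -1):
#' `S(R) = 1 + (h a/2) q^2 - h a q + h a R - (h a/2) R^2` and
#' `H(R) = (h b/2) q - (h b/2)(q+1) R + (h b/2) R^2`. At `h = -1` the S
#' series equals `1 - a (q-1)^2/2` at the electrode, which goes negative
#' for large `a (q-1)^2` — the formula is still evaluated as printed and
#' validity is left to the caller.
#'
#' @param params [model_params()].
#' @param grid a [radial_grid()].
#' @param h HAM convergence-control parameter, nonzero.
#' @return A [concentration_profile()] with `S` and `H`, provenance `"ham"`.
#' @export
ham_profiles <- function(params, grid, h = -1) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "radial_grid"),
            h != 0)
  R <- grid$R
  q <- params$q
  a <- params$gamma_E / (1 + params$alpha)
  b <- params$gamma_S / (1 + params$alpha)
  S <- 1 + (h * a / 2) * q^2 - h * a * q + h * a * R - (h * a / 2) * R^2
  H <- (h * b / 2) * q - (h * b / 2) * (q + 1) * R + (h * b / 2) * R^2
  prof <- concentration_profile(grid, S = S, H = H, params = params,
                                provenance = "ham")
  prof$meta$h <- h
  prof
}

#' HPM approximation in its published scaled variables
#'
#' The homotopy-perturbation pair is published in scaled variables `CSP`
#' (substrate) and `CHP` (peroxide) on the coordinate `x = r/r0`:
#' `CSP = x - x^2/2 + q^2/2 - q` and `CHP = (q x - x^2 - q + x)/2`. The
#' published scaling back to `S`/`H` is typographically ambiguous, so the
#' profiles are returned in these variables rather than silently rescaled.
#'
#' @param q radius ratio (> 1).
#' @param grid a [radial_grid()] (interpreted as `r/r0` values in `[1, q]`).
#' @return Object of class `hpm_profile`: list with `r_over_r0`, `CSP`,
#'   `CHP` and `q`.
#' @export
hpm_profiles <- function(q, grid) {
  stopifnot(q > 1, inherits(grid, "radial_grid"))
  x <- grid$R
  if (any(x < 1 - 1e-12) || any(x > q + 1e-12)) {
    stop("grid must lie within [1, q]")
  }
  CSP <- x - 0.5 * x^2 + 0.5 * q^2 - q
  CHP <- 0.5 * (q * x - x^2 - q + x)
  structure(list(r_over_r0 = x, CSP = CSP, CHP = CHP, q = q),
            class = "hpm_profile")
}

#' Saturated (zero-order) limiting substrate profile
#'
#' For `alpha * S >> 1` the rate saturates at `k = gamma_E/alpha` and the
#' substrate balance becomes the constant-source Poisson problem with
#' solution `S(R) = 1 + k (R^2 - q^2)/6 + (k/3)(1/R - 1/q)`. The limit
#' breaks down (and is flagged invalid) when the formula dips to `S <= 0`,
#' where the film would be substrate-depleted and saturation cannot hold.
#'
#' @param params [model_params()] with `alpha > 0`.
#' @param grid a [radial_grid()].
#' @return A [concentration_profile()] with `S`, provenance
#'   `"exact-limit"`; `meta$valid` is `FALSE` when `min(S) <= 0`.
#' @export
saturated_limit_profile <- function(params, grid) {
  stopifnot(inherits(params, "model_params"), params$alpha > 0,
            inherits(grid, "radial_grid"))
  R <- grid$R
  q <- params$q
  k <- params$gamma_E / params$alpha
  S <- 1 + k * (R^2 - q^2) / 6 + (k / 3) * (1 / R - 1 / q)
  prof <- concentration_profile(grid, S = S, params = params,
                                provenance = "exact-limit")
  prof$meta$valid <- min(S) > 0
  prof
}
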