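#' Uniform radial grid over the enzyme film
#'
#' The film occupies dimensionless radii `R` in `[1, q]` (radial distance in
#' units of the electrode radius). Profiles are stored on this physical
#' coordinate; the first point is always the electrode surface `R = 1` and
#' the last the outer film boundary `R = q`.
#'
#' @param q radius ratio `r1/r0` (> 1).
#' @param n number of grid points (>= 3).
#' @return Object of class `radial_grid`: list with `R` (strictly increasing
#'   radii) and `n`.
#' @export
radial_grid <- function(q, n) {
  stopifnot(q > 1, n >= 3, n == as.integer(n))
  structure(list(R = seq(1, q, length.out = n), n = as.integer(n)),
            class = "radial_grid")
}

#' Radial concentration profile
#'
#' Container for substrate (`S`) and/or hydrogen-peroxide (`H`) values on a
#' radial grid, together with the parameters that produced them and a
#' provenance tag recording which method computed the values.
#'
#' @param grid a [radial_grid()].
#' @param S substrate values on `grid$R`, or `NULL`.
#' @param H peroxide values on `grid$R`, or `NULL`.
#' @param params the [model_params()] used.
#' @param provenance one of `"numerical"`, `"madm"`, `"ham"`,
#'   `"hpm-rescaled"`, `"surrogate"`, `"exact-limit"`.
#' @param meta optional list of solver metadata (iterations, residual norms).
#' @return Object of class `concentration_profile`.
#' @export
concentration_profile <- function(grid, S = NULL, H = NULL, params,
                                  provenance = c("numerical", "madm", "ham",
                                                 "hpm-rescaled", "surrogate",
                                                 "exact-limit"),
                                  meta = list()) {
  stopifnot(inherits(grid, "radial_grid"), inherits(params, "model_params"))
  provenance <- match.arg(provenance)
  if (!is.null(S) && length(S) != grid$n) stop("S length must match grid")
  if (!is.null(H) && length(H) != grid$n) stop("H length must match grid")
  structure(list(grid = grid, S = S, H = H, params = params,
                 provenance = provenance, meta = meta),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  comp <- c(if (!is.null(x$S)) "S", if (!is.null(x$H)) "H")
  cat(sprintf("concentration profile (%s), %d points on [1, %g], components: %s\n",
              x$provenance, x$grid$n, x$params$q,
              paste(comp, collapse = ", ")))
  if (!is.null(x$S)) {
    cat(sprintf("  S(1) = %.6g, S(q) = %.6g\n", x$S[1], x$S[x$grid$n]))
  }
  if (!is.null(x$H)) {
    cat(sprintf("  max H = %.6g\n", max(x$H)))
  }
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(R = x$grid$R,
             S = if (is.null(x$S)) NA_real_ else x$S,
             H = if (is.null(x$H)) NA_real_ else x$H)
}

#' Write / read a profile CSV
#'
#' Profiles are exchanged as CSV with header `R,S,H`, one row per grid
#' point; an absent component is written as an empty field. Floats are
#' written with full precision (`%.17g`).
#'
#' @param profile a [concentration_profile()].
#' @param path file path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a data frame with columns `R`, `S`, `H` (absent components are
#'   `NA`).
#' @export
write_profile_csv <- function(profile, path) {
  fmt <- function(v) {
    if (is.null(v)) return(rep("", profile$grid$n))
    sprintf("%.17g", v)
  }
  lines <- c("R,S,H",
             paste(sprintf("%.17g", profile$grid$R),
                   fmt(profile$S), fmt(profile$H), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  stopifnot(all(c("R", "S", "H") %in% names(df)))
  df
}

#' Discrete residuals of the steady-state balances
#'
#' Evaluates, by second-order central differences, the interior residuals of
#' the substrate equation `S'' + (2/R) S' - gamma_E S/(1+alpha S) = 0` and
#' the peroxide equation `H'' + (2/R) H' + gamma_S S/(1+alpha S) = 0`, plus
#' the four boundary residuals `[S'(1), S(q) - 1, H(1), H(q)]` (with `S'(1)`
#' from a second-order one-sided stencil). A converged numerical profile has
#' max-norm residual decaying as O(h^2) under grid refinement.
#'
#' @param profile a [concentration_profile()] carrying both `S` and `H`.
#' @param params [model_params()]; defaults to the profile's own.
#' @param form `"expanded"` uses `S'' + (2/R) S'` (the contract);
#'   `"conservative"` uses the flux form `(R^2 S')'/R^2`.
#' @return List with `resS`, `resH` (interior residual vectors, length
#'   `n - 2`) and `bc_res` (the 4 boundary residuals).
#' @export
residuals_profile <- function(profile, params = profile$params,
                              form = c("expanded", "conservative")) {
  form <- match.arg(form)
  stopifnot(inherits(profile, "concentration_profile"))
  if (is.null(profile$S) || is.null(profile$H)) {
    stop("profile must carry both S and H")
  }
  R <- profile$grid$R
  n <- profile$grid$n
  S <- profile$S
  H <- profile$H
  if (length(S) != n || length(H) != n) stop("component/grid length mismatch")
  h <- R[2] - R[1]
  i <- 2:(n - 1)
  rate <- mm_rate(pmax(S, 0), params$gamma_E, params$alpha)
  rateH <- mm_rate(pmax(S, 0), params$gamma_S, params$alpha)
  lap <- function(u) {
    if (form == "expanded") {
      (u[i - 1] - 2 * u[i] + u[i + 1]) / h^2 +
        (2 / R[i]) * (u[i + 1] - u[i - 1]) / (2 * h)
    } else {
      Rp <- (R[i] + R[i + 1]) / 2
      Rm <- (R[i] + R[i - 1]) / 2
      (Rp^2 * (u[i + 1] - u[i]) - Rm^2 * (u[i] - u[i - 1])) / (h^2 * R[i]^2)
    }
  }
  resS <- lap(S) - rate[i]
  resH <- lap(H) + rateH[i]
  dS1 <- (-3 * S[1] + 4 * S[2] - S[3]) / (2 * h)
  list(resS = resS, resH = resH,
       bc_res = c(dS_at_1 = dS1, S_at_q = S[n] - 1,
                  H_at_1 = H[1], H_at_q = H[n]))
}
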