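## Closed-form machinery in the interaction-enthalpy parameter h = exp(2 eps1):
## parameter conversions, the quadratic denominator Delta(h), the equiprobable
## equilibrium configuration variables, and the zero-interaction solution.

#' Convert between the interaction enthalpy and the h parameter
#'
#' The algebra of the equiprobable equilibrium is naturally couched in
#' `h = exp(2 * eps1)` rather than in the interaction enthalpy `eps1`
#' itself. `h > 1` (`eps1 > 0`) favors like-with-like clustering.
#'
#' @param eps1 Interaction enthalpy (any real).
#' @param h Interaction enthalpy parameter (strictly positive).
#' @return The converted parameter; the two functions are exact mutual
#'   inverses.
#' @examples
#' h_from_eps1(0.25)   # 1.6487...
#' eps1_from_h(5.828)  # 0.8813...
#' @export
h_from_eps1 <- function(eps1) exp(2 * eps1)

#' @rdname h_from_eps1
#' @export
eps1_from_h <- function(h) {
  if (any(h <= 0))
    stop("`h` must be strictly positive (h = exp(2 * eps1))", call. = FALSE)
  log(h) / 2
}

#' The equilibrium denominator Delta(h) = -h^2 + 6 h - 1
#'
#' Common denominator of the closed-form equilibrium configuration
#' variables. Its roots, `3 -/+ 2 sqrt(2)` (about 0.172 and 5.828), are the
#' divergence points of the analytic solution.
#'
#' @param h Interaction enthalpy parameter (any real; vectorized).
#' @return `-h^2 + 6*h - 1`.
#' @export
delta_h <- function(h) -h^2 + 6 * h - 1

#' Divergence points of the analytic equilibrium
#'
#' @return Named numeric vector `c(h_low, h_high)` with the two roots of
#'   `delta_h`, `3 - 2*sqrt(2)` and `3 + 2*sqrt(2)`, to full precision.
#' @export
divergence_points <- function() {
  c(h_low = 3 - 2 * sqrt(2), h_high = 3 + 2 * sqrt(2))
}

#' Closed-form equilibrium configuration variables at x1 = x2 = 0.5
#'
#' For zero activation enthalpy the free-energy minimum over the
#' configuration variables has a closed form in `h`:
#' \deqn{y_1 = y_3 = (3h-1)/(2\Delta),\quad y_2 = h(3-h)/(2\Delta),}
#' \deqn{w_1 = w_3 = (h+1)^2/(4\Delta),\quad w_2 = (3h-1)(3-h)/(4\Delta),}
#' \deqn{z_1 = z_6 = (3h-1)(h+1)/(8\Delta),\quad
#'       z_2 = z_5 = (3h-1)(3-h)/(8\Delta),\quad
#'       z_3 = z_4 = (3-h)(h+1)/(8\Delta),}
#' with \eqn{\Delta = -h^2 + 6h - 1}. The solution exists strictly inside
#' the interval between the two divergence points; evaluation within `1e-6`
#' of either root is refused.
#'
#' @param h Interaction enthalpy parameter, inside `(0.1716..., 5.8284...)`.
#' @return An object of class `cvm_equilibrium`: a list with `h`, `delta`,
#'   and `fractions` (a `cvm_fractions` object with `x1 = x2 = 0.5`).
#' @examples
#' eq <- analytic_equilibrium(1.65)
#' interpretation_variables(eq$fractions)
#' @export
analytic_equilibrium <- function(h) {
  stopifnot(length(h) == 1L, is.finite(h))
  dv <- divergence_points()
  if (h <= dv[["h_low"]] + 1e-6 || h >= dv[["h_high"]] - 1e-6) {
    nearest <- if (abs(h - dv[["h_low"]]) < abs(h - dv[["h_high"]]))
      sprintf("h_low = %.6f", dv[["h_low"]])
    else sprintf("h_high = %.6f", dv[["h_high"]])
    stop(sprintf(
      "h = %g is outside the valid open interval (%.4f, %.4f): the analytic solution diverges at %s",
      h, dv[["h_low"]], dv[["h_high"]], nearest), call. = FALSE)
  }
  d <- delta_h(h)
  y1 <- (3 * h - 1) / (2 * d)
  y2 <- h * (3 - h) / (2 * d)
  w1 <- (h + 1)^2 / (4 * d)
  w2 <- (3 * h - 1) * (3 - h) / (4 * d)
  z1 <- (3 * h - 1) * (h + 1) / (8 * d)
  z2 <- (3 * h - 1) * (3 - h) / (8 * d)
  z3 <- (3 - h) * (h + 1) / (8 * d)
  fr <- config_fractions(x1 = 0.5, x2 = 0.5,
                         y1 = y1, y2 = y2, y3 = y1,
                         w1 = w1, w2 = w2, w3 = w1,
                         z1 = z1, z2 = z2, z3 = z3,
                         z4 = z3, z5 = z2, z6 = z1)
  structure(list(h = h, delta = d, fractions = fr),
            class = "cvm_equilibrium")
}

#' @export
print.cvm_equilibrium <- function(x, ...) {
  cat(sprintf("<cvm_equilibrium> h = %g (eps1 = %.4f), Delta = %g\n",
              x$h, eps1_from_h(x$h), x$delta))
  print(x$fractions)
  invisible(x)
}

#' Analytic solution when the interaction enthalpy is zero
#'
#' At `eps1 = 0` the units are independent, so the single-unit fraction
#' minimizing the free energy is the logistic weight
#' `x1 = 1 / (1 + exp(eps0))`, and every pair and triplet fraction is the
#' corresponding independence product (per orientation for the degenerate
#' classes): `y1 = x1^2`, `y2 = x1 * x2`, `z1 = x1^3`, `z3 = x1^2 * x2`,
#' and so on.
#'
#' @param eps0 Activation enthalpy (finite real).
#' @return A `cvm_fractions` object.
#' @examples
#' zero_interaction_solution(0)       # the equiprobable random point
#' zero_interaction_solution(log(3))  # x1 = 0.25
#' @export
zero_interaction_solution <- function(eps0) {
  stopifnot(length(eps0) == 1L, is.finite(eps0))
  x1 <- 1 / (1 + exp(eps0))
  x2 <- 1 - x1
  config_fractions(x1 = x1, x2 = x2,
                   y1 = x1^2, y2 = x1 * x2, y3 = x2^2,
                   w1 = x1^2, w2 = x1 * x2, w3 = x2^2,
                   z1 = x1^3, z2 = x1^2 * x2, z3 = x1^2 * x2,
                   z4 = x1 * x2^2, z5 = x1 * x2^2, z6 = x2^3)
}
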