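## Reduced thermodynamics of a configuration-variable state: enthalpy,
## CVM entropy, free energy. All quantities are per unit with k_B T = 1.

#' The entropy kernel Lf(v) = v ln(v) - v
#'
#' Evaluated termwise over the configuration variables in the CVM entropy.
#' `lf(0) = 0` by the limit convention (v ln v -> 0), and values below
#' `1e-300` are treated as exact zeros.
#'
#' @param v Nonnegative numeric vector.
#' @return `v * log(v) - v`, elementwise, with the zero convention.
#' @examples
#' lf(1)    # -1
#' lf(0)    #  0
#' @export
lf <- function(v) {
  if (any(v < 0))
    stop("`lf` is defined for nonnegative arguments only", call. = FALSE)
  out <- numeric(length(v))
  pos <- v > 1e-300
  out[pos] <- v[pos] * log(v[pos]) - v[pos]
  out
}

.beta_pair <- c(1, 2, 1)
.gamma_triplet <- c(1, 2, 1, 1, 2, 1)

#' Reduced CVM enthalpy
#'
#' The per-unit enthalpy at activation enthalpy `eps0` and interaction
#' enthalpy `eps1` (k_B T = 1). The standard variant is
#' `eps0 * x1 + eps1 * (z3 + z4 - z1 - z6)`, equivalently
#' `eps0 * x1 + eps1 * (2 y2 - y1 - y3)` whenever the pair-triplet
#' equivalence relations hold. The legacy variant,
#' `eps0 * x1 + eps1 * 2 y2`, matches earlier work that scaled the
#' interaction term differently.
#'
#' @param fr A `cvm_fractions` object.
#' @param eps0 Activation enthalpy (energy per state-A unit).
#' @param eps1 Interaction enthalpy (energy per unlike nearest-neighbor
#'   pairing).
#' @param variant `"standard"` or `"legacy"`.
#' @return The reduced enthalpy (numeric scalar).
#' @export
enthalpy <- function(fr, eps0, eps1, variant = c("standard", "legacy")) {
  stopifnot(inherits(fr, "cvm_fractions"))
  variant <- match.arg(variant)
  inter <- switch(variant,
    standard = fr$z3 + fr$z4 - fr$z1 - fr$z6,
    legacy = 2 * fr$y2
  )
  eps0 * fr$x1 + eps1 * inter
}

#' Reduced CVM entropy
#'
#' The cluster-variation entropy per unit built from the pair, next-nearest
#' pair, single-unit, and triplet terms:
#' `2 * sum(beta * Lf(y)) + sum(beta * Lf(w)) - sum(Lf(x)) -
#'  2 * sum(gamma * Lf(z))`,
#' with degeneracies `beta = (1, 2, 1)` and `gamma = (1, 2, 1, 1, 2, 1)`
#' (single units carry degeneracy 1). It is zero for a homogeneous grid and
#' `ln 2` at the equiprobable random point.
#'
#' @param fr A `cvm_fractions` object.
#' @return The reduced entropy (numeric scalar).
#' @export
entropy <- function(fr) {
  stopifnot(inherits(fr, "cvm_fractions"))
  y <- c(fr$y1, fr$y2, fr$y3)
  w <- c(fr$w1, fr$w2, fr$w3)
  x <- c(fr$x1, fr$x2)
  z <- c(fr$z1, fr$z2, fr$z3, fr$z4, fr$z5, fr$z6)
  2 * sum(.beta_pair * lf(y)) + sum(.beta_pair * lf(w)) -
    sum(lf(x)) - 2 * sum(.gamma_triplet * lf(z))
}

#' Reduced CVM free energy
#'
#' `F = H - S` per unit (k_B T = 1). No Lagrange-multiplier terms appear:
#' fractions counted from an actual grid satisfy the normalization and
#' consistency constraints structurally, so those terms are identically
#' zero.
#'
#' @inheritParams enthalpy
#' @return An object of class `cvm_thermo`: a list with `eps0`, `eps1`,
#'   `h_value = exp(2 * eps1)`, `hbar`, `sbar`, and `fbar = hbar - sbar`.
#' @examples
#' g <- make_grid(4, 8, matrix(1L, 4, 8))
#' free_energy(grid_fractions(g), eps0 = 0, eps1 = 0.25)  # fbar = -0.25
#' @export
free_energy <- function(fr, eps0, eps1, variant = c("standard", "legacy")) {
  variant <- match.arg(variant)
  hb <- enthalpy(fr, eps0, eps1, variant)
  sb <- entropy(fr)
  structure(list(eps0 = eps0, eps1 = eps1, h_value = exp(2 * eps1),
                 hbar = hb, sbar = sb, fbar = hb - sb),
            class = "cvm_thermo")
}

#' @export
print.cvm_thermo <- function(x, digits = 6, ...) {
  cat(sprintf(
    "<cvm_thermo> eps0 = %g, eps1 = %g (h = %g)\n  H = %.*f  S = %.*f  F = %.*f\n",
    x$eps0, x$eps1, x$h_value, digits, x$hbar, digits, x$sbar, digits, x$fbar))
  invisible(x)
}

#' @export
as.data.frame.cvm_thermo <- function(x, ...) {
  as.data.frame(x[c("eps0", "eps1", "h_value", "hbar", "sbar", "fbar")])
}
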