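## Configuration variables: counting, normalization, equivalence checks.
##
## All counting is vectorized through toroidal shifts of the state matrix.
## .shift_t(M, dr, dc)[r, c] == M[r + dr, c + dc] (0-based, modular).

.shift_t <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + dc) %% nc) + 1L
  M[ri, ci, drop = FALSE]
}

## logical row-parity mask, TRUE on even (0-based) rows, recycled over cols
.even_rows <- function(nr, nc) {
  matrix(rep(c(TRUE, FALSE), length.out = nr), nr, nc)
}

#' Count the configuration variables of a grid
#'
#' Tallies the raw integer counts behind the CVM configuration variables:
#' single units (x), the `2N` distinct nearest-neighbor pairs (y), the `2N`
#' next-nearest-neighbor pair windows (w: `N` same-row plus `N` two-rows-away),
#' and the `2N` ordered horizontal triplet windows (z), classified as
#' A-A-A; A-A-B pooled with B-A-A; A-B-A; B-A-B; B-B-A pooled with A-B-B;
#' B-B-B. Triplets are counted along the two-row zigzag chains only
#' (the horizontal-window approximation).
#'
#' @param grid A `cvm_grid` with at least 4 rows and 3 columns.
#' @return An object of class `cvm_counts`: a list with `n_units`, `x`
#'   (named A, B), `y` and `w` (named AA, unlike, BB), and `z` (named
#'   z1..z6, z2 and z5 being the pooled two-orientation classes).
#' @examples
#' g <- make_grid(4, 8, matrix(1L, 4, 8))
#' count_configuration_variables(g)$z  # every window is A-A-A
#' @export
count_configuration_variables <- function(grid) {
  stopifnot(inherits(grid, "cvm_grid"))
  check_min_size(grid)
  M <- grid$states
  nr <- grid$n_rows; nc <- grid$n_cols
  N <- nr * nc
  ev <- .even_rows(nr, nc)

  nA <- sum(M)
  x <- c(A = nA, B = N - nA)

  ## nearest-neighbor edges: every site owns two edges into the row below:
  ## straight (r+1, c) and diagonal (r+1, c+1) on even rows / (r+1, c-1) on
  ## odd rows. 2N edges total, each counted once.
  below <- .shift_t(M, 1L, 0L)
  diag_b <- ifelse(ev, .shift_t(M, 1L, 1L), .shift_t(M, 1L, -1L))
  y_sum <- c(M + below, M + diag_b)
  y <- c(AA = sum(y_sum == 2L), unlike = sum(y_sum == 1L),
         BB = sum(y_sum == 0L))

  ## next-nearest-neighbor windows: N same-row (r, c)-(r, c+1) and N
  ## vertical (r, c)-(r+2, c) window instances.
  right <- .shift_t(M, 0L, 1L)
  down2 <- .shift_t(M, 2L, 0L)
  w_sum <- c(M + right, M + down2)
  w <- c(AA = sum(w_sum == 2L), unlike = sum(w_sum == 1L),
         BB = sum(w_sum == 0L))

  ## triplet windows: every site is the middle of exactly two windows, one
  ## whose ends are its two up-neighbors, one whose ends are its two
  ## down-neighbors. Classes depend on the middle state and the end sum.
  diag_u <- ifelse(ev, .shift_t(M, -1L, 1L), .shift_t(M, -1L, -1L))
  above <- .shift_t(M, -1L, 0L)
  ends_dn <- below + diag_b
  ends_up <- above + diag_u
  mid <- c(M, M)
  ends <- c(ends_dn, ends_up)
  z <- c(z1 = sum(mid == 1L & ends == 2L),
         z2 = sum(mid == 1L & ends == 1L),
         z3 = sum(mid == 0L & ends == 2L),
         z4 = sum(mid == 1L & ends == 0L),
         z5 = sum(mid == 0L & ends == 1L),
         z6 = sum(mid == 0L & ends == 0L))

  structure(list(n_units = N, x = x, y = y, w = w, z = z),
            class = "cvm_counts")
}

#' @export
print.cvm_counts <- function(x, ...) {
  cat(sprintf("<cvm_counts> N = %d\n", x$n_units))
  cat("  x:", paste(names(x$x), x$x, sep = "=", collapse = "  "), "\n")
  cat("  y:", paste(names(x$y), x$y, sep = "=", collapse = "  "), "\n")
  cat("  w:", paste(names(x$w), x$w, sep = "=", collapse = "  "), "\n")
  cat("  z:", paste(names(x$z), x$z, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

check_counts <- function(counts) {
  N <- counts$n_units
  if (sum(counts$x) != N || sum(counts$y) != 2L * N ||
      sum(counts$w) != 2L * N || sum(counts$z) != 2L * N ||
      any(unlist(counts[c("x", "y", "w", "z")]) < 0L))
    stop("configuration counts violate their census invariants ",
         "(sum x = N; sum y = sum w = sum z = 2N; all nonnegative)",
         call. = FALSE)
  invisible(counts)
}

#' Normalize configuration counts into fractions
#'
#' Converts raw tallies into the dimensionless configuration variables with
#' the per-orientation convention for the degenerate classes: `y2`, `w2`,
#' `z2`, and `z5` are fractions per orientation, so the normalization
#' identities `x1 + x2 = 1`, `y1 + 2 y2 + y3 = 1` (likewise for w), and
#' `z1 + 2 z2 + z3 + z4 + 2 z5 + z6 = 1` hold exactly.
#'
#' @param counts A `cvm_counts` object.
#' @return An object of class `cvm_fractions`: a named list with `x1`, `x2`,
#'   `y1..y3`, `w1..w3`, `z1..z6`, and `n_units`.
#' @export
to_fractions <- function(counts) {
  stopifnot(inherits(counts, "cvm_counts"))
  check_counts(counts)
  N <- counts$n_units
  fr <- list(
    x1 = counts$x[["A"]] / N,
    x2 = counts$x[["B"]] / N,
    y1 = counts$y[["AA"]] / (2 * N),
    y2 = counts$y[["unlike"]] / (4 * N),
    y3 = counts$y[["BB"]] / (2 * N),
    w1 = counts$w[["AA"]] / (2 * N),
    w2 = counts$w[["unlike"]] / (4 * N),
    w3 = counts$w[["BB"]] / (2 * N),
    z1 = counts$z[["z1"]] / (2 * N),
    z2 = counts$z[["z2"]] / (4 * N),
    z3 = counts$z[["z3"]] / (2 * N),
    z4 = counts$z[["z4"]] / (2 * N),
    z5 = counts$z[["z5"]] / (4 * N),
    z6 = counts$z[["z6"]] / (2 * N),
    n_units = N
  )
  structure(fr, class = "cvm_fractions")
}

#' Assemble configuration fractions directly
#'
#' Builds a `cvm_fractions` object from the fourteen configuration-variable
#' values (per-orientation convention for y2, w2, z2, z5). Used by the
#' analytic solutions; grid-derived fractions come from [to_fractions()].
#'
#' @param x1,x2 Single-unit fractions.
#' @param y1,y2,y3 Nearest-neighbor pair fractions.
#' @param w1,w2,w3 Next-nearest-neighbor pair fractions.
#' @param z1,z2,z3,z4,z5,z6 Triplet fractions.
#' @param n_units Optional unit count to carry along (`NA` when not derived
#'   from a grid).
#' @param check If `TRUE` (default), require the three normalization
#'   identities to hold to `1e-9`.
#' @return A `cvm_fractions` object.
#' @export
config_fractions <- function(x1, x2, y1, y2, y3, w1, w2, w3,
                             z1, z2, z3, z4, z5, z6,
                             n_units = NA_integer_, check = TRUE) {
  fr <- structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2, y3 = y3,
                       w1 = w1, w2 = w2, w3 = w3,
                       z1 = z1, z2 = z2, z3 = z3, z4 = z4, z5 = z5, z6 = z6,
                       n_units = n_units),
                  class = "cvm_fractions")
  if (check) {
    sums <- c(fr$x1 + fr$x2,
              fr$y1 + 2 * fr$y2 + fr$y3,
              fr$w1 + 2 * fr$w2 + fr$w3,
              fr$z1 + 2 * fr$z2 + fr$z3 + fr$z4 + 2 * fr$z5 + fr$z6)
    if (any(abs(sums - 1) > 1e-9))
      stop("configuration fractions violate a normalization identity",
           call. = FALSE)
  }
  fr
}

#' @export
print.cvm_fractions <- function(x, digits = 4, ...) {
  v <- unlist(x[c("x1", "x2", "y1", "y2", "y3", "w1", "w2", "w3",
                  paste0("z", 1:6))])
  cat("<cvm_fractions>\n")
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.cvm_fractions <- function(x, ...) {
  as.data.frame(x[c("x1", "x2", "y1", "y2", "y3", "w1", "w2", "w3",
                    paste0("z", 1:6), "n_units")])
}

#' Extract the interpretation variables (z1, z3, y2)
#'
#' The reduced descriptor set used to summarize a topography: `z1` (A-A-A
#' triplets, interior mass), `z3` (A-B-A triplets, jagged borders), and the
#' reported `y2` (unlike nearest-neighbor pairs under the per-orientation,
#' i.e. halved, convention — boundary dispersion).
#'
#' @param fr A `cvm_fractions` object.
#' @return Named numeric vector `c(z1, z3, y2)`.
#' @export
interpretation_variables <- function(fr) {
  stopifnot(inherits(fr, "cvm_fractions"))
  c(z1 = fr$z1, z3 = fr$z3, y2 = fr$y2)
}

#' Residuals of the pair-triplet equivalence relations
#'
#' The nearest-neighbor pair fractions are linearly determined by the
#' triplet fractions: `y2 = z2 + z4`, `y2 = z3 + z5`, `y1 = z1 + z2`, and
#' `y3 = z5 + z6`. For fractions counted from a grid with the
#' horizontal-window scheme these identities hold exactly; the analytic
#' equilibrium satisfies them algebraically.
#'
#' @param fr A `cvm_fractions` object.
#' @return Named numeric vector of the four residuals
#'   (`y - <triplet sum>`), zero up to floating-point error for any
#'   consistent state.
#' @export
check_equivalences <- function(fr) {
  stopifnot(inherits(fr, "cvm_fractions"))
  c(y2_z2z4 = fr$y2 - (fr$z2 + fr$z4),
    y2_z3z5 = fr$y2 - (fr$z3 + fr$z5),
    y1_z1z2 = fr$y1 - (fr$z1 + fr$z2),
    y3_z5z6 = fr$y3 - (fr$z5 + fr$z6))
}

#' Count a grid and normalize in one step
#'
#' @param grid A `cvm_grid`.
#' @return A `cvm_fractions` object.
#' @export
grid_fractions <- function(grid) to_fractions(count_configuration_variables(grid))
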