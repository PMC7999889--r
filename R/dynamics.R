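## Stochastic free-energy minimization: greedy like-for-unlike node-pair
## swaps, perturbation of converged grids, and sweeps over h.

#' Configuration for a minimization run
#'
#' @param h Interaction enthalpy parameter held fixed during the run
#'   (minimization never adjusts h: raising h always lowers the enthalpy, so
#'   a free h would be driven upward instead of reshaping the topography).
#' @param eps0 Activation enthalpy (default 0, the equiprobable regime).
#' @param max_accepted_swaps Stop after this many accepted swaps
#'   (default 100).
#' @param max_attempts Hard cap on proposals (default 10000), preventing
#'   livelock when no improving swap exists.
#' @param f_tolerance Free-energy decrease below which an accepted swap does
#'   not reset the convergence counter (default 0: any acceptance resets).
#' @param stall_attempts Declare convergence after this many consecutive
#'   proposals without an improvement larger than `f_tolerance`
#'   (default 500).
#' @param seed Optional integer seed; fixing it makes the run
#'   bit-reproducible.
#' @param enthalpy_variant `"standard"` or `"legacy"` (see [enthalpy()]).
#' @return A list of class `cvm_config`.
#' @export
minimization_config <- function(h, eps0 = 0, max_accepted_swaps = 100L,
                                max_attempts = 10000L, f_tolerance = 0,
                                stall_attempts = 500L, seed = NULL,
                                enthalpy_variant = c("standard", "legacy")) {
  enthalpy_variant <- match.arg(enthalpy_variant)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (max_accepted_swaps < 0 || max_attempts < 1 || f_tolerance < 0)
    stop("swap limits must be nonnegative and `max_attempts` >= 1",
         call. = FALSE)
  structure(list(h = h, eps0 = eps0,
                 max_accepted_swaps = as.integer(max_accepted_swaps),
                 max_attempts = as.integer(max_attempts),
                 f_tolerance = f_tolerance,
                 stall_attempts = as.integer(stall_attempts),
                 seed = seed, enthalpy_variant = enthalpy_variant),
            class = "cvm_config")
}

#' Propose a random A/B swap pair
#'
#' Selects one state-A unit and one state-B unit uniformly at random (using
#' the current RNG state). Swapping the two conserves the A-count exactly.
#'
#' @param grid A `cvm_grid` containing both states.
#' @return List with `site_a` and `site_b`, each `c(row, col)` 0-based.
#' @export
propose_swap <- function(grid) {
  stopifnot(inherits(grid, "cvm_grid"))
  a_idx <- which(grid$states == 1L)
  b_idx <- which(grid$states == 0L)
  if (length(a_idx) == 0L || length(b_idx) == 0L)
    stop("no swap possible: the grid is homogeneous", call. = FALSE)
  ia <- a_idx[sample.int(length(a_idx), 1L)]
  ib <- b_idx[sample.int(length(b_idx), 1L)]
  nr <- grid$n_rows
  list(site_a = c((ia - 1L) %% nr, (ia - 1L) %/% nr),
       site_b = c((ib - 1L) %% nr, (ib - 1L) %/% nr))
}

#' Minimize the free energy of a grid by greedy node-pair swapping
#'
#' Repeatedly proposes swapping a random state-A unit with a random state-B
#' unit and keeps the swap if and only if the recomputed free energy is
#' strictly lower (ties are rejected). The loop ends when
#' `max_accepted_swaps` swaps have been accepted, `max_attempts` proposals
#' have been made, or `stall_attempts` consecutive proposals yield no
#' improvement beyond `f_tolerance` (reported as converged). The A-count is
#' conserved exactly.
#'
#' @param grid A `cvm_grid`.
#' @param config A `cvm_config` from [minimization_config()].
#' @return A list of class `cvm_minimization` with fields `grid` (final
#'   state), `trace` (data frame of per-attempt records: attempt index,
#'   proposed sites, free energy before/after, accepted flag), `accepted`
#'   (count), `termination` (`"swap_limit"`, `"attempt_limit"`, or
#'   `"converged"`), `initial` and `final` (`cvm_thermo` states), and
#'   `fractions` (final `cvm_fractions`).
#' @export
minimize_free_energy <- function(grid, config) {
  stopifnot(inherits(grid, "cvm_grid"), inherits(config, "cvm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  eps1 <- eps1_from_h(config$h)
  thermo <- function(M) {
    g <- structure(list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                        states = M), class = "cvm_grid")
    free_energy(grid_fractions(g), config$eps0, eps1,
                config$enthalpy_variant)
  }
  M <- grid$states
  th0 <- thermo(M)
  f_cur <- th0$fbar

  a_idx <- which(M == 1L)
  b_idx <- which(M == 0L)
  if (length(a_idx) == 0L || length(b_idx) == 0L) {
    return(structure(list(grid = grid, trace = .empty_trace(), accepted = 0L,
                          termination = "converged", initial = th0,
                          final = th0, fractions = grid_fractions(grid)),
                     class = "cvm_minimization"))
  }

  cap <- config$max_attempts
  tr_ra <- integer(cap); tr_ca <- integer(cap)
  tr_rb <- integer(cap); tr_cb <- integer(cap)
  tr_fb <- numeric(cap); tr_fa <- numeric(cap); tr_ok <- logical(cap)
  nr <- grid$n_rows
  accepted <- 0L
  stall <- 0L
  attempt <- 0L
  termination <- "attempt_limit"
  while (attempt < cap) {
    if (accepted >= config$max_accepted_swaps) {
      termination <- "swap_limit"
      break
    }
    if (stall >= config$stall_attempts) {
      termination <- "converged"
      break
    }
    attempt <- attempt + 1L
    ka <- sample.int(length(a_idx), 1L)
    kb <- sample.int(length(b_idx), 1L)
    ia <- a_idx[ka]; ib <- b_idx[kb]
    M[ia] <- 0L; M[ib] <- 1L
    f_new <- thermo(M)$fbar
    ok <- f_new < f_cur
    tr_ra[attempt] <- (ia - 1L) %% nr; tr_ca[attempt] <- (ia - 1L) %/% nr
    tr_rb[attempt] <- (ib - 1L) %% nr; tr_cb[attempt] <- (ib - 1L) %/% nr
    tr_fb[attempt] <- f_cur; tr_fa[attempt] <- f_new; tr_ok[attempt] <- ok
    if (ok) {
      improvement <- f_cur - f_new
      f_cur <- f_new
      a_idx[ka] <- ib; b_idx[kb] <- ia
      accepted <- accepted + 1L
      stall <- if (improvement > config$f_tolerance) 0L else stall + 1L
    } else {
      M[ia] <- 1L; M[ib] <- 0L
      stall <- stall + 1L
    }
  }
  keep <- seq_len(attempt)
  trace <- data.frame(attempt = keep,
                      row_a = tr_ra[keep], col_a = tr_ca[keep],
                      row_b = tr_rb[keep], col_b = tr_cb[keep],
                      f_before = tr_fb[keep], f_after = tr_fa[keep],
                      accepted = tr_ok[keep])
  out_grid <- make_grid(grid$n_rows, grid$n_cols, M)
  structure(list(grid = out_grid, trace = trace, accepted = accepted,
                 termination = termination, initial = th0,
                 final = thermo(M), fractions = grid_fractions(out_grid)),
            class = "cvm_minimization")
}

.empty_trace <- function() {
  data.frame(attempt = integer(), row_a = integer(), col_a = integer(),
             row_b = integer(), col_b = integer(), f_before = numeric(),
             f_after = numeric(), accepted = logical())
}

#' @export
print.cvm_minimization <- function(x, ...) {
  cat(sprintf(
    "<cvm_minimization> %d attempts, %d accepted (%s)\n  F: %.6f -> %.6f\n",
    nrow(x$trace), x$accepted, x$termination, x$initial$fbar, x$final$fbar))
  invisible(x)
}

#' Perturb a grid by unconditional swaps
#'
#' Performs `n_forced_swaps` random A/B swaps with no free-energy test,
#' jostling a converged topography while conserving the A-count. Typically
#' followed by another [minimize_free_energy()] call.
#'
#' @param grid A `cvm_grid` with both states present (unless
#'   `n_forced_swaps = 0`).
#' @param n_forced_swaps Number of unconditional swaps (>= 0).
#' @param seed Optional integer seed.
#' @return The perturbed `cvm_grid`.
#' @export
perturb <- function(grid, n_forced_swaps, seed = NULL) {
  stopifnot(inherits(grid, "cvm_grid"), n_forced_swaps >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_forced_swaps == 0L) return(grid)
  M <- grid$states
  a_idx <- which(M == 1L)
  b_idx <- which(M == 0L)
  if (length(a_idx) == 0L || length(b_idx) == 0L)
    stop("no swap possible: the grid is homogeneous", call. = FALSE)
  for (i in seq_len(n_forced_swaps)) {
    ka <- sample.int(length(a_idx), 1L)
    kb <- sample.int(length(b_idx), 1L)
    ia <- a_idx[ka]; ib <- b_idx[kb]
    M[ia] <- 0L; M[ib] <- 1L
    a_idx[ka] <- ib; b_idx[kb] <- ia
  }
  make_grid(grid$n_rows, grid$n_cols, M)
}

#' Sweep the minimized thermodynamics over a range of h
#'
#' For each value of `h`, generates `n_trials` seeded random equiprobable
#' grids, minimizes each (optionally with perturb/re-minimize cycles), and
#' tabulates the resulting thermodynamic quantities and interpretation
#' variables.
#'
#' @param h_values Numeric vector of h values (all inside the valid range).
#' @param n_trials Trials (independent random initial grids) per h.
#' @param n_rows,n_cols Grid dimensions (default 16 x 16).
#' @param seed Integer seed for the whole sweep.
#' @param config_fn Function `h -> cvm_config` building the per-run
#'   configuration; by default a run to convergence (large swap budget) at
#'   `eps0 = 0`.
#' @param perturb_cycles Number of perturb/re-minimize cycles after the
#'   first minimization (default 0).
#' @param perturb_swaps Forced swaps per perturbation cycle (default 5).
#' @param summarize If `TRUE`, return per-h means instead of per-trial rows.
#' @return A data frame with columns `h`, `trial`, `hbar`, `sbar`, `fbar`,
#'   `z1`, `z3`, `y2`, `accepted`, `termination` (per-trial), or their means
#'   by `h` when `summarize = TRUE`.
#' @export
sweep_h <- function(h_values, n_trials, n_rows = 16, n_cols = 16,
                    seed = NULL, config_fn = NULL, perturb_cycles = 0L,
                    perturb_swaps = 5L, summarize = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config_fn))
    config_fn <- function(h) minimization_config(
      h = h, max_accepted_swaps = 10000L, max_attempts = 10000L)
  rows <- vector("list", length(h_values) * n_trials)
  k <- 0L
  for (h in h_values) {
    cfg <- config_fn(h)
    cfg$seed <- NULL  # sequential RNG stream from the sweep seed
    for (trial in seq_len(n_trials)) {
      g <- generate_random(n_rows, n_cols, 0.5)
      res <- minimize_free_energy(g, cfg)
      for (cyc in seq_len(perturb_cycles)) {
        g2 <- perturb(res$grid, perturb_swaps)
        res <- minimize_free_energy(g2, cfg)
      }
      iv <- interpretation_variables(res$fractions)
      k <- k + 1L
      rows[[k]] <- data.frame(h = h, trial = trial,
                              hbar = res$final$hbar, sbar = res$final$sbar,
                              fbar = res$final$fbar,
                              z1 = iv[["z1"]], z3 = iv[["z3"]],
                              y2 = iv[["y2"]],
                              accepted = res$accepted,
                              termination = res$termination)
    }
  }
  out <- do.call(rbind, rows)
  if (summarize) {
    agg <- stats::aggregate(out[c("hbar", "sbar", "fbar", "z1", "z3", "y2")],
                     by = list(h = out$h), FUN = mean)
    return(agg[order(agg$h), ])
  }
  out
}
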