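## Initial topography generators: random equiprobable, "extreme rich
## club-like" (one wrapped band), and "scale-free-like" (a hierarchy of
## compact islands, far more small ones than large ones).

#' Generate a random grid with an exact A-count
#'
#' Places exactly `round(x1_target * N)` state-A units uniformly at random
#' without replacement.
#'
#' @param n_rows,n_cols Grid dimensions (`n_rows` even).
#' @param x1_target Fraction of units in state A (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return A `cvm_grid`.
#' @export
generate_random <- function(n_rows, n_cols, x1_target = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_rows) * as.integer(n_cols)
  k <- round(x1_target * N)
  if (x1_target < 0 || x1_target > 1 || k < 0 || k > N)
    stop("`x1_target` must give an achievable A-count", call. = FALSE)
  st <- matrix(0L, n_rows, n_cols)
  st[sample.int(N, k)] <- 1L
  make_grid(n_rows, n_cols, st)
}

#' Generate the "extreme rich club-like" pattern
#'
#' A single solid vertical band of state-A units, half the grid wide,
#' spanning every row; with the toroidal wrap this is one compact landmass
#' connected around the grid envelope in both directions, the configuration
#' that maximizes like-near-like pairings at equal A/B counts. The
#' construction is deterministic.
#'
#' @param n_rows,n_cols Grid dimensions (`n_rows` even, `n_cols` even so the
#'   band is exactly half the grid).
#' @return A `cvm_grid` with `n_units / 2` A-units in one connected band.
#' @export
generate_rich_club <- function(n_rows = 16, n_cols = 16) {
  if (n_cols %% 2L != 0L)
    stop("`n_cols` must be even so the A-band occupies exactly half the grid",
         call. = FALSE)
  st <- matrix(0L, n_rows, n_cols)
  st[, seq_len(n_cols %/% 2L)] <- 1L
  make_grid(n_rows, n_cols, st)
}

## footprint of a compact island: size -> (height, width) block
.island_shape <- function(size) {
  switch(as.character(size),
    "16" = c(4L, 4L),
    "8" = c(4L, 2L),
    "4" = c(4L, 1L),
    "2" = c(1L, 2L),
    "1" = c(1L, 1L),
    {
      h <- max(1L, as.integer(floor(sqrt(size))))
      while (size %% h != 0L) h <- h - 1L
      c(h, size %/% h)
    })
}

## all cells adjacent (nearest-neighbor or same-row) to TRUE cells of `occ`
.dilate <- function(occ) {
  sh <- function(dr, dc) .shift_t(occ, dr, dc)
  ev <- .even_rows(nrow(occ), ncol(occ))
  up_d <- ifelse(ev, sh(-1L, 1L), sh(-1L, -1L))
  dn_d <- ifelse(ev, sh(1L, 1L), sh(1L, -1L))
  occ | sh(0L, 1L) | sh(0L, -1L) | sh(1L, 0L) | sh(-1L, 0L) | up_d | dn_d
}

#' Generate a "scale-free-like" island pattern
#'
#' Places non-overlapping compact A-islands with "far more small things than
#' large ones": by default three 16-unit, five 8-unit, and ten 4-unit
#' islands (128 A-units on a 16 x 16 grid). Larger islands are placed
#' first, each at a seeded random anchor found by a shuffled scan over every
#' anchor position; a one-unit moat of B-cells around the island is required
#' whenever some anchor admits one, and relaxed to plain non-overlap
#' otherwise.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param island_sizes Integer vector of island areas, decreasing.
#' @param island_counts Number of islands of each size (same length as
#'   `island_sizes`, nondecreasing as size decreases).
#' @param x1_target Fraction of A-units; the island areas must sum to
#'   `round(x1_target * N)`.
#' @param seed Optional integer seed.
#' @param restarts Number of independent packing attempts; the attempt
#'   whose A-set has the most nearest-neighbor-connected components (i.e.
#'   the fewest island contacts) is kept.
#' @return A `cvm_grid`.
#' @export
generate_scale_free <- function(n_rows = 16, n_cols = 16,
                                island_sizes = c(16L, 8L, 4L),
                                island_counts = c(3L, 5L, 10L),
                                x1_target = 0.5, seed = NULL,
                                restarts = 25L) {
  if (!is.null(seed)) set.seed(seed)
  if (length(island_sizes) != length(island_counts))
    stop("`island_sizes` and `island_counts` must have equal length",
         call. = FALSE)
  N <- as.integer(n_rows) * as.integer(n_cols)
  target_a <- round(x1_target * N)
  if (sum(island_sizes * island_counts) != target_a)
    stop(sprintf("island areas sum to %d but the A-count target is %d",
                 sum(island_sizes * island_counts), target_a), call. = FALSE)
  sizes <- rep(island_sizes, island_counts)
  sizes <- sort(sizes, decreasing = TRUE)  # largest first
  best <- NULL
  best_comp <- -1L
  for (restart in seq_len(restarts)) {
    occ <- .pack_islands(n_rows, n_cols, sizes)
    if (is.null(occ)) next
    ncomp <- .n_components(occ)
    if (ncomp > best_comp) {
      best <- occ
      best_comp <- ncomp
    }
    if (best_comp >= length(sizes)) break  # every island kept its moat
  }
  if (is.null(best))
    stop("could not pack the requested islands; use a larger grid or ",
         "fewer/smaller islands", call. = FALSE)
  make_grid(n_rows, n_cols, matrix(as.integer(best), n_rows, n_cols))
}

## one greedy packing attempt; NULL if an island cannot be placed at all
.pack_islands <- function(n_rows, n_cols, sizes) {
  occ <- matrix(FALSE, n_rows, n_cols)
  for (s in sizes) {
    sh <- .island_shape(s)
    placed <- FALSE
    forb <- .dilate(occ)  # moat: keep one B-cell between islands
    anchors <- sample.int(n_rows * n_cols) - 1L  # shuffled exhaustive scan
    for (pass in 1:2) {
      blocked <- if (pass == 1L) forb else occ
      for (a in anchors) {
        r0 <- a %% n_rows
        c0 <- a %/% n_rows
        ri <- ((r0 + seq_len(sh[1L]) - 1L) %% n_rows) + 1L
        ci <- ((c0 + seq_len(sh[2L]) - 1L) %% n_cols) + 1L
        if (!any(blocked[ri, ci])) {
          occ[ri, ci] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) return(NULL)
  }
  occ
}

## number of connected components of the TRUE set under nearest-neighbor
## adjacency (rows above/below, column offsets by row parity)
.n_components <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(occ & lab == 0L)) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      r <- (i - 1L) %% nr
      c <- (i - 1L) %/% nr
      off <- if (r %% 2L == 0L) c(0L, 1L) else c(-1L, 0L)
      for (dr in c(-1L, 1L)) for (dc in off) {
        li <- (((c + dc) %% nc) * nr) + ((r + dr) %% nr) + 1L
        if (occ[li] && lab[li] == 0L) {
          lab[li] <- comp
          queue <- c(queue, li)
        }
      }
    }
  }
  comp
}
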