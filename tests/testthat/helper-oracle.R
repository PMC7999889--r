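# Brute-force oracle: classifies every pair and triplet window by direct
# per-site modular arithmetic, independently of the package's vectorized
# counting and of its chain enumeration.

oracle_counts <- function(states) {
  nr <- nrow(states)
  nc <- ncol(states)
  N <- nr * nc
  s <- function(r, c) states[(r %% nr) + 1L, (c %% nc) + 1L]
  y <- c(AA = 0L, unlike = 0L, BB = 0L)
  w <- c(AA = 0L, unlike = 0L, BB = 0L)
  z <- stats::setNames(integer(6), paste0("z", 1:6))
  pair_class <- function(total) c("BB", "unlike", "AA")[total + 1L]
  for (r in 0:(nr - 1L)) {
    offs <- if (r %% 2L == 0L) c(0L, 1L) else c(-1L, 0L)
    for (c in 0:(nc - 1L)) {
      m <- s(r, c)
      # the two nearest-neighbor edges this site owns (into the row below)
      for (dc in offs) {
        cls <- pair_class(m + s(r + 1L, c + dc))
        y[cls] <- y[cls] + 1L
      }
      # next-nearest windows owned by this site: same-row right, two down
      cls <- pair_class(m + s(r, c + 1L)); w[cls] <- w[cls] + 1L
      cls <- pair_class(m + s(r + 2L, c)); w[cls] <- w[cls] + 1L
      # the two triplet windows centered here: ends are the up pair and
      # the down pair (same column offsets either way)
      for (dr in c(-1L, 1L)) {
        ends <- s(r + dr, c + offs[1L]) + s(r + dr, c + offs[2L])
        k <- if (m == 1L) {
          c(4L, 2L, 1L)[ends + 1L]   # BAB / AAB|BAA / AAA
        } else {
          c(6L, 5L, 3L)[ends + 1L]   # BBB / BBA|ABB / ABA
        }
        z[k] <- z[k] + 1L
      }
    }
  }
  nA <- sum(states)
  list(n_units = N, x = c(A = nA, B = N - nA), y = y, w = w, z = z)
}

random_states <- function(n_rows, n_cols, p = 0.5) {
  matrix(as.integer(stats::runif(n_rows * n_cols) < p), n_rows, n_cols)
}

# even (0-based) rows all A, odd rows all B
striped_states <- function(n_rows, n_cols) {
  matrix(rep(c(1L, 0L), length.out = n_rows), n_rows, n_cols)
}

expect_counts_equal <- function(fast, slow) {
  expect_identical(fast$n_units, slow$n_units)
  expect_identical(unname(fast$x), unname(as.integer(slow$x)))
  expect_identical(unname(fast$y), unname(as.integer(slow$y)))
  expect_identical(unname(fast$w), unname(as.integer(slow$w)))
  expect_identical(unname(fast$z), unname(as.integer(slow$z)))
}

# connected components of the state-A set under the lattice's
# nearest-neighbor adjacency, by flood fill
a_components <- function(grid) {
  M <- grid$states
  nr <- grid$n_rows
  nc <- grid$n_cols
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  sizes <- integer()
  g <- make_grid(nr, nc, M)
  for (start in which(M == 1L & lab == 0L)) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    size <- 0L
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      size <- size + 1L
      r <- (i - 1L) %% nr
      c <- (i - 1L) %/% nr
      nbrs <- nn_sites(g, c(r, c))
      for (j in seq_len(nrow(nbrs))) {
        li <- nbrs[j, 2L] * nr + nbrs[j, 1L] + 1L
        if (M[li] == 1L && lab[li] == 0L) {
          lab[li] <- comp
          queue <- c(queue, li)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(n = comp, sizes = sizes)
}
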