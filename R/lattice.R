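#' cvm2d: the two-dimensional cluster variation method
#'
#' The package represents binary ("on"/"off") unit grids on a zigzag-offset
#' toroidal lattice, counts the CVM configuration variables (single units,
#' nearest-neighbor pairs, next-nearest-neighbor pairs, horizontal triplets),
#' evaluates the CVM free energy and its closed-form equilibrium in the
#' interaction-enthalpy parameter h, and minimizes the free energy of a grid
#' by stochastic node-pair swapping.
#'
#' @section Lattice geometry:
#' Rows are offset by half a unit: even-indexed rows (0-based) are displaced
#' half a cell to the right. A unit's four nearest neighbors sit in the rows
#' above and below; its four next-nearest neighbors sit in the same row
#' (left/right) and two rows above/below. Triplets are read along the two-row
#' zigzag chains. Both directions wrap around (toroidal boundary), which is
#' why the number of rows must be even.
#'
#' @keywords internal
#' @importFrom utils write.csv
"_PACKAGE"

#' Construct a validated CVM grid
#'
#' A grid is a rectangular arrangement of bistate units (1 = state A, "on";
#' 0 = state B, "off") on a toroidal lattice whose rows are offset by half a
#' unit (zigzag geometry). The number of rows must be even so the vertical
#' wrap-around joins rows of opposite offset parity.
#'
#' @param n_rows Positive even integer, number of rows.
#' @param n_cols Positive integer, number of columns.
#' @param states Integer/numeric matrix of 0/1 with dimensions
#'   `n_rows x n_cols`. Row 1 of the matrix is the top row (row index 0 in
#'   the package's 0-based site coordinates).
#' @return An object of class `cvm_grid` with fields `n_rows`, `n_cols`, and
#'   `states` (integer matrix).
#' @examples
#' g <- make_grid(4, 4, matrix(0L, 4, 4))
#' n_units(g)
#' @export
make_grid <- function(n_rows, n_cols, states) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || is.na(n_rows) || n_rows < 1L)
    stop("`n_rows` must be a positive integer", call. = FALSE)
  if (length(n_cols) != 1L || is.na(n_cols) || n_cols < 1L)
    stop("`n_cols` must be a positive integer", call. = FALSE)
  if (n_rows %% 2L != 0L)
    stop("`n_rows` must be even: the vertical wrap-around of the zigzag ",
         "lattice requires alternating row offsets", call. = FALSE)
  if (!is.matrix(states))
    stop("`states` must be a matrix", call. = FALSE)
  if (nrow(states) != n_rows || ncol(states) != n_cols)
    stop(sprintf("`states` has shape %d x %d, expected %d x %d",
                 nrow(states), ncol(states), n_rows, n_cols), call. = FALSE)
  st <- states
  storage.mode(st) <- "integer"
  if (anyNA(st) || !all(st == 0L | st == 1L))
    stop("`states` entries must all be 0 or 1", call. = FALSE)
  dimnames(st) <- NULL
  structure(list(n_rows = n_rows, n_cols = n_cols, states = st),
            class = "cvm_grid")
}

#' @export
print.cvm_grid <- function(x, ...) {
  cat(sprintf("<cvm_grid> %d x %d toroidal zigzag grid, %d/%d units in state A\n",
              x$n_rows, x$n_cols, a_count(x), n_units(x)))
  if (x$n_rows <= 32L && x$n_cols <= 64L)
    cat(render_grid(x), sep = "\n")
  invisible(x)
}

#' @export
as.matrix.cvm_grid <- function(x, ...) x$states

#' Total number of units in a grid
#' @param grid A `cvm_grid`.
#' @return Integer `n_rows * n_cols`.
#' @export
n_units <- function(grid) grid$n_rows * grid$n_cols

#' Number of units in state A ("on")
#' @param grid A `cvm_grid`.
#' @return Integer count of 1-entries.
#' @export
a_count <- function(grid) sum(grid$states)

## ---- site coordinates -----------------------------------------------------
## Sites are length-2 integer vectors c(row, col), 0-based, row 0 at top.
## All arithmetic is modular (toroidal wrap in both directions).

check_site <- function(grid, site) {
  site <- as.integer(site)
  if (length(site) != 2L || anyNA(site))
    stop("a site is an integer vector c(row, col)", call. = FALSE)
  if (site[1L] < 0L || site[1L] >= grid$n_rows ||
      site[2L] < 0L || site[2L] >= grid$n_cols)
    stop(sprintf("site (%d, %d) outside a %d x %d grid",
                 site[1L], site[2L], grid$n_rows, grid$n_cols), call. = FALSE)
  site
}

site_mat <- function(r, c) {
  m <- cbind(row = as.integer(r), col = as.integer(c))
  dimnames(m) <- list(NULL, c("row", "col"))
  m
}

#' Nearest neighbors of a site
#'
#' Under the half-unit row offset (even rows displaced right), the four
#' nearest neighbors of a unit all lie in the rows immediately above and
#' below it: at columns `c` and `c + 1` when the unit's row is even, and at
#' `c - 1` and `c` when it is odd (0-based indices, toroidal wrap).
#'
#' @param grid A `cvm_grid`.
#' @param site Integer vector `c(row, col)`, 0-based.
#' @param unique If `TRUE`, collapse coordinate collisions caused by
#'   wrap-around on small grids; by default the full multiset of 4 is
#'   returned.
#' @return Integer matrix with columns `row`, `col`, one neighbor per row.
#' @export
nn_sites <- function(grid, site, unique = FALSE) {
  s <- check_site(grid, site)
  r <- s[1L]; c <- s[2L]
  off <- if (r %% 2L == 0L) c(0L, 1L) else c(-1L, 0L)
  rr <- rep(c(r - 1L, r + 1L), each = 2L) %% grid$n_rows
  cc <- rep(c + off, times = 2L) %% grid$n_cols
  m <- site_mat(rr, cc)
  if (unique) m <- m[!duplicated(m), , drop = FALSE]
  m
}

#' Next-nearest neighbors of a site
#'
#' The four next-nearest neighbors lie in the same row (immediately left and
#' right) and directly above and below two rows away (toroidal wrap). On a
#' 4-row grid the two vertical partners coincide; they are kept as a
#' multiset unless `unique = TRUE`.
#'
#' @inheritParams nn_sites
#' @return Integer matrix with columns `row`, `col`.
#' @export
nnn_sites <- function(grid, site, unique = FALSE) {
  s <- check_site(grid, site)
  r <- s[1L]; c <- s[2L]
  m <- site_mat(c(r, r, (r - 2L) %% grid$n_rows, (r + 2L) %% grid$n_rows),
                c((c - 1L) %% grid$n_cols, (c + 1L) %% grid$n_cols, c, c))
  if (unique) m <- m[!duplicated(m), , drop = FALSE]
  m
}

#' Enumerate the horizontal triplet windows of a grid
#'
#' The grid is a stack of two-row zigzag chains: chain `r` (one per row,
#' toroidal) alternates between rows `r` and `r + 1`. Every length-3
#' contiguous window along each cyclic chain, read left to right, is one
#' horizontal triplet; there are exactly `2 N` of them, and every
#' nearest-neighbor pair is the leading pair of exactly one window and the
#' trailing pair of exactly one window.
#'
#' @param grid A `cvm_grid`.
#' @return Integer matrix with `2 * n_units(grid)` rows and columns
#'   `r1, c1, r2, c2, r3, c3` (0-based site coordinates of the ordered
#'   window).
#' @export
horizontal_triplets <- function(grid) {
  check_min_size(grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  out <- matrix(NA_integer_, nrow = 2L * nr * nc, ncol = 6L,
                dimnames = list(NULL, c("r1", "c1", "r2", "c2", "r3", "c3")))
  k <- 1L
  for (r in 0:(nr - 1L)) {
    rb <- (r + 1L) %% nr
    ## cyclic chain sequence of length 2 * nc alternating rows r, r + 1
    if (r %% 2L == 0L) {
      ## even top row (shifted right): ... (r,c) (r+1,c+1) (r,c+1) ...
      rows <- rep(c(r, rb), times = nc)
      cols <- as.integer(rbind(0:(nc - 1L), (1:nc) %% nc))
    } else {
      ## odd top row: ... (r,c) (r+1,c) (r,c+1) ...
      rows <- rep(c(r, rb), times = nc)
      cols <- as.integer(rbind(0:(nc - 1L), 0:(nc - 1L)))
    }
    L <- 2L * nc
    i1 <- seq_len(L)
    i2 <- c(2:L, 1L)
    i3 <- c(3:L, 1L, 2L)
    out[k:(k + L - 1L), ] <- cbind(rows[i1], cols[i1],
                                   rows[i2], cols[i2],
                                   rows[i3], cols[i3])
    k <- k + L
  }
  out
}

check_min_size <- function(grid) {
  if (grid$n_rows < 4L || grid$n_cols < 3L)
    stop("counting operations need at least 4 rows and 3 columns so that ",
         "the sites of every pair and triplet window are distinct",
         call. = FALSE)
  invisible(grid)
}

## ---- grid text format -----------------------------------------------------

#' Read a grid from the plain-text 0/1 format
#'
#' The format is line-oriented: optional `#`-prefixed comment lines, then a
#' header line `"<n_rows> <n_cols>"`, then `n_rows` lines of exactly
#' `n_cols` characters from `{0,1}`.
#'
#' @param path Path to a grid text file.
#' @return A `cvm_grid`.
#' @seealso [write_grid()]
#' @export
read_grid <- function(path) {
  if (!file.exists(path))
    stop(sprintf("grid file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) i <- i + 1L
  if (i > length(lines))
    stop(sprintf("%s: no header line found", path), call. = FALSE)
  header <- lines[i]
  if (!grepl("^[0-9]+ [0-9]+$", header))
    stop(sprintf("%s:%d: malformed header %s (expected \"<n_rows> <n_cols>\")",
                 path, i, dQuote(header)), call. = FALSE)
  dims <- as.integer(strsplit(header, " ", fixed = TRUE)[[1L]])
  nr <- dims[1L]; nc <- dims[2L]
  if (length(lines) < i + nr)
    stop(sprintf("%s: expected %d grid rows after line %d, found %d",
                 path, nr, i, length(lines) - i), call. = FALSE)
  st <- matrix(0L, nr, nc)
  for (j in seq_len(nr)) {
    ln <- lines[i + j]
    lno <- i + j
    if (nchar(ln) != nc)
      stop(sprintf("%s:%d: row has %d characters, expected %d",
                   path, lno, nchar(ln), nc), call. = FALSE)
    ch <- strsplit(ln, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("0", "1")))
      stop(sprintf("%s:%d: row contains characters other than 0/1",
                   path, lno), call. = FALSE)
    st[j, ] <- as.integer(ch)
  }
  make_grid(nr, nc, st)
}

#' Write a grid in the plain-text 0/1 format
#'
#' @param grid A `cvm_grid`.
#' @param path Output file path.
#' @return `path`, invisibly. `read_grid(write_grid(g, p))` reproduces `g`
#'   bit for bit.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cvm_grid"))
  rows <- apply(grid$states, 1L, paste, collapse = "")
  writeLines(c(sprintf("%d %d", grid$n_rows, grid$n_cols), rows), path)
  invisible(path)
}

## ---- rendering ------------------------------------------------------------

#' Render a grid as text or a raster image
#'
#' Text rendering prints one glyph per unit (default `#` for state A, `.`
#' for state B) with two character columns per cell; even rows (0-based) are
#' shifted one character right to visualize the half-unit zigzag offset.
#' Image rendering produces a grayscale raster (A = black, B = white), one
#' `cell x cell` pixel block per unit with the same half-cell shift, written
#' as PNG when `file` is given.
#'
#' @param grid A `cvm_grid`.
#' @param style `"text"` or `"image"`.
#' @param glyphs Length-2 character vector, glyphs for states A and B.
#' @param file Output path for `style = "image"` (PNG). If `NULL` the raster
#'   matrix is returned instead.
#' @param cell Pixel size of one unit cell for `style = "image"`; must be
#'   even.
#' @return For `"text"`, a character vector of `n_rows` lines. For
#'   `"image"`, the grayscale raster matrix (invisibly, after writing
#'   `file` if requested).
#' @export
render_grid <- function(grid, style = c("text", "image"),
                        glyphs = c("#", "."), file = NULL, cell = 8L) {
  stopifnot(inherits(grid, "cvm_grid"))
  style <- match.arg(style)
  if (style == "text") {
    gl <- c(glyphs[2L], glyphs[1L])  # index by state + 1
    lines <- character(grid$n_rows)
    for (i in seq_len(grid$n_rows)) {
      body <- paste(gl[grid$states[i, ] + 1L], collapse = " ")
      r0 <- i - 1L  # 0-based row index
      lines[i] <- if (r0 %% 2L == 0L) paste0(" ", body) else body
    }
    return(lines)
  }
  cell <- as.integer(cell)
  if (cell < 2L || cell %% 2L != 0L)
    stop("`cell` must be an even integer >= 2", call. = FALSE)
  half <- cell %/% 2L
  w <- grid$n_cols * cell + half
  img <- matrix(1, nrow = grid$n_rows * cell, ncol = w)
  for (i in seq_len(grid$n_rows)) {
    r0 <- i - 1L
    x0 <- if (r0 %% 2L == 0L) half else 0L
    py <- ((i - 1L) * cell + 1L):(i * cell)
    for (j in seq_len(grid$n_cols)) {
      if (grid$states[i, j] == 1L) {
        px <- (x0 + (j - 1L) * cell + 1L):(x0 + j * cell)
        img[py, px] <- 0
      }
    }
  }
  if (!is.null(file)) png::writePNG(img, target = file)
  invisible(img)
}
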