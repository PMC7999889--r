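test_that("make_grid validates shape, parity, and binary states", {
  g <- make_grid(16, 16, matrix(0L, 16, 16))
  expect_s3_class(g, "cvm_grid")
  expect_equal(n_units(g), 256)
  expect_equal(a_count(g), 0)

  st <- matrix(0L, 16, 16)
  st[seq_len(128)] <- 1L
  expect_equal(a_count(make_grid(16, 16, st)), 128)

  expect_error(make_grid(15, 16, matrix(0L, 15, 16)), "even")
  expect_error(make_grid(4, 4, matrix(2L, 4, 4)), "0 or 1")
  expect_error(make_grid(4, 4, matrix(0L, 4, 5)), "shape")
})

test_that("nearest neighbors follow the even-rows-shifted-right convention", {
  g <- make_grid(4, 4, matrix(0L, 4, 4))
  even <- nn_sites(g, c(0, 0))
  expect_setequal(apply(even, 1, paste, collapse = ","),
                  c("3,0", "3,1", "1,0", "1,1"))
  odd <- nn_sites(g, c(1, 0))
  expect_setequal(apply(odd, 1, paste, collapse = ","),
                  c("0,3", "0,0", "2,3", "2,0"))
  expect_equal(nrow(unique(nn_sites(g, c(2, 3)))), 4)
})

test_that("next-nearest neighbors are same-row and two-rows-away", {
  g16 <- make_grid(16, 16, matrix(0L, 16, 16))
  m <- nnn_sites(g16, c(5, 5))
  expect_setequal(apply(m, 1, paste, collapse = ","),
                  c("5,4", "5,6", "3,5", "7,5"))
  expect_true(all(m[1:2, "row"] == 5))

  # 4-row wrap collision: (r-2) and (r+2) coincide, dedup on request
  g4 <- make_grid(4, 4, matrix(0L, 4, 4))
  m4 <- nnn_sites(g4, c(0, 0))
  expect_equal(nrow(m4), 4)
  expect_equal(nrow(nnn_sites(g4, c(0, 0), unique = TRUE)), 3)
  expect_setequal(apply(nnn_sites(g4, c(0, 0), unique = TRUE), 1,
                        paste, collapse = ","),
                  c("0,3", "0,1", "2,0"))
})

test_that("neighbor relations are symmetric", {
  g <- make_grid(6, 5, matrix(0L, 6, 5))
  for (site in list(c(0, 0), c(1, 3), c(3, 4), c(5, 2))) {
    for (fn in list(nn_sites, nnn_sites)) {
      nbrs <- fn(g, site)
      for (i in seq_len(nrow(nbrs))) {
        back <- fn(g, nbrs[i, ])
        expect_true(any(back[, 1] == site[1] & back[, 2] == site[2]))
      }
    }
  }
})

test_that("triplet windows: 2N census, zigzag structure, edge coverage", {
  for (dims in list(c(4, 4), c(16, 16), c(6, 5))) {
    g <- make_grid(dims[1], dims[2], matrix(0L, dims[1], dims[2]))
    tr <- horizontal_triplets(g)
    expect_equal(nrow(tr), 2 * n_units(g))
    # the three sites alternate between two adjacent rows (toroidally)
    expect_true(all(tr[, "r1"] == tr[, "r3"]))
    expect_true(all((tr[, "r2"] - tr[, "r1"]) %% dims[1] %in%
                      c(1, dims[1] - 1)))
    # consecutive window sites are nearest neighbors
    for (i in sample(nrow(tr), 10)) {
      n2 <- nn_sites(g, tr[i, c("r2", "c2")])
      expect_true(any(n2[, 1] == tr[i, "r1"] & n2[, 2] == tr[i, "c1"]))
      expect_true(any(n2[, 1] == tr[i, "r3"] & n2[, 2] == tr[i, "c3"]))
    }
    # every nearest-neighbor pair leads exactly one window and trails one
    lead <- paste(pmin(tr[, "r1"] * 100 + tr[, "c1"],
                       tr[, "r2"] * 100 + tr[, "c2"]),
                  pmax(tr[, "r1"] * 100 + tr[, "c1"],
                       tr[, "r2"] * 100 + tr[, "c2"]))
    trail <- paste(pmin(tr[, "r2"] * 100 + tr[, "c2"],
                        tr[, "r3"] * 100 + tr[, "c3"]),
                   pmax(tr[, "r2"] * 100 + tr[, "c2"],
                        tr[, "r3"] * 100 + tr[, "c3"]))
    expect_true(all(table(lead) == 1))
    expect_true(all(table(trail) == 1))
    expect_setequal(unique(lead), unique(trail))
    expect_equal(length(unique(lead)), 2 * n_units(g))
  }
})

test_that("the derived nearest-neighbor edge multiset has 2N members", {
  g <- make_grid(6, 4, matrix(0L, 6, 4))
  edges <- character()
  for (r in 0:5) for (c in 0:3) {
    nbrs <- nn_sites(g, c(r, c))
    key_a <- r * 100 + c
    key_b <- nbrs[, 1] * 100 + nbrs[, 2]
    edges <- c(edges, paste(pmin(key_a, key_b), pmax(key_a, key_b)))
  }
  tab <- table(edges)
  expect_equal(length(tab), 2 * n_units(g))
  expect_true(all(tab == 2))  # each edge seen once from each endpoint
})

test_that("counts are invariant under parity-preserving toroidal shifts", {
  set.seed(11)
  st <- random_states(6, 5)
  g <- make_grid(6, 5, st)
  base <- count_configuration_variables(g)
  shift2 <- make_grid(6, 5, st[c(3:6, 1:2), ])           # rows by 2
  shiftc <- make_grid(6, 5, st[, c(4:5, 1:3)])           # cols by 3
  for (g2 in list(shift2, shiftc)) {
    cc <- count_configuration_variables(g2)
    expect_identical(cc$y, base$y)
    expect_identical(cc$w, base$w)
    expect_identical(cc$z, base$z)
  }
})

test_that("grid files round-trip bit-for-bit and reject malformed input", {
  set.seed(5)
  g <- make_grid(16, 16, random_states(16, 16))
  path <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g2$states, g$states)

  p2 <- withr::local_tempfile(fileext = ".grid")
  writeLines(c("# comment", "4 4", "0101", "1010", "0101", "1010"), p2)
  g3 <- read_grid(p2)
  expect_equal(dim(g3$states), c(4, 4))
  expect_equal(a_count(g3), 8)

  writeLines(c("4 4", "0101", "101", "0101", "1010"), p2)
  expect_error(read_grid(p2), ":3")
  writeLines(c("4 4", "0101", "1012", "0101", "1010"), p2)
  expect_error(read_grid(p2), "0/1")
  writeLines(c("4x4", "0101"), p2)
  expect_error(read_grid(p2), "header")
})

test_that("rendering is deterministic and shows the row offset", {
  g <- make_grid(4, 4, matrix(1L, 4, 4))
  txt <- render_grid(g)
  expect_length(txt, 4)
  expect_false(any(grepl("\\.", txt)))          # all-A: no B glyph
  expect_match(txt[1], "^ ")                    # even row shifted
  expect_match(txt[2], "^[^ ]")
  expect_identical(render_grid(g), txt)

  img <- render_grid(g, "image", cell = 4)
  expect_equal(dim(img), c(16, 4 * 4 + 2))
  set.seed(3)
  g2 <- make_grid(4, 4, random_states(4, 4))
  expect_identical(render_grid(g2, "image"), render_grid(g2, "image"))
})
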