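test_that("swap proposals pick one unit of each state, reproducibly", {
  set.seed(2)
  st <- random_states(4, 4)
  st[1, 1] <- 1L
  g <- make_grid(4, 4, st)
  set.seed(10)
  p1 <- propose_swap(g)
  expect_equal(g$states[p1$site_a[1] + 1, p1$site_a[2] + 1], 1L)
  expect_equal(g$states[p1$site_b[1] + 1, p1$site_b[2] + 1], 0L)
  set.seed(10)
  expect_identical(propose_swap(g), p1)

  # single-A grid: the A site is forced
  st1 <- matrix(0L, 4, 4)
  st1[2, 3] <- 1L
  g1 <- make_grid(4, 4, st1)
  for (i in 1:5) expect_equal(propose_swap(g1)$site_a, c(1, 2))

  expect_error(propose_swap(make_grid(4, 4, matrix(1L, 4, 4))),
               "homogeneous")
})

test_that("minimization is a strict descent that conserves the A-count", {
  g <- generate_random(16, 16, 0.5, seed = 42)
  cfg <- minimization_config(h = 1.65, seed = 11)
  res <- minimize_free_energy(g, cfg)
  expect_lte(res$final$fbar, res$initial$fbar)
  expect_equal(a_count(res$grid), 128)
  expect_equal(res$fractions$x1, 0.5)
  acc <- res$trace[res$trace$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$f_after < acc$f_before))
  expect_true(all(diff(acc$f_after) < 0))
  expect_true(res$termination %in% c("swap_limit", "attempt_limit",
                                     "converged"))
  # the running free energy only moves on acceptance
  running <- c(res$initial$fbar,
               ifelse(res$trace$accepted, res$trace$f_after,
                      res$trace$f_before))
  expect_equal(res$trace$f_before, running[-length(running)],
               tolerance = 1e-12)
})

test_that("minimization runs are bit-reproducible under a fixed seed", {
  g <- generate_random(16, 16, 0.5, seed = 5)
  cfg <- minimization_config(h = 1.3, max_accepted_swaps = 50, seed = 77)
  r1 <- minimize_free_energy(g, cfg)
  r2 <- minimize_free_energy(g, cfg)
  expect_identical(r1$grid$states, r2$grid$states)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$final$fbar, r2$final$fbar)
})

test_that("a homogeneous grid returns unchanged as converged", {
  g <- make_grid(4, 4, matrix(1L, 4, 4))
  res <- minimize_free_energy(g, minimization_config(h = 1.5, seed = 1))
  expect_identical(res$grid$states, g$states)
  expect_equal(res$termination, "converged")
  expect_equal(res$accepted, 0L)
})

test_that("perturbation conserves x1 and undoes its own gains on descent", {
  g0 <- generate_random(16, 16, 0.5, seed = 3)
  cfg <- minimization_config(h = 1.65, max_accepted_swaps = 100, seed = 9)
  res <- minimize_free_energy(g0, cfg)

  expect_identical(perturb(res$grid, 0)$states, res$grid$states)
  gp <- perturb(res$grid, 5, seed = 13)
  expect_equal(a_count(gp), 128)
  expect_identical(perturb(res$grid, 5, seed = 13)$states, gp$states)

  eps1 <- eps1_from_h(1.65)
  f_perturbed <- free_energy(grid_fractions(gp), 0, eps1)$fbar
  res2 <- minimize_free_energy(gp, cfg)
  expect_lte(res2$final$fbar, f_perturbed)
})

test_that("a massed start retains more interior mass than a random start", {
  cfg <- minimization_config(h = 1.65, max_accepted_swaps = 100, seed = 31)
  from_rc <- minimize_free_energy(generate_rich_club(16, 16), cfg)
  from_rand <- minimize_free_energy(generate_random(16, 16, 0.5, seed = 32),
                                    cfg)
  expect_gt(from_rc$fractions$z1, from_rand$fractions$z1)
})

test_that("small sweeps are deterministic and internally consistent", {
  cfg_fn <- function(h) minimization_config(h = h, max_accepted_swaps = 40,
                                            max_attempts = 1500)
  tab <- sweep_h(c(1.0, 1.4), n_trials = 3, seed = 19, config_fn = cfg_fn)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$fbar, tab$hbar - tab$sbar, tolerance = 1e-12)
  tab2 <- sweep_h(c(1.0, 1.4), n_trials = 3, seed = 19, config_fn = cfg_fn)
  expect_identical(tab, tab2)
  smry <- sweep_h(c(1.0, 1.4), n_trials = 3, seed = 19, config_fn = cfg_fn,
                  summarize = TRUE)
  expect_equal(nrow(smry), 2)
  expect_equal(smry$fbar, smry$hbar - smry$sbar, tolerance = 1e-12)
})
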