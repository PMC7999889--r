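test_that("h and eps1 conversions are exact inverses with the known values", {
  expect_equal(h_from_eps1(0), 1)
  expect_equal(round(h_from_eps1(0.25), 4), 1.6487)
  expect_equal(round(h_from_eps1(0.25), 2), 1.65)
  expect_equal(round(eps1_from_h(5.828), 4), 0.8813)
  for (e in c(-0.5, 0, 0.1, 0.8813))
    expect_equal(eps1_from_h(h_from_eps1(e)), e, tolerance = 1e-15)
  expect_error(eps1_from_h(0), "positive")
  expect_error(eps1_from_h(-1), "positive")
})

test_that("Delta and its divergence points", {
  expect_equal(delta_h(1), 4)
  dv <- divergence_points()
  expect_equal(unname(round(dv, 3)), c(0.172, 5.828))
  expect_lt(abs(delta_h(0.172)), 1e-2)
  expect_lt(abs(delta_h(5.828)), 1e-2)
  expect_equal(delta_h(dv[["h_low"]]), 0, tolerance = 1e-12)
  expect_equal(delta_h(dv[["h_high"]]), 0, tolerance = 1e-12)
  # Vieta on -h^2 + 6h - 1
  expect_equal(prod(dv), 1, tolerance = 1e-12)
  expect_equal(sum(dv), 6, tolerance = 1e-12)
})

test_that("h = 1 equilibrium is the equiprobable random point, exactly", {
  eq <- analytic_equilibrium(1)
  fr <- eq$fractions
  expect_equal(eq$delta, 4)
  expect_equal(fr$x1, 0.5)
  for (v in c("y1", "y2", "y3", "w1", "w2", "w3"))
    expect_identical(fr[[v]], 0.25)
  for (v in paste0("z", 1:6))
    expect_identical(fr[[v]], 0.125)
})

test_that("equilibrium fractions satisfy all identities across the h range", {
  for (h in c(0.2, 0.5, 1, 1.16, 1.65, 2, 3, 5, 5.5)) {
    fr <- analytic_equilibrium(h)$fractions
    expect_lt(abs(fr$x1 + fr$x2 - 1), 1e-12)
    expect_lt(abs(fr$y1 + 2 * fr$y2 + fr$y3 - 1), 1e-12)
    expect_lt(abs(fr$w1 + 2 * fr$w2 + fr$w3 - 1), 1e-12)
    expect_lt(abs(fr$z1 + 2 * fr$z2 + fr$z3 + fr$z4 + 2 * fr$z5 + fr$z6 - 1),
              1e-12)
    expect_lt(max(abs(check_equivalences(fr))), 1e-12)
    # A<->B symmetry is built in
    expect_identical(fr$z1, fr$z6)
    expect_identical(fr$z2, fr$z5)
    expect_identical(fr$z3, fr$z4)
    expect_identical(fr$y1, fr$y3)
  }
})

test_that("z1 rises and z3 falls with h; y2 falls beyond h = 1", {
  hs <- seq(0.3, 5.5, by = 0.2)
  z1 <- sapply(hs, function(h) analytic_equilibrium(h)$fractions$z1)
  z3 <- sapply(hs, function(h) analytic_equilibrium(h)$fractions$z3)
  expect_true(all(diff(z1) > 0))
  expect_true(all(diff(z3) < 0))
  hs2 <- seq(1, 5.5, by = 0.2)
  y2 <- sapply(hs2, function(h) analytic_equilibrium(h)$fractions$y2)
  expect_true(all(diff(y2) < 0))
})

test_that("evaluation at or beyond the divergence points is refused", {
  expect_error(analytic_equilibrium(0.17), "diverges")
  expect_error(analytic_equilibrium(5.83), "h_high")
  expect_error(analytic_equilibrium(0.01), "h_low")
  expect_error(analytic_equilibrium(6), "diverges")
  expect_error(analytic_equilibrium(3 + 2 * sqrt(2) - 1e-9), "diverges")
})

test_that("zero-interaction solution: logistic x1 and independence products", {
  fr0 <- zero_interaction_solution(0)
  eq1 <- analytic_equilibrium(1)$fractions
  for (v in c("x1", "y1", "y2", "w2", paste0("z", 1:6)))
    expect_equal(fr0[[v]], eq1[[v]], tolerance = 1e-15)

  fr3 <- zero_interaction_solution(log(3))
  expect_equal(fr3$x1, 0.25, tolerance = 1e-15)
  expect_equal(fr3$z1, 0.25^3)
  expect_equal(fr3$z3, 0.25^2 * 0.75)

  expect_lt(zero_interaction_solution(30)$x1, 1e-12)

  # independent check: x1 = 1/(1 + e^eps0) minimizes the implemented free
  # energy over independence-product states at eps1 = 0
  f_of_x1 <- function(x1, eps0) {
    x2 <- 1 - x1
    fr <- config_fractions(x1, x2, x1^2, x1 * x2, x2^2,
                           x1^2, x1 * x2, x2^2,
                           x1^3, x1^2 * x2, x1^2 * x2,
                           x1 * x2^2, x1 * x2^2, x2^3)
    free_energy(fr, eps0, 0)$fbar
  }
  for (eps0 in c(0, log(3), 1.7)) {
    opt <- stats::optimize(f_of_x1, c(1e-6, 1 - 1e-6), eps0 = eps0,
                           tol = 1e-10)
    expect_equal(opt$minimum, 1 / (1 + exp(eps0)), tolerance = 1e-5)
  }
})
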