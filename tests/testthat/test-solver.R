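test_that("no consumption gives a flat substrate profile", {
  prof <- solve_substrate(model_params(0, 0, 3, 5), solver_options(n = 101))
  expect_equal(prof$S, rep(1, 101))
})

test_that("first-order solver matches the analytic oracle", {
  # S(1) = 2/e for gamma_E = 1, q = 2
  prof <- solve_substrate(model_params(1, 1, 0, 2), solver_options(n = 4001))
  expect_equal(prof$S[1], 2 / exp(1), tolerance = 1e-6)
  for (gE in c(1, 4)) {
    for (q in c(2, 5)) {
      pr <- solve_substrate(model_params(gE, gE, 0, q),
                            solver_options(n = 4001))
      ex <- first_order_exact(gE, q, pr$grid)
      expect_lt(max(abs(pr$S - ex$S)), 1e-5)
    }
  }
})

test_that("first_order_exact satisfies its boundary conditions by construction", {
  for (gE in c(1e-10, 0.5, 4, 50)) {
    for (q in c(1.5, 2, 5)) {
      g <- radial_grid(q, 401)
      ex <- first_order_exact(gE, q, g)
      expect_lt(abs(ex$S[401] - 1), 1e-14)
      # one-sided derivative at R = 1 is O(h^2), not exactly 0 on the grid
      h <- g$R[2] - g$R[1]
      expect_lt(abs((-3 * ex$S[1] + 4 * ex$S[2] - ex$S[3]) / (2 * h)), 1e-3)
    }
  }
  # vanishing reaction: profile tends to 1 uniformly
  g <- radial_grid(2, 101)
  expect_lt(max(abs(first_order_exact(1e-10, 2, g)$S - 1)), 1e-8)
})

test_that("solver error vs the oracle decays at order h^2", {
  errs <- vapply(c(251, 501, 1001, 2001), function(n) {
    pr <- solve_substrate(model_params(4, 4, 0, 5), solver_options(n = n))
    max(abs(pr$S - first_order_exact(4, 5, pr$grid)$S))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(c(250, 500, 1000, 2000))))[[2]]
  expect_equal(slope, -2, tolerance = 0.2)
})

test_that("numerical profiles satisfy physical bounds and boundary rows", {
  for (cs in all_default_cases()) {
    pr <- solve_substrate(cs$params, coarse_opts())
    expect_true(all(pr$S > 0))
    expect_true(all(pr$S <= 1 + 1e-12))
    expect_equal(pr$S[length(pr$S)], 1)          # Dirichlet row is exact
    expect_true(all(diff(pr$S) >= -1e-12))       # nondecreasing
  }
})

test_that("peroxide vanishes without a source and is nonnegative with one", {
  p0 <- model_params(4, 0, 0, 5)
  pr <- solve_substrate(p0, coarse_opts())
  pr <- solve_peroxide_linear(p0, pr)
  expect_equal(max(abs(pr$H)), 0)
  for (cs in all_default_cases()) {
    prof <- solve_profile(cs$params, coarse_opts())
    expect_true(all(prof$H >= -1e-12))
    expect_lt(abs(prof$H[1]), 1e-12)
    expect_lt(abs(prof$H[length(prof$H)]), 1e-12)
  }
})

test_that("linear solve and harmonic reconstruction agree on H", {
  # hand-computed point value for the first-order case
  p <- model_params(1, 1, 0, 2)
  prof <- solve_profile(p, solver_options(n = 4001))
  i <- which.min(abs(prof$grid$R - 1.5))
  S1 <- 2 / exp(1)
  b <- 2 * (S1 - 1)
  a <- S1 - b
  H_expect <- a + b / 1.5 - 2 * exp(-0.5) / 1.5
  expect_equal(prof$H[i], H_expect, tolerance = 1e-5)

  alt <- reconstruct_peroxide_harmonic(p, prof)
  expect_equal(alt$meta$harmonic[["a"]], a, tolerance = 1e-5)
  expect_equal(alt$meta$harmonic[["b"]], b, tolerance = 1e-5)
  expect_lt(max(abs(prof$H - alt$H)), 1e-8)

  for (cs in all_default_cases()[c(1, 4)]) {
    prof <- solve_profile(cs$params, solver_options(n = 4001))
    alt <- reconstruct_peroxide_harmonic(cs$params, prof)
    expect_lt(max(abs(prof$H - alt$H)), 1e-8)
  }
})

test_that("harmonic reconstruction is linear in gamma_S and exact at bounds", {
  p <- model_params(4, 4, 2, 5)
  prof <- solve_substrate(p, coarse_opts())
  h1 <- reconstruct_peroxide_harmonic(p, prof)
  p2 <- model_params(4, 8, 2, 5)
  h2 <- reconstruct_peroxide_harmonic(p2, prof)
  expect_equal(h2$H, 2 * h1$H, tolerance = 1e-12)
  expect_equal(h1$H[1], 0)
  expect_lt(abs(h1$H[length(h1$H)]), 1e-14)
  # flat substrate (gamma_E -> 0 limit shape) gives H identically zero
  flat <- prof
  flat$S <- rep(1, prof$grid$n)
  h0 <- reconstruct_peroxide_harmonic(p, flat)
  expect_lt(max(abs(h0$H)), 1e-14)
  # gamma_E = 0 must be routed to the linear solver
  expect_error(reconstruct_peroxide_harmonic(model_params(0, 1, 0, 5), prof),
               "solve_peroxide_linear")
})

test_that("harmonic-combination invariant holds for solved profiles", {
  p <- model_params(4, 4, 2, 5)
  prof <- solve_profile(p, solver_options(n = 4001))
  expect_lt(harmonic_invariant_residual(prof), 1e-5)
  alt <- reconstruct_peroxide_harmonic(p, prof)
  expect_lt(harmonic_invariant_residual(alt), 1e-12)
  # negative control: zeroing the interior H must break the identity
  corrupt <- prof
  corrupt$H[2:(prof$grid$n - 1)] <- 0
  expect_gt(harmonic_invariant_residual(corrupt), 1e-3)
})

test_that("substrate surface value is monotone in gamma_E and alpha", {
  gammas <- c(2, 5, 10, 20)
  alphas <- c(0.5, 2, 8, 32)
  S1 <- outer(gammas, alphas, Vectorize(function(gE, al) {
    solve_substrate(model_params(gE, gE, al, 1.5), coarse_opts())$S[1]
  }))
  # strictly decreasing in gamma_E (rows), strictly increasing in alpha (cols)
  expect_true(all(apply(S1, 2, diff) < 0))
  expect_true(all(apply(S1, 1, diff) > 0))
})

test_that("solver handles a stiff saturated case via continuation", {
  p <- model_params(200, 200, 5, 5)
  prof <- solve_profile(p, solver_options(n = 2001))
  # deep depletion: S(1) is zero to rounding, so allow the rounding floor
  expect_true(all(prof$S > -1e-12 & prof$S <= 1 + 1e-12))
  res <- residuals_profile(prof)
  expect_lt(max(abs(res$resS)), 1e-3)
})
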