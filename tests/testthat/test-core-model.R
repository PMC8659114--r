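test_that("mm_rate matches direct arithmetic and rejects bad input", {
  expect_identical(mm_rate(0, 30, 100), 0)
  expect_identical(mm_rate(1, 30, 0), 30)
  expect_equal(mm_rate(1, 30, 100), 30 / 101)
  expect_error(mm_rate(-0.1, 30, 100), "nonnegative")
  expect_error(mm_rate(1, -1, 0), "nonnegative")
})

test_that("mm_rate is monotone, bounded, and concave for alpha > 0", {
  s <- seq(0, 5, length.out = 101)
  for (al in c(0, 0.5, 10, 100)) {
    v <- mm_rate(s, gamma = 7, alpha = al)
    expect_true(all(diff(v) >= 0))
    if (al > 0) {
      expect_true(all(v <= 7 / al + 1e-15))
      # concavity: second difference nonpositive
      expect_true(all(diff(v, differences = 2) <= 1e-12))
    } else {
      # linear in s
      expect_equal(v, 7 * s)
    }
  }
})

test_that("to_dimensionless reproduces the defining ratios", {
  p <- dimensional_params(DS = 1, DH = 2, kcat = 1, CE = 1, KM = 1,
                          r0 = 1, r1 = 5, CS_star = 1)
  mp <- to_dimensionless(p)
  expect_equal(mp$gamma_E, 1)
  expect_equal(mp$gamma_S, 0.5)
  expect_equal(mp$alpha, 1)
  expect_equal(mp$q, 5)

  # equal diffusivities give equal reaction-diffusion parameters
  p2 <- dimensional_params(DS = 3e-6, DH = 3e-6, kcat = 12, CE = 2e-8,
                           KM = 1e-6, r0 = 2e-3, r1 = 6e-3, CS_star = 5e-6)
  mp2 <- to_dimensionless(p2)
  expect_equal(mp2$gamma_E, mp2$gamma_S)

  # gamma_E/gamma_S always equals DH/DS
  expect_equal(mp$gamma_E / mp$gamma_S, p$DH / p$DS, tolerance = 1e-12)
})

test_that("dimensionless groups are invariant under joint rescaling", {
  base <- list(DS = 2e-6, DH = 5e-6, kcat = 8, CE = 4e-8, KM = 2e-6,
               r0 = 1e-3, r1 = 4e-3, CS_star = 3e-6)
  mp0 <- to_dimensionless(do.call(dimensional_params, base))
  for (c_ in c(0.1, 3, 100)) {
    scaled <- base
    scaled$kcat <- base$kcat * c_
    scaled$CE <- base$CE  # kcat*CE scaling split across the two factors
    scaled$DS <- base$DS * c_
    scaled$DH <- base$DH * c_
    mp <- to_dimensionless(do.call(dimensional_params, scaled))
    expect_equal(mp$gamma_E, mp0$gamma_E, tolerance = 1e-12)
    expect_equal(mp$gamma_S, mp0$gamma_S, tolerance = 1e-12)
    expect_equal(mp$alpha, mp0$alpha)
    expect_equal(mp$q, mp0$q)
  }
})

test_that("dimensional invariants are enforced", {
  expect_error(dimensional_params(DS = 1, DH = 1, kcat = 1, CE = 1, KM = 1,
                                  r0 = 2, r1 = 1, CS_star = 1),
               "r1 must exceed")
  expect_error(dimensional_params(DS = -1, DH = 1, kcat = 1, CE = 1, KM = 1,
                                  r0 = 1, r1 = 2, CS_star = 1),
               "positive")
  # KM consistency with elementary constants
  expect_silent(dimensional_params(DS = 1, DH = 1, kcat = 2, CE = 1, KM = 3,
                                   r0 = 1, r1 = 2, CS_star = 1,
                                   k1 = 1, k_rev = 1))
  expect_error(dimensional_params(DS = 1, DH = 1, kcat = 2, CE = 1, KM = 4,
                                  r0 = 1, r1 = 2, CS_star = 1,
                                  k1 = 1, k_rev = 1),
               "KM inconsistent")
})

test_that("residuals vanish for the no-reaction steady state", {
  g <- radial_grid(5, 11)
  prof <- concentration_profile(g, S = rep(1, 11), H = rep(0, 11),
                                params = model_params(0, 0, 0, 5))
  res <- residuals_profile(prof)
  expect_equal(max(abs(res$resS)), 0)
  expect_equal(max(abs(res$resH)), 0)
  expect_equal(unname(res$bc_res), c(0, 0, 0, 0))
})

test_that("a constant profile leaves exactly the rate term as residual", {
  g <- radial_grid(5, 21)
  p <- model_params(30, 30, 100, 5)
  prof <- concentration_profile(g, S = rep(1, 21), H = rep(0, 21), params = p)
  res <- residuals_profile(prof)
  expect_equal(res$resS, rep(-30 / 101, 19))
  expect_equal(res$resH, rep(30 / 101, 19))
})

test_that("residuals of the exact first-order solution decay at order h^2", {
  ns <- c(51, 101, 201, 401)
  errs <- vapply(ns, function(n) {
    g <- radial_grid(2, n)
    ex <- first_order_exact(1, 2, g)
    prof <- concentration_profile(g, S = ex$S, H = rep(0, n),
                                  params = model_params(1, 0, 0, 2))
    max(abs(residuals_profile(prof)$resS))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(ns - 1)))[[2]]
  expect_equal(slope, -2, tolerance = 0.2)
})

test_that("residuals support both expanded and conservative forms", {
  p <- model_params(4, 4, 0, 5)
  prof <- solve_substrate(p, solver_options(n = 1001))
  prof <- solve_peroxide_linear(p, prof)
  for (form in c("expanded", "conservative")) {
    res <- residuals_profile(prof, form = form)
    expect_lt(max(abs(res$resS)), 1e-4)
  }
  # mismatched lengths are a shape error
  bad <- prof
  bad$H <- bad$H[-1]
  expect_error(residuals_profile(bad), "mismatch|length")
})

test_that("profile CSV round-trips at full precision", {
  p <- model_params(4, 4, 2, 5)
  prof <- solve_profile(p, solver_options(n = 101))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  df <- read_profile_csv(path)
  expect_equal(df$R, prof$grid$R)
  expect_equal(df$S, prof$S)
  expect_equal(df$H, prof$H)
  # absent component written as empty field, read back as NA
  s_only <- solve_substrate(p, solver_options(n = 51))
  write_profile_csv(s_only, path)
  df2 <- read_profile_csv(path)
  expect_true(all(is.na(df2$H)))
  expect_equal(df2$S, s_only$S)
})
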