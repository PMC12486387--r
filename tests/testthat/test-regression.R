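test_that("growth-rate estimation from viable-cell data", {
  # doubling over 24 h
  mu <- estimate_mu_from_vcc(c(0, 24), c(1, 2))
  expect_equal(mu[2], log(2) / 24)
  expect_equal(mu[1], mu[2])          # first entry duplicates the second
  # constant cells give zero everywhere
  expect_equal(estimate_mu_from_vcc(c(0, 24, 48), c(3, 3, 3)),
               rep(0, 3))
  # missing interior values propagate, the first entry takes the first
  # available estimate
  mu2 <- estimate_mu_from_vcc(c(0, 24, 48, 72), c(1, NA, 4, 8))
  expect_true(is.na(mu2[2]) && is.na(mu2[3]))
  expect_equal(mu2[4], log(2) / 24)
  expect_equal(mu2[1], mu2[4])
  expect_error(estimate_mu_from_vcc(c(0, 24), c(1, -2)), "positive")
})

test_that("min-max normalization and its inverse", {
  m <- cbind(a = c(1, 2, 3), b = c(10, NA, 30), c = c(5, 5, 5))
  nm <- minmax_normalize(m)
  expect_equal(nm$scaled[, "a"], c(0, 0.5, 1))
  expect_equal(nm$scaled[c(1, 3), "b"], c(0, 1))
  expect_true(is.na(nm$scaled[2, "b"]))
  expect_true(nm$constant[["c"]])
  back <- minmax_denormalize(nm$scaled[, 1:2], nm)
  expect_equal(back[, "a"], m[, "a"], tolerance = 1e-12)
})

test_that("goodness-of-fit metrics match their definitions", {
  d <- c(0, 1, 2)
  expect_equal(r_squared(d, d), 1)
  expect_equal(r_squared(d, rep(mean(d), 3)), 0)
  expect_equal(r_squared(d, c(0, 0, 0)), 1 - 5 / 2)  # hand evaluation
  expect_true(is.na(r_squared(c(2, 2, 2), c(1, 2, 3))))
  expect_equal(nrmse(d, d), 0)
  expect_equal(nrmse(c(0, 10), c(1, 11)), 10)   # all residuals 0.1 scaled
  # unit invariance of NRMSE
  expect_equal(nrmse(d * 180.16, c(0.1, 1.2, 1.9) * 180.16),
               nrmse(d, c(0.1, 1.2, 1.9)))
  expect_error(nrmse(c(1, 1), c(1, 2)), "degenerate")
})

test_that("yield initial guesses follow the mass-balance formula", {
  # no feeds, constant volume: c_i 0 -> 2 while c_j 4 -> 0 gives 0.5
  obs <- matrix(NA_real_, 7, 8, dimnames = list(NULL, mckm_state_names))
  obs[, "Xv"] <- seq(1, 7)
  obs[, "lac"] <- seq(0, 2, length.out = 7)
  obs[, "glc"] <- seq(4, 0, length.out = 7)
  obs[, c("P", "glu", "gln", "amm")] <- 1
  run <- suppressWarnings(culture_run(seq(0, 144, by = 24), obs))
  yb <- suppressWarnings(estimate_yield_ig_bounds(list(run)))
  expect_equal(unname(yb$per_run[1, "Y_lac_glc"]), 0.5)
  # no change in the numerator gives a zero yield (clipped to the bound box)
  expect_equal(unname(yb$per_run[1, "Y_P_X"]),
               unname(parameter_bounds()$lb[["Y_P_X"]]))
  # single-run cohort bounds are widened around the guess
  expect_lt(yb$lb[["Y_lac_glc"]], 0.5)
  expect_gt(yb$ub[["Y_lac_glc"]], 0.5)
  # feeds enter the denominator as fed mass
  run2 <- run
  run2$schedule <- feed_schedule(24, 0.001, 100, 50)
  yb2 <- suppressWarnings(estimate_yield_ig_bounds(list(run2),
                                                   model_constants()))
  V0 <- model_constants()$V0
  expect_equal(unname(yb2$per_run[1, "Y_lac_glc"]),
               (2 * (V0 + 0.001)) / (4 * V0 + 0.1),
               tolerance = 1e-12)
})

test_that("Monod pre-regression recovers exact generating parameters", {
  glc <- c(6, 3, 1.2, 0.4)
  mu <- 0.03 * glc / (1.2 + glc)
  obs <- matrix(NA_real_, 4, 8, dimnames = list(NULL, mckm_state_names))
  obs[, "Xv"] <- 1; obs[, "glc"] <- glc; obs[, "mu_est"] <- mu
  obs[, c("P", "glu", "gln", "amm", "lac")] <- 1
  run <- culture_run(c(0, 24, 48, 72), obs)
  est <- preregress_monod(run)
  expect_equal(unname(est), c(0.03, 1.2), tolerance = 1e-6)
  # rank-deficient glucose triggers the fallback
  obs2 <- obs; obs2[, "glc"] <- 5
  run2 <- culture_run(c(0, 24, 48, 72), obs2)
  expect_warning(est2 <- preregress_monod(run2), "no spread")
  expect_equal(unname(est2), unname(parameter_bounds()$ig[c("mu_max",
                                                            "K_glc")]))
  # zero growth estimates drive mu_max to its lower bound
  obs3 <- obs; obs3[, "mu_est"] <- 0
  run3 <- culture_run(c(0, 24, 48, 72), obs3)
  est3 <- suppressWarnings(preregress_monod(run3))
  expect_equal(unname(est3[["mu_max"]]),
               unname(parameter_bounds()$lb[["mu_max"]]), tolerance = 1e-8)
})

test_that("objective is zero at the generating truth and unit-invariant", {
  run <- noise_free_run()
  theta <- attr(run, "theta_true")
  cons <- model_constants()
  expect_lte(mckm_objective(theta, run, cons), 1e-8)
  th2 <- kinetic_parameters(replace(unclass(theta), "mu_max",
                                    theta[["mu_max"]] * 1.2))
  base <- mckm_objective(th2, run, cons)
  expect_gt(base, 0)
  # min-max scaling makes each column's residuals invariant to its units:
  # an affine change of units applied to data and prediction alike leaves
  # the normalized residual unchanged
  d <- run$observations[, "glc"]
  p <- d + rnorm(length(d), 0, 0.3)
  norm_res <- function(d, p) (p - min(d)) / diff(range(d)) -
    (d - min(d)) / diff(range(d))
  expect_equal(norm_res(d * 180.16 + 3, p * 180.16 + 3), norm_res(d, p),
               tolerance = 1e-12)
  # masking an entry never increases the cost
  run_masked <- run
  run_masked$observations[4, "lac"] <- NA
  expect_lte(mckm_objective(th2, run_masked, cons), base + 1e-12)
})

test_that("fitting a noise-free run reproduces every trajectory", {
  run <- noise_free_run()
  theta <- attr(run, "theta_true")
  fit <- fit_run(run)
  expect_s3_class(fit, "mckm_fit")
  expect_true(all(fit$r2 >= 0.99))
  rel <- abs(unclass(fit$theta_hat) - unclass(theta)) / unclass(theta)
  expect_lt(rel[["mu_max"]], 0.10)
  expect_lt(rel[["Y_P_X"]], 0.10)
  expect_lt(rel[["Y_X_glc"]], 0.10)
})

test_that("degenerate bounds pin the fit to the truth in free mode", {
  run <- noise_free_run()
  theta <- attr(run, "theta_true")
  b <- parameter_bounds()
  eps <- 1e-9
  b$lb[] <- unclass(theta) * (1 - eps)
  b$ub[] <- unclass(theta) * (1 + eps) + 1e-15
  b$ig[] <- unclass(theta)
  fit <- suppressWarnings(fit_run(run, bounds = b, balancing = FALSE))
  expect_equal(unclass(fit$theta_hat), unclass(theta), tolerance = 1e-4)
  expect_identical(fit$mode, "free")
})

test_that("culture runs validate their schema", {
  run <- noise_free_run()
  obs <- run$observations
  expect_error(culture_run(c(0, 24), obs[1:3, ]), "one row per")
  expect_error(culture_run(c(0, 24, 24), obs[1:3, ]), "increasing")
  bad <- obs; bad[1, "Xv"] <- NA
  expect_error(culture_run(run$sample_times, bad), "first viable-cell")
  extra <- cbind(obs, junk = 1)
  expect_error(culture_run(run$sample_times, extra), "unknown")
  # a 7-column table gains the growth-rate estimate automatically
  run7 <- culture_run(run$sample_times,
                      obs[, setdiff(mckm_state_names, "mu_est")])
  expect_equal(run7$observations[, "mu_est"],
               estimate_mu_from_vcc(run$sample_times, obs[, "Xv"]))
})
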