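test_that("bolus feeds mix, dilute, and conserve mass", {
  st <- culture_state(Xv = 2, P = 0.4, glc = 1, glu = 4, gln = 0.5,
                      amm = 1, lac = 0.6, mu_est = 0.02)
  ev <- feed_schedule(10, 0.010, 3, 50)[1, ]
  out <- apply_bolus_feed(st, 0.010, ev)
  expect_equal(out$V, 0.020)
  expect_equal(out$state[["glc"]], 2)            # equal-volume mixing
  expect_equal(out$state[["Xv"]], 1)             # dilution only
  expect_equal(out$state[["mu_est"]], 0.02)      # a rate is not diluted
  # mass conservation for every species
  for (v in c("glc", "glu")) {
    fed <- ev[[if (v == "glc") "glc_feed_gL" else "glu_feed_mM"]] * ev$V_feed_L
    expect_equal(out$state[[v]] * out$V, st[[v]] * 0.010 + fed,
                 tolerance = 1e-12)
  }
  for (v in c("Xv", "P", "gln", "amm", "lac"))
    expect_equal(out$state[[v]] * out$V, st[[v]] * 0.010, tolerance = 1e-12)
  # an empty bolus is a no-op
  ev0 <- feed_schedule(10, 0, 3, 50)[1, ]
  out0 <- apply_bolus_feed(st, 0.010, ev0)
  expect_identical(out0$state, st)
  expect_identical(out0$V, 0.010)
})

test_that("feed schedule construction validates its invariants", {
  expect_error(feed_schedule(c(10, 10), 1e-3, 3, 50), "increasing")
  expect_error(feed_schedule(c(10, 20), -1e-3, 3, 50), "non-negative")
  sched <- default_feed_schedule()
  expect_equal(nrow(sched), 5)
  expect_equal(sched$time_h, default_sample_times()[2:6])
})

test_that("fed-batch simulation iterates the batch model between samples", {
  theta <- central_theta()
  cons <- model_constants()
  sim <- simulate_fedbatch(theta, default_initial_state(), cons,
                           default_feed_schedule(), dense_n = 2)
  expect_equal(length(sim$diagnostics), 6)   # 7 sampling times, 6 iterations
  expect_equal(dim(sim$states), c(7, 8))
  expect_true(all(diff(sim$volume) >= 0))
  expect_error(simulate_fedbatch(theta, default_initial_state(), cons,
                                 feed_schedule(33, 1e-3, 3, 50)),
               "coincide")
  # frozen dynamics: only dilution changes the states between samples
  th0 <- unclass(theta)
  th0[c("mu_max", "m_glc", "k_d")] <- 0
  sim0 <- simulate_fedbatch(kinetic_parameters(th0),
                            default_initial_state(), cons,
                            default_feed_schedule(), dense_n = 2)
  expect_equal(sim0$states[2, "Xv"], sim0$states[1, "Xv"])
  dil <- cons$V0 / (cons$V0 + 5e-4)
  expect_equal(sim0$states[3, "Xv"], sim0$states[2, "Xv"] * dil,
               tolerance = 1e-10)
})

test_that("an empty schedule reproduces one continuous batch integration", {
  theta <- central_theta()
  cons <- model_constants()
  empty <- feed_schedule(numeric(0), numeric(0), numeric(0), numeric(0))
  sim <- simulate_fedbatch(theta, default_initial_state(), cons, empty,
                           dense_n = 2, rtol = 1e-8, atol = 1e-10)
  y0 <- sim$states[1, ]
  one <- mckm:::.integrate_batch(y0, default_sample_times(), theta, cons,
                                 rtol = 1e-8, atol = 1e-10)
  # agreement within 10x the solver's own error weights
  err_ratio <- abs(sim$states - one) / (1e-10 + 1e-8 * abs(one))
  expect_lt(max(err_ratio), 10)
})

test_that("splitting a feed-free interval at interior points preserves the endpoint", {
  theta <- central_theta()
  cons <- model_constants()
  y0 <- unclass(default_initial_state())
  y0[["mu_est"]] <- growth_rate(theta, y0[["glc"]])
  direct <- mckm:::.integrate_batch(y0, c(0, 150), theta, cons,
                                    rtol = 1e-8, atol = 1e-10)
  for (split in c(40, 75, 120)) {
    a <- mckm:::.integrate_batch(y0, c(0, split), theta, cons,
                                 rtol = 1e-8, atol = 1e-10)
    b <- mckm:::.integrate_batch(a[nrow(a), ], c(split, 150), theta, cons,
                                 rtol = 1e-8, atol = 1e-10)
    expect_equal(unname(b[nrow(b), ]), unname(direct[nrow(direct), ]),
                 tolerance = 1e-6)
  }
})

test_that("glucose mass balance closes across the whole fed run", {
  theta <- central_theta()
  mb <- glucose_mass_balance(theta, default_initial_state(),
                             model_constants(), default_feed_schedule())
  expect_lt(mb$rel_error, 1e-6)
  expect_equal(mb$fed_mass_g, 5 * 5e-4 * 100)
})

test_that("permanently active production keeps lactate non-decreasing", {
  theta <- central_theta()
  cons <- model_constants(alpha_glc = 1e-9)  # production branch everywhere
  sim <- simulate_fedbatch(theta, default_initial_state(), cons,
                           feed_schedule(numeric(0), numeric(0),
                                         numeric(0), numeric(0)),
                           dense_n = 40)
  expect_true(all(diff(sim$trajectory$lac) > -1e-9))
  # without ammonium production or initial ammonium there is no death, so
  # biomass is non-decreasing while glucose lasts
  th <- unclass(theta)
  th["Y_X_amm"] <- 20  # weakest allowed ammonium production
  ini <- culture_state(Xv = 0.3, P = 0, glc = 6, glu = 4, gln = 0.5,
                       amm = 0, lac = 0.2)
  sim2 <- simulate_fedbatch(kinetic_parameters(th), ini, cons,
                            feed_schedule(numeric(0), numeric(0),
                                          numeric(0), numeric(0)),
                            sample_times = c(0, 24, 48, 72), dense_n = 40)
  expect_true(all(diff(sim2$trajectory$Xv) > -1e-8))
})

test_that("the lactate switch crossing is located and the branches change", {
  theta <- central_theta()
  cons <- model_constants(alpha_glc = 0.5)
  sim <- simulate_fedbatch(theta, default_initial_state(), cons,
                           default_feed_schedule(), dense_n = 50)
  roots <- na.omit(vapply(sim$diagnostics,
                          function(d) d$switch_time_h, numeric(1)))
  expect_gt(length(roots), 0)
  tr <- sim$trajectory
  t1 <- roots[1]
  before <- tr[max(which(tr$time_h < t1 - 1)), ]
  after <- tr[min(which(tr$time_h > t1 + 1 & tr$time_h < t1 + 20)), ]
  expect_gt(before$glc, cons$alpha_glc)
  expect_lt(after$glc, cons$alpha_glc)
  expect_lt(after$lac, before$lac + (after$time_h - before$time_h) * 1e-4)
})
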