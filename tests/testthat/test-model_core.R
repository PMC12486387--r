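test_that("parameter vector construction enforces the model's invariants", {
  theta <- central_theta()
  expect_length(theta, 13)
  expect_named(theta, mckm_parameter_names)
  expect_error(kinetic_parameters(replace(unclass(theta), "mu_max", -1)),
               "non-negative")
  expect_error(kinetic_parameters(replace(unclass(theta), "Y_lac_glc", 2.5)),
               "stoichiometric")
  expect_error(kinetic_parameters(replace(unclass(theta), "Y_gln_glu", 1.2)),
               "stoichiometric")
  expect_error(kinetic_parameters(unclass(theta)[-1]), "missing")
  b <- parameter_bounds()
  expect_true(all(b$lb <= b$ig & b$ig <= b$ub))
  expect_error(parameter_bounds(lb = c(mu_max = 0.05), ub = c(mu_max = 0.02)))
})

test_that("growth rate follows Monod kinetics in glucose", {
  theta <- kinetic_parameters(replace(unclass(central_theta()),
                                      c("mu_max", "K_glc"), c(0.02, 1)))
  expect_equal(growth_rate(theta, 1), 0.01)     # half saturation
  expect_equal(growth_rate(theta, 0), 0)
  expect_lt(growth_rate(theta, 1e6), 0.02)      # bounded by mu_max
  th2 <- kinetic_parameters(replace(unclass(central_theta()),
                                    c("mu_max", "K_glc"), c(0.0258, 1.05)))
  expect_equal(growth_rate(th2, 5), 0.0258 * 5 / 6.05)
  expect_error(growth_rate(theta, -0.1), "non-negative")
})

test_that("death rate saturates in ammonium", {
  theta <- kinetic_parameters(replace(unclass(central_theta()),
                                      c("k_d", "KD_amm"), c(0.016, 5)))
  expect_equal(death_rate(theta, 0), 0)
  expect_equal(death_rate(theta, 5), 0.008)     # half saturation
  expect_equal(death_rate(theta, 1e9), 0.016, tolerance = 1e-6)
  expect_error(death_rate(theta, -1), "non-negative")
})

test_that("specific rates implement the glucose-gated lactate switch", {
  theta <- central_theta()
  cons <- model_constants(alpha_glc = 0.5)
  above <- culture_state(Xv = 1, P = 0, glc = 2, glu = 4, gln = 0.5,
                         amm = 1, lac = 0.2, mu_est = 0.02)
  below <- replace(unclass(above), "glc", 0.2)
  qa <- specific_rates(theta, above, cons)
  qb <- specific_rates(theta, below, cons)
  expect_equal(qa$q_lac, theta[["Y_lac_glc"]] * qa$q_glc) # production
  expect_equal(qb$q_lac, -qb$mu / theta[["Y_X_lac"]])     # consumption
  expect_lt(qb$q_lac, 0)
  # flipping the printed inequality swaps the branches
  qa2 <- specific_rates(theta, above, cons, lactate_switch_as_printed = TRUE)
  expect_equal(qa2$q_lac, -qa$mu / theta[["Y_X_lac"]])
  # worked values: production is Y_lac_glc * q_glc, consumption mu/Y_X_lac
  th <- replace(unclass(theta), c("Y_lac_glc", "Y_X_lac"), c(0.615, 2.7))
  st <- replace(unclass(above), "glc", 100)
  q <- specific_rates(kinetic_parameters(th), st, cons)
  expect_equal(q$q_lac, 0.615 * q$q_glc)
  # zero growth and zero maintenance silence every rate
  th0 <- replace(unclass(theta), c("mu_max", "m_glc"), c(0, 0))
  q0 <- specific_rates(kinetic_parameters(th0), above, cons)
  expect_true(all(abs(unlist(q0[c("q_P", "q_glc", "q_glu", "q_gln",
                                  "q_amm", "q_lac", "mu")])) == 0))
  expect_error(specific_rates(kinetic_parameters(
    replace(unclass(theta), "Y_X_glc", 0)), above, cons), "zero yield")
})

test_that("batch right-hand side has the stated structure", {
  theta <- central_theta()
  cons <- model_constants()
  st <- culture_state(Xv = 2, P = 0.1, glc = 3, glu = 4, gln = 0.5,
                      amm = 1.5, lac = 0.5, mu_est = 0.02)
  d <- batch_rhs(0, st, theta, cons)
  # no cells, no fluxes
  d0 <- batch_rhs(0, replace(unclass(st), "Xv", 0), theta, cons)
  expect_true(all(d0 == 0))
  # growth-rate state derivative carries the sign of dglc/dt
  expect_equal(sign(d[["mu_est"]]), sign(d[["glc"]]))
  # sign of dgln/dt follows the net of GS production vs consumption
  q <- specific_rates(theta, st, cons)
  expect_equal(sign(d[["gln"]]),
               sign(theta[["Y_gln_glu"]] / theta[["Y_X_glu"]] -
                      1 / theta[["Y_X_gln"]]))
  # with maintenance off and production branch active,
  # dlac/dt = -Y_lac_glc * dglc/dt
  th <- kinetic_parameters(replace(unclass(theta), "m_glc", 0))
  dm <- batch_rhs(0, st, th, cons)
  expect_equal(dm[["lac"]], -th[["Y_lac_glc"]] * dm[["glc"]])
  expect_error(batch_rhs(0, replace(unclass(st), "glc", NaN), theta, cons),
               "non-finite")
})

test_that("growth and death rates stay inside their saturation bounds over random states", {
  set.seed(11)
  b <- parameter_bounds()
  for (i in 1:25) {
    th <- kinetic_parameters(b$lb + runif(13) * (b$ub - b$lb))
    st <- culture_state(Xv = runif(1, 0, 30), P = runif(1, 0, 3),
                        glc = runif(1, 0, 10), glu = runif(1, 0, 10),
                        gln = runif(1, 0, 5), amm = runif(1, 0, 10),
                        lac = runif(1, 0, 5), mu_est = 0.02)
    q <- specific_rates(th, st, model_constants())
    expect_gte(q$mu, 0); expect_lte(q$mu, th[["mu_max"]])
    expect_gte(q$mu_d, 0); expect_lte(q$mu_d, th[["k_d"]])
  }
})

test_that("compiled derivative agrees with the reference R implementation", {
  theta <- central_theta()
  cons <- model_constants()
  sched <- default_feed_schedule()
  y0 <- unclass(default_initial_state())
  y0[["mu_est"]] <- growth_rate(theta, y0[["glc"]])
  s_c <- mckm:::.simulate_states(unname(theta), y0, cons, sched,
                                 default_sample_times(),
                                 use_compiled = TRUE)
  s_r <- mckm:::.simulate_states(unname(theta), y0, cons, sched,
                                 default_sample_times(),
                                 use_compiled = FALSE)
  expect_equal(s_c, s_r, tolerance = 1e-7)
})

test_that("integrated trajectory is consistent with the right-hand side", {
  # local truncation check: finite differences of a dense trajectory match
  # batch_rhs midpoints
  theta <- central_theta()
  cons <- model_constants()
  sim <- simulate_fedbatch(theta, default_initial_state(), cons,
                           feed_schedule(numeric(0), numeric(0),
                                         numeric(0), numeric(0)),
                           sample_times = c(0, 48), dense_n = 200,
                           rtol = 1e-10, atol = 1e-12)
  tr <- sim$trajectory
  i <- seq(10, 180, by = 20)
  for (k in i) {
    dt <- tr$time_h[k + 1] - tr$time_h[k - 1]
    fd <- (unlist(tr[k + 1, mckm_state_names]) -
             unlist(tr[k - 1, mckm_state_names])) / dt
    st <- unlist(tr[k, mckm_state_names])
    rhs <- batch_rhs(tr$time_h[k], st, theta, cons)
    expect_equal(unname(fd), unname(rhs), tolerance = 1e-3)
  }
})
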