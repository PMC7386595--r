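p <- model_params()

test_that("dendritic nonlinearity matches its closed form", {
  # frozen values computed from the closed form (see helper oracle)
  expect_equal(g_dend(0, p), 3.030265e-05, tolerance = 1e-4)
  expect_equal(g_dend(2.5, p), 1.3487922, tolerance = 1e-6)
  expect_equal(g_dend(-1, p), 5.551545e-07, tolerance = 1e-4)
  expect_equal(g_dend(1e3, p), 2)
  I <- seq(-5, 15, by = 0.05)
  expect_equal(g_dend(I, p), g_dend_oracle(I), tolerance = 1e-12)
  # range property
  expect_true(all(g_dend(I, p) >= 0 & g_dend(I, p) <= 2))
  expect_error(g_dend(NaN, p), "non-finite")
})

test_that("linear dendrite control keeps the maximum and small-signal gain", {
  pl <- model_params(dendrite_mode = "linear")
  expect_equal(g_dend(1e4, pl), 2)
  eps <- 1e-6
  expect_equal(g_dend(eps, pl) / eps, g_dend(eps, p) / eps -
                 (g_dend(0, p) / eps), tolerance = 1e-3)
  # no dendritic-spike step: the linear curve is concave throughout
  I <- seq(0.1, 10, by = 0.1)
  d2 <- diff(diff(g_dend(I, pl)))
  expect_true(all(d2 < 1e-12))
})

test_that("propagation gate is all-or-nothing with configurable strictness", {
  expect_equal(g_prop(p$theta_prop - 0.1, p), 0)
  expect_equal(g_prop(p$theta_prop + 0.1, p), 1)
  expect_equal(g_prop(0, model_params(theta_prop = -0.2)), 1)
  # non-strict by default: open at equality, so the injection threshold
  # lands exactly at I_ext = I_soma + theta_prop
  expect_equal(g_prop(p$theta_prop, p), 1)
  expect_equal(g_prop(p$theta_prop, model_params(gate_strict = TRUE)), 0)
  expect_equal(g_prop(-100, model_params(gate_enabled = FALSE)), 1)
})

test_that("dendritic and somatic drives are exact sums", {
  expect_equal(dendritic_drive(rep(0, 5), runif(5), 0.8), -0.8)
  expect_equal(dendritic_drive(rep(1, 10), rep(0.1, 10), 0), 1)
  expect_equal(dendritic_drive(c(2, rep(0, 9)), c(2.2, runif(9)), 0.8, 1), 4.6)
  expect_error(dendritic_drive(1:3, 1:2, 0), "length")
  sd <- somatic_drive(0, 0, 1.2)
  expect_equal(sd$E_soma, 0)
  expect_equal(sd$V_soma, -1.2)
  expect_equal(somatic_drive(0, 1.5, 1.2)$V_soma, 0.3)
})

test_that("rate dynamics converge to their fixed points", {
  # constant dendritic drive at the spike threshold
  st <- list(r_dend = 0, r_soma = 0, t = 0)
  for (i in 1:50) {  # 50 ms = 10 tau0
    st <- step_dynamics(st, list(p_dend = 2.5, E_soma = 1, I_soma = 0), p)
  }
  expect_equal(st$r_dend, g_dend(2.5, p), tolerance = 0.01)
  # gate open, somatic fixed point g_prop * r_dend + E - I_soma - N_th
  expect_equal(st$r_soma, st$r_dend + 1 - 0 - 1, tolerance = 0.01)
  # gate closed: soma relaxes to 0
  st2 <- list(r_dend = 2, r_soma = 1, t = 0)
  for (i in 1:100) {
    st2 <- step_dynamics(st2, list(p_dend = 2.5, E_soma = 1, I_soma = 2), p)
  }
  expect_equal(st2$r_soma, 0, tolerance = 1e-3)
  expect_error(step_dynamics(list(r_dend = NaN, r_soma = 0, t = 0),
                             list(p_dend = 0, E_soma = 0, I_soma = 0), p),
               "non-finite")
})

test_that("relaxation towards the fixed point is exponential with tau0", {
  # drive held constant; the error should decay by ~e per tau0 = 5 ms
  st <- list(r_dend = 0, r_soma = 0, t = 0)
  rstar <- g_dend(1.5, p)
  err <- numeric(30)
  for (i in 1:30) {
    st <- step_dynamics(st, list(p_dend = 1.5, E_soma = 0, I_soma = 0), p)
    err[i] <- abs(st$r_dend - rstar)
  }
  ratio <- err[10] / err[15]   # 5 ms apart
  expect_equal(log(ratio), 1, tolerance = 0.15)  # Euler discretization error
})
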