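p3 <- model_params("novel_active")   # I_dend: 0.8 -> 8.5, I_soma: 1.2 -> 0

test_that("novelty signal decays exponentially and resets", {
  sch <- novelty_schedule(tau_n = 1e5)
  expect_equal(novelty_value(0, sch), 1)
  expect_equal(novelty_value(1e5, sch), exp(-1))
  expect_equal(novelty_value(5e5, sch), exp(-5))
  schr <- novelty_schedule(tau_n = 1e5, reset_times = 2e5)
  expect_equal(novelty_value(2e5, schr), 1)
  expect_equal(novelty_value(3e5, schr), exp(-1))
  expect_equal(novelty_value(1e5, schr), exp(-1))  # before the reset
  off <- novelty_schedule(enabled = FALSE)
  expect_equal(novelty_value(c(0, 1e6), off), c(1, 1))
})

test_that("inhibition interpolates between novel and familiar levels", {
  sch <- novelty_schedule(tau_n = 1e5)
  inh0 <- inhibition_at(0, sch, p3)
  expect_equal(inh0$I_dend, 0.8)
  expect_equal(inh0$I_soma, 1.2)
  inh_inf <- inhibition_at(1e9, sch, p3)
  expect_equal(inh_inf$I_dend, 8.5, tolerance = 1e-4)
  expect_equal(inh_inf$I_soma, 0, tolerance = 1e-4)
  inh1 <- inhibition_at(1e5, sch, p3)
  expect_equal(inh1$I_dend, 8.5 - 7.7 * exp(-1), tolerance = 1e-10)
  expect_equal(inh1$I_soma, 1.2 * exp(-1), tolerance = 1e-10)
  # monotone: dendritic rising, somatic falling
  t <- seq(0, 1e6, length.out = 100)
  tr <- inhibition_at(t, sch, p3)
  expect_true(all(diff(tr$I_dend) > 0))
  expect_true(all(diff(tr$I_soma) < 0))
})

test_that("protocol currents respect lap windows and regions", {
  expect_equal(protocol_currents(10, 1, list(), 50),
               list(I_dend_ext = 0, I_soma_ext = 0, suppression = 0))
  full <- induction_protocol("somatic_current", c(0, 1), first_lap = 2,
                             n_laps = 1, amplitude = 1.5)
  expect_equal(protocol_currents(33, 2, list(full), 50)$I_soma_ext, 1.5)
  expect_equal(protocol_currents(33, 3, list(full), 50)$I_soma_ext, 0)
  # wrapped region through the 0/L seam
  wrap <- induction_protocol("dendritic_current", c(0.9, 0.1),
                             first_lap = 1, n_laps = 5, amplitude = 10)
  expect_equal(protocol_currents(46, 1, list(wrap), 50)$I_dend_ext, 10)
  expect_equal(protocol_currents(4, 1, list(wrap), 50)$I_dend_ext, 10)
  expect_equal(protocol_currents(5.1, 1, list(wrap), 50)$I_dend_ext, 0)
  expect_equal(protocol_currents(25, 1, list(wrap), 50)$I_dend_ext, 0)
  # additivity over protocols
  both <- list(full, induction_protocol("somatic_current", c(0, 1), 2, 1, 0.5))
  expect_equal(protocol_currents(10, 2, both, 50)$I_soma_ext, 2)
  # disinhibition is a multiplicative suppression, overlap rejected
  dis <- induction_protocol("dendritic_disinhibition", c(0.2, 0.4), 1, 3, 0.8)
  expect_equal(protocol_currents(15, 2, list(dis), 50)$suppression, 0.8)
  expect_error(protocol_currents(15, 2, list(dis, dis), 50), "overlap")
  expect_error(induction_protocol("dendritic_disinhibition", c(0, 1),
                                  amplitude = 2), "suppression")
})

test_that("a novelty reset restores novel-environment inhibition mid-session", {
  reset_t <- 2 * 5000  # start of lap 3
  pr <- ca1_protocol(params = p3, n_laps = 4,
                     novelty = novelty_schedule(tau_n = p3$tau_n,
                                                reset_times = reset_t),
                     weights = list(generator = "single_bump", delta = 1.2),
                     name = "reset")
  s <- run_session(pr)
  expect_equal(s$novelty[3], 1)
  expect_equal(s$I_dend[3], 0.8)
  expect_true(s$novelty[2] < 1)
})
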