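test_that("somatic current injection turns the silent cell on all-or-nothing", {
  sw <- current_injection_sweep(c(0, 0.9, 1, 1.5))
  expect_false(sw$is_place_field[1])
  expect_false(sw$is_place_field[2])   # just below the gate threshold
  expect_true(sw$is_place_field[3])
  expect_true(sw$is_place_field[4])
  # amplitude does not grow with the current once the gate is open
  expect_lt(abs(sw$field_amplitude[4] - sw$field_amplitude[3]) /
              sw$field_amplitude[3], 0.05)
})

test_that("without the gate the field amplitude grows with the current", {
  pr <- preset_protocol("familiar_injection",
          params = model_params("familiar_injection", gate_enabled = FALSE))
  amps <- seq(0, 1.5, by = 0.25)
  sw <- current_injection_sweep(amps, protocol = pr)
  on <- sw$field_amplitude > 0
  expect_true(all(diff(sw$field_amplitude[on]) > 0))
  # no single dominating jump: the transition is graded, unlike the
  # gated sweep which switches in one step
  jumps <- diff(sw$field_amplitude)
  expect_lt(max(jumps) / max(sw$field_amplitude), 0.8)
})

test_that("subthreshold somatic activity is flat for silent, tuned for place cells", {
  sw <- current_injection_sweep(c(0, 1.5))
  pr <- preset_protocol("familiar_injection")
  pr$inductions <- list(induction_protocol("somatic_current", c(0, 1),
                                           first_lap = 2, n_laps = 1,
                                           amplitude = 0))
  silent <- run_session(pr)
  cv <- sd(silent$map_sub[2, ]) / abs(mean(silent$map_sub[2, ]))
  expect_lt(cv, 1e-6)
  pr$inductions[[1]]$amplitude <- 1.5
  place <- run_session(pr)
  expect_gt(diff(range(place$map_sub[2, ])), 0.3)
})

test_that("dendritic place field precedes the somatic place field", {
  s <- run_session(preset_protocol("novel_silent", n_laps = 20))
  expect_lt(first_field_lap(s, "dendrite"), first_field_lap(s, "soma"))
})

test_that("novel vs familiar network states differ despite matched fields", {
  s <- run_session(preset_protocol("novel_active", n_laps = 100))
  expect_gt(sum(s$w_snapshots[100, ]), sum(s$w_snapshots[1, ]))
  expect_gt(s$I_dend[100], s$I_dend[1])
  expect_lt(s$I_soma[100], s$I_soma[1])
  # both laps carry a place field
  expect_true(field_metrics(s$map_soma[1, ])$is_place_field)
  expect_true(field_metrics(s$map_soma[100, ])$is_place_field)
})

test_that("induction regions sit at the antipode and wrap correctly", {
  r <- induction_region(25.5, 0.15, 50)
  expect_equal(r, c(46.75, 4.25) / 50)
  r2 <- induction_region(0, 0.2, 50)
  expect_equal(r2, c(20, 30) / 50)
})

test_that("induction-lap outcomes are monotone over the novel-environment sweep", {
  pr <- preset_protocol("novel_induction")
  res <- min_induction_laps(pr, "shifted", sweep = 3:6, first_lap = 5,
                            region_frac = 0.45)
  expect_equal(res$min_laps, 4)
  # once shifting succeeds it keeps succeeding for larger counts
  first <- which(res$outcomes)[1]
  expect_true(all(res$outcomes[first:length(res$outcomes)]))
})

test_that("dendritic disinhibition restricted to a region can move the field", {
  # familiar environment, suppression of dendritic inhibition inside a
  # region away from the field increases dendritic activity there
  pr <- preset_protocol("novel_induction")
  pr$n_laps <- 103L
  pr$inductions <- list(induction_protocol("dendritic_disinhibition",
      region = induction_region(25.5, 0.15), first_lap = 101, n_laps = 3,
      amplitude = 1))
  s <- run_session(pr)
  in_bins <- c(48:50, 1:4)
  base <- mean(s$map_pdend[100, in_bins])
  dis <- mean(s$map_pdend[101, in_bins])
  expect_gt(dis, base + 5)   # 8.5 a.u. of inhibition removed in-region
})
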