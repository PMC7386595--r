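sess <- run_session(preset_protocol("novel_active", n_laps = 2))
st1 <- session_state(sess, 1)

test_that("zero-amplitude noise leaves the state and the field unchanged", {
  for (kind in c("presyn_field", "presyn_rate", "weights")) {
    pert <- perturb_network(st1, noise_spec(kind, 0), draw = 1)
    expect_equal(pert$w, st1$w)
    expect_equal(pert$pop$gains, st1$pop$gains)
    expect_equal(pert$pop$offsets, st1$pop$offsets)
  }
  res <- stability_protocol(st1, noise_spec("weights", 0, n_samples = 3))
  expect_equal(res$mean_distance, 0)
})

test_that("noise draws follow the documented distributions", {
  # rate offsets are rectified non-negative
  off <- vapply(1:200, function(d) {
    perturb_network(st1, noise_spec("presyn_rate", 0.5, seed = 3),
                    draw = d)$pop$offsets
  }, numeric(10))
  expect_true(all(off >= 0))
  # weight noise: additive Normal(0, N^2), checked by Monte Carlo
  dw <- vapply(1:2000, function(d) {
    perturb_network(st1, noise_spec("weights", 0.1, seed = 4),
                    draw = d)$w - st1$w
  }, numeric(10))
  expect_equal(sd(as.numeric(dw)), 0.1, tolerance = 0.05)
  expect_equal(mean(as.numeric(dw)), 0, tolerance = 0.05)
  # field gains: multiplicative Normal(1, N^2)
  g <- vapply(1:2000, function(d) {
    perturb_network(st1, noise_spec("presyn_field", 0.2, seed = 5),
                    draw = d)$pop$gains
  }, numeric(10))
  expect_equal(mean(as.numeric(g)), 1, tolerance = 0.02)
  expect_equal(sd(as.numeric(g)), 0.2, tolerance = 0.05)
})

test_that("stability protocol is deterministic and plasticity-frozen", {
  spec <- noise_spec("weights", 0.1, n_samples = 5, seed = 9)
  a <- stability_protocol(st1, spec)
  b <- stability_protocol(st1, spec)
  expect_identical(a$per_sample_distances, b$per_sample_distances)
  # the probed state is untouched: weights identical before and after
  expect_identical(st1$w, session_state(sess, 1)$w)
  # a probe lap run twice from the same state is bit-identical
  expect_identical(probe_lap(st1), probe_lap(st1))
  expect_output(print(a), "stability")
})

test_that("mean field change is non-decreasing in the noise amplitude", {
  for (kind in c("presyn_field", "presyn_rate", "weights")) {
    d <- vapply(c(0, 0.05, 0.1, 0.2), function(N) {
      stability_protocol(st1, noise_spec(kind, N, n_samples = 30,
                                         seed = 21))$mean_distance
    }, numeric(1))
    expect_true(all(diff(d) >= 0), info = kind)
  }
})

test_that("a silent baseline is flagged rather than failing", {
  silent <- st1
  silent$w <- rep(0, length(silent$w))
  res <- stability_protocol(silent, noise_spec("weights", 0.05,
                                               n_samples = 2))
  expect_true(res$silent)
})

test_that("compensated manipulations preserve the field and reduce robustness", {
  full <- run_session(preset_protocol("novel_active", n_laps = 100))
  st100 <- session_state(full, 100)
  amp0 <- field_metrics(probe_lap(st100))$amplitude
  # weaker weights with compensating disinhibition: same field, more
  # sensitive to weight noise
  weak <- compensated_state(st100, "weights_down", scale = 0.6)
  expect_equal(field_metrics(probe_lap(weak))$amplitude, amp0,
               tolerance = 5e-3)
  spec3 <- noise_spec("weights", 0.3, n_samples = 40, seed = 13)
  expect_gt(stability_protocol(weak, spec3)$mean_distance,
            stability_protocol(st100, spec3)$mean_distance)
  # lower dendritic inhibition with compensating somatic inhibition:
  # same field, more sensitive to presynaptic rate noise
  leaky <- compensated_state(st100, "dend_inhibition_down", scale = 0.8)
  expect_equal(field_metrics(probe_lap(leaky))$amplitude, amp0,
               tolerance = 5e-3)
  spec2 <- noise_spec("presyn_rate", 0.5, n_samples = 40, seed = 14)
  expect_gt(stability_protocol(leaky, spec2)$mean_distance,
            stability_protocol(st100, spec2)$mean_distance)
})
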