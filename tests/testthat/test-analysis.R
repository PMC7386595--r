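test_that("rate-map binning averages within half-open bins", {
  pos <- seq(0, 50, length.out = 5001)[-5001]
  expect_equal(as.numeric(bin_rate_map(pos, rep(2, 5000), 50, 50)),
               rep(2, 50))
  ind <- as.numeric(pos < 25)
  m <- bin_rate_map(pos, ind, 50, 50)
  expect_equal(as.numeric(m), c(rep(1, 25), rep(0, 25)))
  # Gaussian-tuned activity peaks in the bin containing the center
  act <- exp(-circular_distance(pos, 17.3, 50)^2 / 50)
  m2 <- bin_rate_map(pos, act, 50, 50)
  expect_equal(which.max(m2), 18)   # bin [17, 18)
  expect_error(bin_rate_map(c(1, 2), c(1, 1), 50, 50), "empty")
})

test_that("field metrics use a decile baseline and amplitude threshold", {
  expect_false(field_metrics(rep(0, 50))$is_place_field)
  fm <- field_metrics(c(2, rep(0, 49)))
  expect_equal(fm$peak, 2)
  expect_equal(fm$baseline, 0)
  expect_equal(fm$amplitude, 2)
  expect_true(fm$is_place_field)
  # offset invariance of the amplitude
  m <- exp(-((1:50) - 20)^2 / 30)
  expect_equal(field_metrics(m)$amplitude, field_metrics(m + 5)$amplitude,
               tolerance = 1e-12)
  expect_equal(field_metrics(m, L = 50)$peak_location, 19.5)
})

test_that("field change is a scale-invariant rescaled distance", {
  m <- exp(-((1:50) - 20)^2 / 30)
  expect_equal(field_change(m, m), 0)
  expect_equal(field_change(c(0, 1, 0), c(1, 0, 0)), 2 / 3)
  expect_equal(field_change(m, 3 * m), 0)
  m2 <- exp(-((1:50) - 35)^2 / 30)
  expect_equal(field_change(m, m2), field_change(m2, m))
  expect_true(field_change(m, m2) > 0)
  z <- field_change(m, rep(0, 50))
  expect_true(isTRUE(attr(z, "zero_peak")))
  expect_equal(as.numeric(z), mean(m / max(m)))
  expect_error(field_change(1:3, 1:4), "binning")
})

test_that("block-wise spatial correlation averages within-block lap pairs", {
  one <- exp(-((1:50) - 20)^2 / 30)
  maps <- matrix(rep(one, 20), nrow = 20, byrow = TRUE)
  expect_equal(as.numeric(spatial_correlation_blocks(maps, 10)), c(1, 1))
  # alternating anti-correlated maps: brute-force over the pair list
  a <- c(rep(1, 25), rep(0, 25)); b <- c(rep(0, 25), rep(1, 25))
  alt <- matrix(rep(c(a, b), 5), nrow = 10, byrow = TRUE)
  pairs <- combn(10, 2)
  brute <- mean(apply(pairs, 2, function(ij)
    cor(alt[ij[1], ], alt[ij[2], ])))
  expect_equal(as.numeric(spatial_correlation_blocks(alt, 10)), brute)
  expect_true(brute < 0)
  # zero-variance laps are excluded and reported
  flat <- maps
  flat[3, ] <- 1
  out <- spatial_correlation_blocks(flat, 10)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("dendritic events are upward threshold crossings", {
  pars <- model_params()
  expect_length(detect_dendritic_events(rep(1.5, 100), pars), 0)
  ramp <- seq(0, 5, length.out = 100)
  expect_length(detect_dendritic_events(ramp, pars), 1)
  # square wave with k periods has exactly k events
  sq <- rep(c(rep(0, 10), rep(3, 10)), 7)
  expect_length(detect_dendritic_events(sq, pars), 7)
  # sustained supra-threshold activity is a single event
  expect_length(detect_dendritic_events(c(0, rep(3, 50)), pars), 1)
})

test_that("rate maps and lap summaries export as delimited text", {
  s <- run_session(short_active(2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_rate_maps(s, f1, "soma")
  df <- read.delim(f1)
  expect_equal(nrow(df), 2 * 50)
  expect_equal(df$activity[df$lap == 2], as.numeric(s$map_soma[2, ]))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_lap_summary(s, f2)
  df2 <- read.delim(f2)
  expect_equal(df2$mean_soma, s$mean_soma)
  expect_equal(df2$novelty, s$novelty)
})
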