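# minimal hand-built spike record for rate arithmetic
fake_record <- function(events, sizes = c(POP = 100), duration = 1000) {
  structure(list(events = events, sizes = as.list(sizes),
                 duration_ms = duration, record_window = c(0, duration),
                 dt = 0.5, seed = 0L), class = "spike_record")
}

# synthetic rate series on a 2 ms grid for the spectral oracles
fake_rate <- function(x, stride = 2, population = "POP") {
  structure(data.frame(time_ms = seq_along(x) * stride, rate_hz = x),
            population = population, window_ms = stride,
            stride_ms = stride, n_runs = 1L,
            class = c("firing_rate_series", "data.frame"))
}

test_that("firing rate implements count / T / population size", {
  # 10 spikes in one 50 ms window of a 100-neuron population -> 2 Hz
  ev <- data.frame(population = "POP", neuron = 1:10,
                   time_ms = seq(10, 40, length.out = 10))
  rec <- fake_record(ev, duration = 100)
  r <- firing_rate(rec, "POP", window_ms = 50, stride_ms = 50)
  expect_equal(r$rate_hz, c(10 / 0.05 / 100, 0))
  # raw population-summed convention via the flag
  r2 <- firing_rate(rec, "POP", window_ms = 50, stride_ms = 50,
                    per_neuron = FALSE)
  expect_equal(r2$rate_hz[1], 200)
  # empty record gives an all-zero series
  r0 <- firing_rate(fake_record(ev[0, ], duration = 100), "POP")
  expect_true(all(r0$rate_hz == 0))
  expect_error(firing_rate(rec, "NOPE"), "unknown population")
})

test_that("shifting spikes by one stride shifts the series by one index", {
  ev <- data.frame(population = "POP", neuron = 1,
                   time_ms = c(12, 110, 113, 341))
  rec <- fake_record(ev, duration = 1000)
  a <- firing_rate(rec, "POP", window_ms = 50, stride_ms = 25)
  ev2 <- transform(ev, time_ms = time_ms + 25)
  b <- firing_rate(fake_record(ev2, duration = 1000), "POP",
                   window_ms = 50, stride_ms = 25)
  n <- nrow(a)
  expect_equal(b$rate_hz[-1], a$rate_hz[-n])
})

test_that("average_rates is the pointwise mean with run bookkeeping", {
  s1 <- fake_rate(c(1, 2, 3, 4))
  s2 <- fake_rate(c(3, 2, 1, 0))
  m <- average_rates(list(s1, s2))
  expect_equal(m$rate_hz, c(2, 2, 2, 2))
  expect_equal(attr(m, "n_runs"), 2L)
  expect_equal(average_rates(list(s1))$rate_hz, s1$rate_hz)
  expect_equal(average_rates(list(s1, s1))$rate_hz, s1$rate_hz)
  expect_error(average_rates(list(s1, fake_rate(1:5))), "mismatched")
})

test_that("band classification uses half-open printed band edges", {
  expect_equal(band_of(c(4, 7.9, 8, 12.9, 13, 29.9, 30, 149)),
               c("theta", "theta", "alpha", "alpha", "beta", "beta",
                 "gamma", "gamma"))
  expect_true(is.na(band_of(2)))
  expect_true(is.na(band_of(200)))
})

test_that("spectral summary recovers known oscillations", {
  t <- seq(0, 6.998, by = 0.002)
  # constant series: no non-DC power, dominant flagged undefined
  flat <- spectral_summary(fake_rate(rep(5, length(t))))
  expect_true(is.na(flat$dominant_frequency))
  # 20 Hz sinusoid + weak noise: dominant 20 Hz, beta band
  set.seed(7)
  x20 <- 10 + 3 * sin(2 * pi * 20 * t) + rnorm(length(t), 0, 0.3)
  s20 <- spectral_summary(fake_rate(x20))
  expect_equal(s20$dominant_frequency, 20, tolerance = 0.06)
  expect_equal(s20$band, "beta")
  expect_gt(s20$band_power_fraction, 0.5)
  # 6 Hz and 40 Hz mixture with 4:1 power: theta dominates, and the
  # band-power ratio reproduces the 4:1 construction
  x <- 10 + 2 * sin(2 * pi * 6 * t) + 1 * sin(2 * pi * 40 * t)
  sm <- spectral_summary(fake_rate(x))
  expect_equal(sm$dominant_frequency, 6, tolerance = 0.06)
  expect_equal(sm$band, "theta")
  theta_p <- sum(sm$power_histogram[sm$frequencies >= 4 &
                                      sm$frequencies < 8])
  gamma_p <- sum(sm$power_histogram[sm$frequencies >= 30 &
                                      sm$frequencies < 150])
  expect_equal(theta_p / gamma_p, 4, tolerance = 0.25)
})

test_that("power histogram satisfies Parseval within estimator tolerance", {
  set.seed(11)
  x <- 5 + as.numeric(arima.sim(list(ar = 0.6), 3500))
  sm <- spectral_summary(fake_rate(x))
  expect_equal(sum(sm$power_histogram[-1]), var(x), tolerance = 0.3)
})

test_that("spectral analysis refuses a stride above Nyquist needs", {
  r <- fake_rate(rep(1, 300), stride = 50)
  expect_error(spectral_summary(r), "Nyquist|caps analysis")
})

test_that("synchrony index behaves at its extremes", {
  # all neurons spiking at identical times: index 1
  ev <- data.frame(population = "POP",
                   neuron = rep(1:20, times = 10),
                   time_ms = rep(seq(50, 950, by = 100), each = 20))
  rec <- fake_record(ev, sizes = c(POP = 20))
  expect_equal(as.numeric(synchrony_index(rec, "POP")), 1)
  # independent Poisson trains: near zero
  set.seed(3)
  ev2 <- data.frame(population = "POP",
                    neuron = sample(1:50, 4000, TRUE),
                    time_ms = runif(4000, 0, 5000))
  rec2 <- fake_record(ev2, sizes = c(POP = 50), duration = 5000)
  expect_lt(abs(as.numeric(synchrony_index(rec2, "POP"))), 0.02)
  # perfect anti-phase two-group firing: negative raw, clipped to 0
  ta <- seq(25, 975, by = 100)
  ev3 <- data.frame(population = "POP",
                    neuron = c(rep(1, 10), rep(2, 10)),
                    time_ms = c(ta, ta + 50))
  rec3 <- fake_record(ev3, sizes = c(POP = 2))
  s3 <- synchrony_index(rec3, "POP", bin_ms = 50)
  expect_equal(as.numeric(s3), 0)
  expect_lt(attr(s3, "raw"), 0)
  # a silent population is flagged undefined, not zero
  expect_true(is.na(synchrony_index(fake_record(ev[0, ],
                                                sizes = c(POP = 5)),
                                    "POP")))
})

test_that("burst statistics find runs of short ISIs after silence", {
  ev <- data.frame(population = "POP", neuron = 1,
                   time_ms = c(100, 110, 120, 500, 900, 905, 910, 915))
  rec <- fake_record(ev, sizes = c(POP = 3))
  b <- burst_stats(rec, "POP", max_isi_ms = 25, min_gap_ms = 50)
  expect_equal(b$max_burst_len, 4L)
  expect_equal(b$n_rebound_bursts, 2L)
  none <- burst_stats(fake_record(ev[0, ], sizes = c(POP = 3)), "POP")
  expect_equal(none$max_burst_len, 0L)
})

test_that("PDC columns are normalised and white noise shows no coupling", {
  set.seed(13)
  x <- fake_rate(rnorm(2000), population = "A")
  y <- fake_rate(rnorm(2000), population = "B")
  vp <- var_pdc(list(x, y), model_order = 5,
                freqs_hz = seq(1, 100, by = 5))
  colsum <- apply(vp$pdc^2, c(1, 3), sum)
  expect_equal(as.numeric(colsum), rep(1, length(colsum)),
               tolerance = 1e-10)
  offdiag <- c(vp$pdc[, 1, 2], vp$pdc[, 2, 1])
  expect_lt(max(offdiag), 0.25)
})

test_that("PDC recovers directionality of a constructed VAR(1)", {
  set.seed(17)
  n <- 3000
  x <- rnorm(n)
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.8 * x[t - 1] + 0.3 * rnorm(1)
  vp <- var_pdc(list(fake_rate(x, population = "X"),
                     fake_rate(y, population = "Y")),
                model_order = 3, freqs_hz = seq(1, 100, by = 3))
  # influence X -> Y dominates Y -> X at every frequency
  expect_true(all(vp$pdc[, 2, 1] > vp$pdc[, 1, 2]))
  expect_true(all(vp$gpdc[, 2, 1] > vp$gpdc[, 1, 2]))
  expect_equal(unname(vp$populations), c("X", "Y"))
})
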