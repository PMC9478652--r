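# Filters (analytic response + simulation) and sliding-window segmentation.

test_that("notch filter removes 50 Hz and passes 200 Hz", {
  # analytic zero-phase response of the designed filter
  expect_lt(filter_response(50, 1000, which = "notch"), 0.01)
  expect_gt(filter_response(200, 1000, which = "notch"), 0.95)
  expect_lt(filter_response(200, 1000, which = "notch"), 1.05)

  # steady-state simulation on tones (middle section avoids edge transients)
  t <- (0:1999) / 1000
  mid <- 500:1500
  rms <- function(x) sqrt(mean(x^2))
  y50 <- notch_filter(sin(2 * pi * 50 * t), 1000)
  expect_lt(rms(y50[mid]) / rms(sin(2 * pi * 50 * t)[mid]), 0.1)
  y200 <- notch_filter(sin(2 * pi * 200 * t), 1000)
  expect_lt(abs(rms(y200[mid]) / rms(sin(2 * pi * 200 * t)[mid]) - 1), 0.05)
  expect_equal(notch_filter(numeric(2000), 1000), numeric(2000))
})

test_that("band-pass filter rejects DC and preserves the 10-400 Hz band", {
  expect_lt(filter_response(0, 1000, which = "bandpass"), 0.01)
  expect_gt(filter_response(100, 1000, which = "bandpass"), 0.95)
  t <- (0:1999) / 1000
  mid <- 500:1500
  rms <- function(x) sqrt(mean(x^2))
  ydc <- bandpass_filter(rep(1, 2000), 1000)
  expect_lt(max(abs(ydc[mid])), 0.01)
  y100 <- bandpass_filter(sin(2 * pi * 100 * t), 1000)
  expect_lt(abs(rms(y100[mid]) / rms(sin(2 * pi * 100 * t)[mid]) - 1), 0.05)
  expect_equal(bandpass_filter(numeric(2000), 1000), numeric(2000))
  expect_error(bandpass_filter(rnorm(2000), 700), "Nyquist")
  expect_error(notch_filter(rnorm(3), 1000), "warm-up")
})

test_that("filters are linear and length-preserving", {
  set.seed(21)
  x <- rnorm(2000); y <- rnorm(2000)
  for (f in list(notch_filter, bandpass_filter)) {
    lhs <- f(2 * x + 3 * y, 1000)
    rhs <- 2 * f(x, 1000) + 3 * f(y, 1000)
    expect_length(lhs, 2000)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("preprocess_epoch suppresses 50 Hz relative to in-band content", {
  t <- (0:1999) / 1000
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 100 * t)
  ep <- structure(list(samples = matrix(rep(x, 2), nrow = 2, byrow = TRUE),
                       fs = 1000, label = 0L, subject = 1L, session = 1L),
                  class = "semg_epoch")
  out <- preprocess_epoch(ep)
  expect_identical(dim(out$samples), dim(ep$samples))
  y <- out$samples[1, 500:1500]
  pg <- Mod(stats::fft(y - mean(y)))[1:500]^2
  f <- (0:499) * 1000 / length(y)
  p50 <- max(pg[f >= 45 & f <= 55])
  p100 <- max(pg[f >= 95 & f <= 105])
  expect_gt(10 * log10(p100 / p50), 20)

  # zeros map to zeros; metadata preserved
  ep$samples[] <- 0
  z <- preprocess_epoch(ep)
  expect_true(all(z$samples == 0))
  expect_identical(z$label, 0L)

  # idempotence in the passband: filtering twice changes an in-band tone
  # by less than 10% RMS
  tone <- sin(2 * pi * 100 * t)
  ep1 <- structure(list(samples = matrix(tone, nrow = 1), fs = 1000,
                        label = 0L, subject = 1L, session = 1L),
                   class = "semg_epoch")
  once <- preprocess_epoch(ep1)$samples[1, ]
  twice <- preprocess_epoch(structure(list(samples = matrix(once, nrow = 1),
                                           fs = 1000, label = 0L,
                                           subject = 1L, session = 1L),
                                      class = "semg_epoch"))$samples[1, ]
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(twice[500:1500]) / rms(once[500:1500]) - 1), 0.1)
})

test_that("trim_and_window reproduces the 32-window protocol arithmetic", {
  x <- rnorm(2000)
  w <- trim_and_window(x, 1000)
  expect_identical(dim(w), c(32L, 200L))
  # windows are views: first window starts right after the 250 ms trim
  expect_equal(w[1, ], x[251:450])
  expect_equal(w[2, ], x[301:500])

  expect_identical(dim(trim_and_window(rnorm(200), 1000,
                                       window_plan(trim_ms = 0))),
                   c(1L, 200L))
  expect_error(trim_and_window(rnorm(449), 1000), "too short")
})

test_that("window count formula matches brute-force enumeration", {
  brute_count <- function(n, trim, win, hop) {
    k <- 0; s <- trim
    while (s + win <= n) { k <- k + 1; s <- s + hop }
    k
  }
  set.seed(33)
  for (i in 1:200) {
    win <- sample(5:50, 1)
    hop <- sample(1:win, 1)
    trim <- sample(0:30, 1)
    n <- trim + win + sample(0:200, 1)
    plan <- window_plan(win_ms = win, hop_ms = hop, trim_ms = trim)
    got <- nrow(trim_and_window(rnorm(n), 1000, plan))
    expect_identical(got, as.integer(brute_count(n, trim, win, hop)))
  }
})
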