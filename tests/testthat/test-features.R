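# Feature extractors against independent brute-force oracles.

test_that("time-domain features match their defining sums", {
  expect_equal(mav(rep(3, 10)), 3)
  expect_equal(mav(rep(c(2, -2), 100)), 2)
  expect_equal(emg_var(rep(5, 64)), 0)
  expect_equal(emg_var(rep(c(1, -1), 100)), 1)
  expect_equal(emg_rms(rep(-2, 10)), 2)
  expect_equal(mwl(rep(7, 32)), 0)
  # alternating +/-1 over W = 200: 199 unit-steps of size 2 over W
  expect_equal(mwl(rep(c(1, -1), 100)), 1.99)

  set.seed(101)
  for (i in 1:200) {
    x <- runif(200, -5, 5)
    W <- length(x)
    expect_equal(mav(x), sum(abs(x)) / W, tolerance = 1e-12)
    expect_equal(emg_var(x), sum((x - sum(x) / W)^2) / W, tolerance = 1e-12)
    expect_equal(emg_rms(x), sqrt(sum(x^2) / W), tolerance = 1e-12)
    expect_equal(mwl(x), sum(abs(x[-1] - x[-W])) / W, tolerance = 1e-12)
    # population-variance identity
    expect_equal(emg_rms(x)^2, emg_var(x) + mean(x)^2, tolerance = 1e-10)
  }
})

test_that("time-domain features are scale-covariant", {
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(200); c0 <- runif(1, -4, 4)
    expect_equal(mav(c0 * x), abs(c0) * mav(x))
    expect_equal(emg_rms(c0 * x), abs(c0) * emg_rms(x))
    expect_equal(emg_var(c0 * x), c0^2 * emg_var(x))
    expect_equal(mwl(c0 * x), abs(c0) * mwl(x))
  }
})

test_that("periodogram PSD locates tones and satisfies Parseval", {
  t <- (0:199) / 1000
  psd <- estimate_psd(sin(2 * pi * 100 * t), 1000)
  expect_true(all(psd$P >= 0))
  expect_true(all(diff(psd$f) > 0))
  expect_equal(psd$f[which.max(psd$P)], 100)
  expect_true(all(estimate_psd(numeric(200), 1000)$P == 0))
  expect_error(estimate_psd(rnorm(3), 1000), "short")

  # total PSD ~ population variance for broadband input
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(200)
    expect_equal(sum(estimate_psd(x, 1000)$P), emg_var(x), tolerance = 0.05)
  }

  # white noise: averaged spectrum is flat (no bin exceeds 10x the median)
  set.seed(10)
  acc <- 0
  for (i in 1:100) acc <- acc + estimate_psd(rnorm(200), 1000)$P
  expect_lt(max(acc[-1]), 10 * median(acc[-1]))  # drop the demeaned DC bin
})

test_that("mean and median frequency match periodogram oracles", {
  t <- (0:199) / 1000
  binw <- 1000 / 200
  tone <- sin(2 * pi * 100 * t)
  expect_lt(abs(mnf(tone, 1000) - 100), binw)
  expect_equal(mdf(tone, 1000), 100)

  two <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  expect_lt(abs(mnf(two, 1000) - 200), binw)
  m <- mdf(two, 1000)
  expect_gte(m, 100); expect_lte(m, 300)

  expect_error(mnf(numeric(200), 1000), "zero-power")
  expect_error(mdf(numeric(200), 1000), "zero-power")

  # oracle cross-check on random windows: centroid and cumulative median
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(200)
    psd <- estimate_psd(x, 1000)
    expect_equal(mnf(x, 1000), sum(psd$f * psd$P) / sum(psd$P))
    expect_equal(mdf(x, 1000),
                 psd$f[min(which(cumsum(psd$P) >= sum(psd$P) / 2))])
    # the median splits power into halves up to one bin's worth
    below <- sum(psd$P[psd$f <= mdf(x, 1000)])
    above <- sum(psd$P[psd$f > mdf(x, 1000)])
    expect_lte(abs(below - above), 2 * max(psd$P))
  }
})

test_that("TD4 and TFD6 stack per-window features in the documented order", {
  sp <- synthetic_spec(n_classes = 3, seed = 14)
  ds <- generate_dataset(sp, subjects = 1)
  ep <- preprocess_epoch(semgssr:::dataset_epoch(ds, 2))

  td <- extract_epoch_features(ep, "TD4")
  expect_identical(dim(unclass(td)), c(6L, 32L, 4L))
  tf <- extract_epoch_features(ep, "TFD6")
  expect_identical(dim(unclass(tf)), c(6L, 32L, 6L))
  expect_equal(tf[, , 1:4], td[, , 1:4])

  # every cell equals the corresponding single-feature call
  wins <- trim_and_window(ep$samples[3, ], ep$fs)
  for (k in c(1, 17, 32)) {
    expect_equal(td[3, k, 1], mav(wins[k, ]))
    expect_equal(td[3, k, 2], emg_var(wins[k, ]))
    expect_equal(td[3, k, 3], emg_rms(wins[k, ]))
    expect_equal(td[3, k, 4], mwl(wins[k, ]))
    expect_equal(tf[3, k, 5], mnf(wins[k, ], ep$fs))
    expect_equal(tf[3, k, 6], mdf(wins[k, ], ep$fs))
  }

  # zero-power windows yield the 0 sentinel (with a warning), not an error
  expect_warning(semgssr:::tfd6_windows(matrix(0, 1, 200), 1000),
                 "zero-power")
  zep <- ep; zep$samples[] <- 0
  ztf <- suppressWarnings(extract_epoch_features(zep, "TFD6"))
  expect_true(all(ztf[, , 5:6] == 0))

  zt <- extract_epoch_features(zep, "TD4")
  expect_true(all(zt == 0))
})

test_that("STFT spectrogram concentrates tone energy at the right bin", {
  n <- 1750
  t <- (0:(n - 1)) / 1000
  cfg <- stft_config()
  S <- stft_feature(sin(2 * pi * 100 * t), 1000, cfg)
  expect_identical(dim(S), c(36L, 101L))
  freq <- attr(S, "freq")
  bin100 <- which.min(abs(freq - 100))
  am <- apply(S, 1, which.max)
  # interior frames peak exactly at the tone bin; the two boundary frames
  # see the reflection discontinuity and may shift by one bin
  expect_true(all(am[2:35] == bin100))
  expect_true(all(abs(am - bin100) <= 1))
  # >= 90% of total energy within +/- 2 bins of the tone
  e_tot <- sum(S^2)
  e_loc <- sum(S[, (bin100 - 2):(bin100 + 2)]^2)
  expect_gt(e_loc / e_tot, 0.9)
  expect_true(all(stft_feature(numeric(n), 1000, cfg) == 0))
})

test_that("MFSC matches a from-scratch STFT -> Mel -> log oracle", {
  cfg <- stft_config()
  n <- 1750
  fs <- 1000

  # independent oracle: explicit DFT by cosine/sine sums, hand-built
  # triangular filters on the HTK Mel scale
  oracle_mfsc <- function(x) {
    pad <- 100
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    w <- 0.5 - 0.5 * cos(2 * pi * (0:199) / 200)
    mel <- function(f) 2595 * log10(1 + f / 700)
    imel <- function(m) 700 * (10^(m / 2595) - 1)
    edges <- imel(seq(mel(0), mel(fs / 2), length.out = 38))
    fbin <- (0:100) * fs / 200
    fb <- sapply(seq_len(36), function(m) {
      pmax(0, pmin((fbin - edges[m]) / (edges[m + 1] - edges[m]),
                   (edges[m + 2] - fbin) / (edges[m + 2] - edges[m + 1])))
    })  # bins x mels
    out <- matrix(0, 36, 36)
    for (i in 0:35) {
      fr <- xp[(i * 50 + 1):(i * 50 + 200)] * w
      k <- 0:199
      P <- vapply(0:100, function(b)
        sum(fr * cos(2 * pi * b * k / 200))^2 +
          sum(fr * sin(2 * pi * b * k / 200))^2, numeric(1))
      out[i + 1, ] <- log(as.numeric(P %*% fb) + 1e-10)
    }
    out
  }

  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(n)
    expect_equal(unclass(mfsc(x, fs, cfg)), oracle_mfsc(x),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }

  # shape, zero floor, tone localization in Mel space
  M <- mfsc(numeric(n), fs, cfg)
  expect_identical(dim(M), c(36L, 36L))
  expect_true(all(M == log(cfg$log_floor)))

  tone <- sin(2 * pi * 300 * (0:(n - 1)) / fs)
  Mt <- mfsc(tone, fs, cfg)
  centers <- attr(Mt, "center")
  amel <- apply(Mt, 1, which.max)
  band300 <- which.min(abs(centers - 300))
  # frames whose 200-sample window lies fully inside the signal are exact
  expect_true(all(amel[3:34] == band300))
  expect_true(all(abs(amel - band300) <= 1))

  expect_error(mfsc(rnorm(n), fs, stft_config(fft_len = 64, n_mels = 36)),
               "resolution")
})

test_that("MFCC stacks DCT-II cepstra with vanishing deltas for stationary input", {
  cfg <- stft_config()
  n <- 1750
  C <- mfcc(sin(2 * pi * 120 * (0:(n - 1)) / 1000), 1000, cfg)
  expect_identical(dim(C), c(36L, 36L))

  # tone frames are identical after centered framing of a periodic signal?
  # use a genuinely stationary (constant) signal instead: all frames equal
  Cc <- mfcc(rep(0.7, n), 1000, cfg)
  expect_true(all(abs(Cc[, 13:36]) < 1e-10))

  # cepstral block equals a direct DCT-II of the 12-filter log Mel energies
  set.seed(81)
  x <- rnorm(n)
  cfg12 <- cfg; cfg12$n_mels <- 12L
  logmel <- unclass(mfsc(x, 1000, cfg12))
  oracle_cep <- matrix(0, 36, 12)
  for (r in 0:11) {
    scale <- if (r == 0) sqrt(1 / 12) else sqrt(2 / 12)
    for (fidx in 1:36)
      oracle_cep[fidx, r + 1] <- scale *
        sum(logmel[fidx, ] * cos(pi * r * (2 * (0:11) + 1) / 24))
  }
  expect_equal(mfcc(x, 1000, cfg)[, 1:12], oracle_cep, tolerance = 1e-10)
})

test_that("extract_epoch_features produces the per-method tensor shapes", {
  sp <- synthetic_spec(n_classes = 3, seed = 15)
  ep <- semgssr:::dataset_epoch(generate_dataset(sp, subjects = 1), 2)
  shapes <- list(MAV = c(6L, 32L, 1L), VAR = c(6L, 32L, 1L),
                 RMS = c(6L, 32L, 1L), MWL = c(6L, 32L, 1L),
                 TD4 = c(6L, 32L, 4L), TFD6 = c(6L, 32L, 6L),
                 STFT = c(6L, 36L, 101L), MFCC = c(6L, 36L, 36L),
                 MFSC = c(6L, 36L, 36L))
  for (m in names(shapes))
    expect_identical(dim(unclass(extract_epoch_features(ep, m))), shapes[[m]])
  expect_error(extract_epoch_features(ep, "WAVELET"), "unknown feature method")
})
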