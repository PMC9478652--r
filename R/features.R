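# Feature extraction: four sliding-window time-domain features (MAV, VAR,
# RMS, MWL), two frequency-domain features (MNF, MDF) from a Hann-tapered
# periodogram, their TD4/TFD6 stacks, and three spectral representations
# (STFT magnitude spectrogram, MFSC log Mel-filterbank energies, MFCC
# cepstra with delta and delta-delta blocks).

#' Mean absolute value of a window
#'
#' `MAV = (1/W) * sum(|x_i|)` — the overall level of muscle activity in the
#' window.
#' @param x numeric window of W samples.
#' @return non-negative scalar.
#' @export
mav <- function(x) mean(abs(x))

#' Population variance of a window
#'
#' `VAR = (1/W) * sum((x_i - mean(x))^2)`. Note the population convention
#' (divide by W, not W-1).
#' @inheritParams mav
#' @return non-negative scalar.
#' @export
emg_var <- function(x) mean((x - mean(x))^2)

#' Root mean square of a window
#'
#' `RMS = sqrt((1/W) * sum(x_i^2))` — relates to the average power of the
#' movement. Satisfies `rms^2 = var + mean^2` exactly under the population
#' variance convention.
#' @inheritParams mav
#' @return non-negative scalar.
#' @export
emg_rms <- function(x) sqrt(mean(x^2))

#' Mean waveform length of a window
#'
#' `MWL = (1/W) * sum_{i=1}^{W-1} |x_{i+1} - x_i|` — W-1 first differences
#' normalized by W (not W-1), measuring signal complexity.
#' @inheritParams mav
#' @return non-negative scalar.
#' @export
mwl <- function(x) sum(abs(diff(x))) / length(x)

#' One-sided periodogram power spectral density of a window
#'
#' Demeans the window, applies a Hann taper, and returns the one-sided
#' periodogram renormalized so that the summed PSD equals the window's
#' population variance exactly (discrete Parseval; the taper's random
#' energy weighting is divided out). A single tapered periodogram is used
#' rather than Welch averaging because the windows are short.
#'
#' @param x numeric window (length >= 4).
#' @param fs sampling rate in Hz.
#' @return list with `f` (Hz, from 0 to fs/2) and `P` (non-negative PSD
#'   values, same length).
#' @export
estimate_psd <- function(x, fs) {
  W <- length(x)
  if (W < 4) stop("window too short for a PSD estimate")
  w <- hann_window(W)
  y <- (x - mean(x)) * w
  Y <- stats::fft(y)
  two_sided <- Mod(Y)^2 / (W * sum(w^2))
  half <- floor(W / 2)
  P <- two_sided[1:(half + 1)]
  # fold negative frequencies onto positive ones (skip DC and Nyquist)
  if (half >= 2) {
    idx <- 2:(half + if (W %% 2 == 0) 0 else 1)
    P[idx] <- P[idx] + two_sided[W + 2 - idx]
  }
  tot <- sum(P)
  if (tot > 0) P <- P * (mean((x - mean(x))^2) / tot)
  list(f = (0:half) * fs / W, P = P)
}

#' Mean (centroid) frequency of a window's PSD
#'
#' `MNF = sum(f_i * P_i) / sum(P_i)` over the periodogram grid.
#' @inheritParams estimate_psd
#' @return frequency in Hz.
#' @export
mnf <- function(x, fs) {
  psd <- estimate_psd(x, fs)
  tot <- sum(psd$P)
  if (tot <= 0) stop("zero-power window: mean frequency undefined")
  sum(psd$f * psd$P) / tot
}

#' Median frequency of a window's PSD
#'
#' The smallest grid frequency at which cumulative power reaches half of
#' the total power, i.e. the frequency dividing the PSD into two equal
#' parts (up to discretization).
#' @inheritParams estimate_psd
#' @return frequency in Hz.
#' @export
mdf <- function(x, fs) {
  psd <- estimate_psd(x, fs)
  tot <- sum(psd$P)
  if (tot <= 0) stop("zero-power window: median frequency undefined")
  psd$f[which(cumsum(psd$P) >= tot / 2)[1]]
}

# Apply the four time-domain features to a window matrix (rows = windows).
td4_windows <- function(wins) {
  cbind(MAV = apply(wins, 1, mav),
        VAR = apply(wins, 1, emg_var),
        RMS = apply(wins, 1, emg_rms),
        MWL = apply(wins, 1, mwl))
}

tfd6_windows <- function(wins, fs) {
  td <- td4_windows(wins)
  freq <- t(apply(wins, 1, function(w) {
    psd <- estimate_psd(w, fs)
    tot <- sum(psd$P)
    if (tot <= 0) {
      warning("zero-power window: substituting 0 for MNF/MDF")
      c(0, 0)
    } else {
      c(sum(psd$f * psd$P) / tot, psd$f[which(cumsum(psd$P) >= tot / 2)[1]])
    }
  }))
  colnames(freq) <- c("MNF", "MDF")
  cbind(td, freq)
}

#' Short-time Fourier transform configuration
#'
#' @param fft_len FFT window length in samples (default 200).
#' @param hop hop between frame centers in samples (default 50).
#' @param n_mels number of triangular Mel filters for MFSC (default 36).
#' @param n_coeff number of cepstral coefficients for MFCC (default 12;
#'   the MFCC matrix stacks coefficients, deltas and delta-deltas).
#' @param log_floor additive floor inside the logarithm (default 1e-10).
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(fft_len = 200, hop = 50, n_mels = 36, n_coeff = 12,
                        log_floor = 1e-10) {
  stopifnot(fft_len > 0, hop > 0, hop <= fft_len, n_mels >= 1, n_coeff >= 1,
            log_floor > 0)
  structure(list(fft_len = as.integer(fft_len), hop = as.integer(hop),
                 n_mels = as.integer(n_mels), n_coeff = as.integer(n_coeff),
                 log_floor = log_floor), class = "stft_config")
}

# Centered framing with reflect padding: frame i (0-based) is centered on
# sample i*hop, n_frames = 1 + floor(L / hop). On a 1,750-sample
# reaction-trimmed channel with hop 50 this gives exactly 36 frames.
frame_signal <- function(x, cfg) {
  L <- length(x)
  pad <- cfg$fft_len %/% 2
  xp <- reflect_pad(x, pad)
  n_frames <- 1 + floor(L / cfg$hop)
  out <- matrix(0, nrow = n_frames, ncol = cfg$fft_len)
  for (i in seq_len(n_frames)) {
    s <- (i - 1) * cfg$hop
    out[i, ] <- xp[(s + 1):(s + cfg$fft_len)]
  }
  out
}

# Hann-windowed one-sided spectrogram; value = "magnitude" or "power".
spectrogram <- function(x, cfg, value = "magnitude") {
  frames <- frame_signal(x, cfg)
  w <- hann_window(cfg$fft_len)
  half <- cfg$fft_len %/% 2
  Y <- t(apply(frames, 1, function(fr) {
    sp <- Mod(stats::fft(fr * w))[1:(half + 1)]
    if (value == "power") sp^2 else sp
  }))
  Y
}

#' STFT magnitude spectrogram of one channel
#'
#' Hann-windowed, centered (reflect-padded) short-time Fourier transform of
#' an already reaction-trimmed channel signal.
#'
#' @param x numeric channel signal (already trimmed).
#' @param fs sampling rate in Hz.
#' @param cfg an [stft_config()].
#' @return `frames x bins` magnitude matrix; bin frequencies in Hz are
#'   attached as attribute `"freq"`.
#' @export
stft_feature <- function(x, fs, cfg = stft_config()) {
  S <- spectrogram(x, cfg, value = "magnitude")
  attr(S, "freq") <- (0:(cfg$fft_len %/% 2)) * fs / cfg$fft_len
  S
}

# HTK-style Mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filter bank
#'
#' `n_mels` unit-height triangular filters spanning 0 to fs/2 on the
#' HTK Mel scale, sampled on the one-sided FFT bin grid.
#'
#' @param n_mels number of filters.
#' @param fft_len FFT length in samples.
#' @param fs sampling rate in Hz.
#' @return `n_mels x bins` filter matrix; filter center frequencies in Hz
#'   are attached as attribute `"center"`.
#' @export
mel_filterbank <- function(n_mels, fft_len, fs) {
  n_bins <- fft_len %/% 2 + 1
  if (n_mels + 2 > n_bins)
    stop("n_mels exceeds the FFT frequency resolution")
  f_bins <- (0:(n_bins - 1)) * fs / fft_len
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2),
                         length.out = n_mels + 2))
  fb <- matrix(0, nrow = n_mels, ncol = n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f_bins - lo) / (mid - lo)
    down <- (hi - f_bins) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center") <- edges[2:(n_mels + 1)]
  fb
}

#' MFSC features of one channel
#'
#' Log Mel-filterbank energies: power spectrogram -> triangular Mel filter
#' averaging -> log with an additive floor. With the defaults on a
#' 1,750-sample trimmed channel the result is 36 frames x 36 Mel bands.
#'
#' @inheritParams stft_feature
#' @return `frames x n_mels` matrix of log Mel energies; filter centers
#'   (Hz) attached as attribute `"center"`.
#' @export
mfsc <- function(x, fs, cfg = stft_config()) {
  P <- spectrogram(x, cfg, value = "power")
  fb <- mel_filterbank(cfg$n_mels, cfg$fft_len, fs)
  M <- log(P %*% t(fb) + cfg$log_floor)
  attr(M, "center") <- attr(fb, "center")
  M
}

# DCT-II (orthonormal) matrix, k coefficients from n inputs.
dct2_matrix <- function(k, n) {
  D <- outer(0:(k - 1), 0:(n - 1),
             function(r, c) cos(pi * r * (2 * c + 1) / (2 * n)))
  D <- D * sqrt(2 / n)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

# Centered regression deltas over frames (rows), half-window N = 2,
# edge frames replicated.
delta_frames <- function(M, N = 2) {
  n <- nrow(M)
  idx <- function(i) pmin(pmax(i, 1), n)
  num <- 0
  for (d in seq_len(N)) num <- num + d * (M[idx(seq_len(n) + d), , drop = FALSE] -
                                          M[idx(seq_len(n) - d), , drop = FALSE])
  num / (2 * sum(seq_len(N)^2))
}

#' MFCC features of one channel
#'
#' DCT-II of the log Mel energies from `n_coeff` Mel filters, stacked with
#' first- and second-order delta blocks: each frame carries
#' `[coefficients, deltas, delta-deltas]`, giving 36 values per frame at
#' the defaults (12 + 12 + 12) over 36 frames.
#'
#' @inheritParams stft_feature
#' @return `frames x (3 * n_coeff)` matrix.
#' @export
mfcc <- function(x, fs, cfg = stft_config()) {
  cfg_c <- cfg
  cfg_c$n_mels <- cfg$n_coeff  # one Mel filter per retained coefficient
  logmel <- mfsc(x, fs, cfg_c)
  D <- dct2_matrix(cfg$n_coeff, cfg$n_coeff)
  cep <- logmel %*% t(D)
  d1 <- delta_frames(cep)
  d2 <- delta_frames(d1)
  cbind(cep, d1, d2)
}

#' Extract a feature tensor from one epoch
#'
#' Orchestrates preprocessing-independent feature extraction for a single
#' epoch: time/frequency-domain methods are computed on the trimmed,
#' sliding-windowed signal; spectral methods on the trimmed signal
#' directly. Channel order is preserved.
#'
#' @param epoch a `semg_epoch` (normally already preprocessed).
#' @param method one of `"MAV"`, `"VAR"`, `"RMS"`, `"MWL"`, `"TD4"`,
#'   `"TFD6"`, `"STFT"`, `"MFCC"`, `"MFSC"`.
#' @param plan a [window_plan()] (the trim also applies to spectral
#'   methods).
#' @param cfg an [stft_config()] for the spectral methods.
#' @return a 3-D array `channels x d1 x d2` of class `feature_tensor` with
#'   attribute `method`; e.g. `6 x 32 x 4` for TD4 and `6 x 36 x 36` for
#'   MFSC at the defaults.
#' @export
extract_epoch_features <- function(epoch, method,
                                   plan = window_plan(),
                                   cfg = stft_config()) {
  stopifnot(inherits(epoch, "semg_epoch"))
  method <- toupper(method)
  known <- c("MAV", "VAR", "RMS", "MWL", "TD4", "TFD6", "STFT", "MFCC", "MFSC")
  if (!method %in% known)
    stop("unknown feature method: ", method)
  nch <- nrow(epoch$samples)
  per_channel <- lapply(seq_len(nch), function(ch) {
    x <- epoch$samples[ch, ]
    if (method %in% c("MAV", "VAR", "RMS", "MWL", "TD4", "TFD6")) {
      wins <- trim_and_window(x, epoch$fs, plan)
      switch(method,
             MAV = matrix(apply(wins, 1, mav), ncol = 1),
             VAR = matrix(apply(wins, 1, emg_var), ncol = 1),
             RMS = matrix(apply(wins, 1, emg_rms), ncol = 1),
             MWL = matrix(apply(wins, 1, mwl), ncol = 1),
             TD4 = td4_windows(wins),
             TFD6 = tfd6_windows(wins, epoch$fs))
    } else {
      trim <- plan_samples(plan, epoch$fs)$trim
      xt <- if (trim > 0) x[-seq_len(trim)] else x
      switch(method,
             STFT = unclass(stft_feature(xt, epoch$fs, cfg)),
             MFSC = unclass(mfsc(xt, epoch$fs, cfg)),
             MFCC = unclass(mfcc(xt, epoch$fs, cfg)))
    }
  })
  d <- dim(per_channel[[1]])
  out <- array(0, dim = c(nch, d[1], d[2]))
  for (ch in seq_len(nch)) out[ch, , ] <- per_channel[[ch]]
  structure(out, method = method, class = "feature_tensor")
}

#' Extract features for every epoch of a dataset
#'
#' @param dataset a `semg_dataset`.
#' @param method see [extract_epoch_features()].
#' @param plan a [window_plan()].
#' @param cfg an [stft_config()].
#' @return an object of class `feature_set`: list with `x` (array
#'   `n x channels x d1 x d2`), `labels`, `subjects`, `sessions`,
#'   `method`, `n_classes`.
#' @export
extract_features <- function(dataset, method, plan = window_plan(),
                             cfg = stft_config()) {
  stopifnot(inherits(dataset, "semg_dataset"))
  n <- dim(dataset$epochs)[1]
  first <- extract_epoch_features(dataset_epoch(dataset, 1), method, plan, cfg)
  d <- dim(first)
  x <- array(0, dim = c(n, d[1], d[2], d[3]))
  x[1, , , ] <- first
  if (n > 1) for (i in 2:n)
    x[i, , , ] <- extract_epoch_features(dataset_epoch(dataset, i), method,
                                         plan, cfg)
  structure(list(x = x, labels = dataset$labels, subjects = dataset$subjects,
                 sessions = dataset$sessions, method = toupper(method),
                 n_classes = length(dataset$class_names)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<feature_set> method %s: %d epochs x %d channels x %d x %d\n",
              x$method, d[1], d[2], d[3], d[4]))
  invisible(x)
}
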