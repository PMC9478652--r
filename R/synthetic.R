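# Synthetic multichannel sEMG generator.
#
# Emulates a phrase-reading acquisition protocol: a fixed set of utterance
# classes, each repeated once per session over several sessions per subject,
# recorded from six speech-related muscles at 1 kHz for 2 s per utterance.
# Every epoch is amplitude-modulated band-limited noise (the sEMG carrier)
# plus the artifacts the preprocessing stage must remove: a per-channel DC
# offset, 50 Hz powerline interference with random phase, and white sensor
# noise. Class identity lives entirely in the per-channel activation
# envelopes; a `separation` dial scales how far class envelopes lie apart.

#' Specification of a synthetic sEMG dataset
#'
#' Collects every generative parameter of the synthetic corpus. The defaults
#' mirror the acquisition protocol the pipeline targets: 101 classes (100
#' phrases plus one non-content baseline, class 0), 6 channels, 1,000 Hz,
#' 2 s epochs, and 10 sessions per subject.
#'
#' @param n_classes number of classes including the non-content baseline
#'   class 0 (default 101).
#' @param n_channels number of sEMG channels (default 6).
#' @param fs sampling rate in Hz (default 1000).
#' @param epoch_s epoch duration in seconds (default 2).
#' @param n_subjects number of simulated subjects (default 1).
#' @param n_sessions sessions per subject; each session contains every class
#'   exactly once (default 10).
#' @param separation non-negative scale of between-class envelope
#'   differences; 0 makes all non-baseline classes identical.
#' @param noise_sd standard deviation of additive white sensor noise,
#'   in the same arbitrary amplitude units as the carrier.
#' @param powerline_amp amplitude of the 50 Hz powerline interference.
#' @param dc_offset_range length-2 interval from which per-channel DC
#'   offsets are drawn.
#' @param seed master integer seed; all generator output is a pure function
#'   of the spec including this seed.
#' @return an object of class `synthetic_spec`.
#' @examples
#' sp <- synthetic_spec(n_classes = 5, n_subjects = 1, n_sessions = 2)
#' ds <- generate_dataset(sp)
#' dim(ds$epochs)  # 10 epochs x 6 channels x 2000 samples
#' @export
synthetic_spec <- function(n_classes = 101L, n_channels = 6L, fs = 1000,
                           epoch_s = 2, n_subjects = 1L, n_sessions = 10L,
                           separation = 1, noise_sd = 0.2,
                           powerline_amp = 0.5, dc_offset_range = c(-0.5, 0.5),
                           seed = 1L) {
  stopifnot(is_count(n_classes), n_classes >= 2,
            is_count(n_channels), n_channels >= 1,
            fs > 0, epoch_s > 0,
            is_count(n_subjects), n_subjects >= 1,
            is_count(n_sessions), n_sessions >= 1,
            separation >= 0, noise_sd >= 0, powerline_amp >= 0,
            length(dc_offset_range) == 2,
            dc_offset_range[1] <= dc_offset_range[2])
  n_samp <- fs * epoch_s
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("fs * epoch_s must be an integer sample count")
  structure(list(
    n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
    fs = fs, epoch_s = epoch_s, n_samples = as.integer(round(n_samp)),
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    separation = separation, noise_sd = noise_sd,
    powerline_amp = powerline_amp, dc_offset_range = dc_offset_range,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Draw per-class activation templates
#'
#' Each class owns, per channel, a list of Gaussian burst descriptors
#' (center, width, amplitude) defining its activation envelope; 1-3 bursts
#' are drawn per channel, mimicking phasic muscle activation. Burst
#' amplitudes scale linearly with `spec$separation`, so the mean pairwise
#' envelope distance grows monotonically with the separation dial and all
#' templates collapse to silence at `separation = 0` (any classifier is
#' then at chance). Class 0 is the non-content baseline: no bursts at all.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of `n_classes` templates; each template is a list with one
#'   data frame of burst descriptors (`center`, `width`, `amplitude`) per
#'   channel, plus the class index under `$class`.
#' @export
make_class_templates <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dur <- spec$epoch_s
  lapply(seq_len(spec$n_classes) - 1L, function(cls) {
    chans <- if (cls == 0L) {
      lapply(seq_len(spec$n_channels), function(ch)
        data.frame(center = numeric(0), width = numeric(0),
                   amplitude = numeric(0)))
    } else {
      with_seed(stable_seed(spec$seed, 7100L, cls), {
        lapply(seq_len(spec$n_channels), function(ch) {
          nb <- sample(1:3, 1)
          data.frame(
            center = stats::runif(nb, 0.15 * dur, 0.9 * dur),
            width = stats::runif(nb, 0.05 * dur, 0.2 * dur),
            amplitude = spec$separation * stats::runif(nb, 0.5, 1.5))
        })
      })
    }
    structure(list(class = cls, channels = chans), class = "class_template")
  })
}

# Evaluate a template's activation envelope on a time grid (seconds).
template_envelope <- function(template, t, amp_scale = NULL) {
  nch <- length(template$channels)
  if (is.null(amp_scale)) amp_scale <- rep(1, nch)
  env <- matrix(0, nrow = nch, ncol = length(t))
  for (ch in seq_len(nch)) {
    b <- template$channels[[ch]]
    if (nrow(b) == 0) next
    for (j in seq_len(nrow(b))) {
      env[ch, ] <- env[ch, ] + amp_scale[ch] * b$amplitude[j] *
        exp(-(t - b$center[j])^2 / (2 * b$width[j]^2))
    }
  }
  env
}

#' Draw a subject profile
#'
#' Per-channel multiplicative gains (log-normal around 1), per-channel DC
#' offsets, and an envelope-jitter scale: the stand-in for physiological and
#' behavioral differences among users that make cross-subject recognition
#' hard.
#'
#' @param spec a [synthetic_spec()].
#' @param subject subject index (1-based).
#' @param gain_shift optional multiplicative shift applied to all channel
#'   gains, used to manufacture a strong domain shift for transfer-learning
#'   experiments.
#' @return an object of class `subject_profile` with fields `gain`, `dc`,
#'   `jitter_sd`.
#' @export
subject_profile <- function(spec, subject, gain_shift = 1) {
  stopifnot(inherits(spec, "synthetic_spec"), is_count(subject), subject >= 1,
            gain_shift > 0)
  with_seed(stable_seed(spec$seed, 8000L, subject), {
    gain <- gain_shift * exp(stats::rnorm(spec$n_channels, 0, 0.25))
    dc <- stats::runif(spec$n_channels, spec$dc_offset_range[1],
                       spec$dc_offset_range[2])
    structure(list(subject = as.integer(subject), gain = gain, dc = dc,
                   jitter_sd = 0.1), class = "subject_profile")
  })
}

# 4th-order Butterworth band-pass 20-450 Hz applied zero-phase: the carrier
# band sits inside the 10-400 Hz analysis band so the synthetic "signal"
# survives preprocessing.
carrier_noise <- function(n, fs) {
  bf <- signal::butter(4, c(20, min(450, 0.98 * fs / 2)) / (fs / 2),
                       type = "pass")
  x <- stats::rnorm(n)
  signal::filtfilt(bf, x)
}

#' Synthesize one labelled sEMG epoch
#'
#' `samples = gain * (envelope x band-limited noise carrier) + DC +
#' powerline_amp * sin(2 pi 50 t + phi) + white noise`, channel-wise. The
#' powerline phase is drawn per epoch so the notch filter has to work
#' regardless of phase.
#'
#' @param template a class template from [make_class_templates()].
#' @param profile a [subject_profile()].
#' @param spec the generating [synthetic_spec()].
#' @param seed integer seed for this epoch's random draws.
#' @param session session index recorded in the epoch metadata.
#' @return an object of class `semg_epoch`: list with `samples`
#'   (`n_channels x n_samples` matrix), `fs`, `label`, `subject`, `session`.
#' @export
synthesize_epoch <- function(template, profile, spec, seed,
                             session = 1L) {
  stopifnot(inherits(template, "class_template"),
            inherits(profile, "subject_profile"),
            inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  t <- (seq_len(n) - 1) / spec$fs
  with_seed(seed, {
    amp_scale <- exp(stats::rnorm(spec$n_channels, 0, profile$jitter_sd))
    env <- template_envelope(template, t, amp_scale)
    x <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      sig <- if (any(env[ch, ] != 0)) env[ch, ] * carrier_noise(n, spec$fs)
             else numeric(n)
      phi <- stats::runif(1, 0, 2 * pi)
      x[ch, ] <- profile$gain[ch] * sig + profile$dc[ch] +
        spec$powerline_amp * sin(2 * pi * 50 * t + phi) +
        spec$noise_sd * stats::rnorm(n)
    }
    structure(list(samples = x, fs = spec$fs, label = template$class,
                   subject = profile$subject, session = as.integer(session)),
              class = "semg_epoch")
  })
}

#' Generate a full synthetic dataset
#'
#' Produces `n_subjects x n_sessions x n_classes` epochs; every
#' (subject, session) block contains each class exactly once, mirroring a
#' protocol in which all phrases are read once per session. Per-epoch seeds
#' are derived by stable hashing of (subject, session, class) from the
#' master seed, so the dataset is reproducible and any sub-block can be
#' regenerated independently.
#'
#' @param spec a [synthetic_spec()].
#' @param subjects optional integer vector of subject indices to generate
#'   (default `1:n_subjects`); profiles are keyed by index so subject 3 has
#'   the same profile whether or not subjects 1-2 are generated.
#' @param gain_shift passed to [subject_profile()] for every subject.
#' @return an object of class `semg_dataset`: list with `epochs`
#'   (`n x n_channels x n_samples` array), integer vectors `labels`
#'   (0-based), `subjects`, `sessions`, scalar `fs`, character
#'   `class_names`, and `provenance` (the generating spec).
#' @export
generate_dataset <- function(spec, subjects = NULL, gain_shift = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  subjects <- as.integer(subjects %||% seq_len(spec$n_subjects))
  templates <- make_class_templates(spec)
  n_total <- length(subjects) * spec$n_sessions * spec$n_classes
  epochs <- array(0, dim = c(n_total, spec$n_channels, spec$n_samples))
  labels <- integer(n_total); subj <- integer(n_total); sess <- integer(n_total)
  i <- 0L
  for (s in subjects) {
    prof <- subject_profile(spec, s, gain_shift = gain_shift)
    for (k in seq_len(spec$n_sessions)) {
      for (cls in seq_len(spec$n_classes)) {
        i <- i + 1L
        ep <- synthesize_epoch(templates[[cls]], prof, spec,
                               seed = stable_seed(spec$seed, s, k, cls - 1L),
                               session = k)
        epochs[i, , ] <- ep$samples
        labels[i] <- ep$label; subj[i] <- s; sess[i] <- k
      }
    }
  }
  new_semg_dataset(epochs, labels, subj, sess, fs = spec$fs,
                   class_names = c("baseline",
                                   paste0("phrase_", seq_len(spec$n_classes - 1))),
                   provenance = unclass(spec))
}

# Low-level constructor shared by the generator and the IO layer.
new_semg_dataset <- function(epochs, labels, subjects, sessions, fs,
                             class_names, provenance = NULL) {
  stopifnot(length(dim(epochs)) == 3,
            length(labels) == dim(epochs)[1],
            length(subjects) == length(labels),
            length(sessions) == length(labels),
            fs > 0, all(labels >= 0), all(labels < length(class_names)))
  structure(list(epochs = epochs, labels = as.integer(labels),
                 subjects = as.integer(subjects),
                 sessions = as.integer(sessions), fs = fs,
                 class_names = class_names, provenance = provenance),
            class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<semg_dataset> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %d  subjects: %d  sessions/subject: %s\n",
              length(x$class_names), length(unique(x$subjects)),
              paste(range(x$sessions), collapse = "-")))
  invisible(x)
}

# Extract epoch i of a dataset as a semg_epoch.
dataset_epoch <- function(ds, i) {
  structure(list(samples = ds$epochs[i, , , drop = TRUE],
                 fs = ds$fs, label = ds$labels[i],
                 subject = ds$subjects[i], session = ds$sessions[i]),
            class = "semg_epoch")
}
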