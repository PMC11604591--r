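#' Synthetic data generators
#'
#' Seedable generators that emulate the two task families the attention
#' model is exercised on: small glyphs stamped at random positions on large
#' blank canvases (the "find a small object" structure of translated-digit
#' benchmarks) and EEG-like multichannel epochs carrying class-specific
#' localized oscillatory bursts (a stand-in for motor-imagery band-power
#' features, shaped like the BCI Competition IV-2a recordings: 22 channels,
#' 4 s at 250 Hz, 4 classes, 9 subjects x 2 sessions x 6 runs x 48 trials).
#'
#' @name synthetic-data
NULL

#' One labelled signal epoch
#'
#' @param data Numeric channels x time (or image rows x cols) matrix.
#' @param label 0-based class index.
#' @param subject,session,run,trial Integer metadata ids.
#' @return An object of class `signal_epoch`.
#' @export
signal_epoch <- function(data, label, subject = 1L, session = 1L,
                         run = 1L, trial = 1L) {
  if (!is.matrix(data) || !all(is.finite(data))) stop("data must be a finite matrix")
  structure(list(data = data, label = as.integer(label),
                 subject = as.integer(subject), session = as.integer(session),
                 run = as.integer(run), trial = as.integer(trial)),
            class = "signal_epoch")
}

#' @export
print.signal_epoch <- function(x, ...) {
  cat(sprintf("<signal_epoch> %d x %d, label %d (subject %d, session %d, run %d, trial %d)\n",
              nrow(x$data), ncol(x$data), x$label, x$subject, x$session,
              x$run, x$trial))
  invisible(x)
}

# Balanced label vector: counts differ by at most 1, order shuffled.
balanced_labels <- function(n, n_classes) {
  sample(rep_len(seq_len(n_classes) - 1L, n))
}

## ---- translated glyphs ---------------------------------------------------

# Procedural 12x12 seven-segment style glyph templates for classes 0..9.
# Segments: a = top, b = top-right, c = bottom-right, d = bottom, e =
# bottom-left, f = top-left, g = middle.
seven_segment_map <- function() {
  list(`0` = c("a","b","c","d","e","f"), `1` = c("b","c"),
       `2` = c("a","b","g","e","d"),     `3` = c("a","b","g","c","d"),
       `4` = c("f","g","b","c"),         `5` = c("a","f","g","c","d"),
       `6` = c("a","f","g","e","c","d"), `7` = c("a","b","c"),
       `8` = c("a","b","c","d","e","f","g"), `9` = c("a","b","c","d","f","g"))
}

#' Procedural glyph templates
#'
#' Ten fixed 12 x 12 binary digit-like templates drawn as seven-segment
#' strokes (value 1 on strokes, 0 elsewhere). Deterministic; no external
#' image data.
#'
#' @param size Template edge length (default 12).
#' @return List of 10 `size x size` matrices, one per class 0..9.
#' @export
glyph_templates <- function(size = 12L) {
  stopifnot(size >= 7L)
  mid <- (size + 1L) %/% 2L
  seg_cells <- list(
    a = cbind(1L, 2:(size - 1L)),
    d = cbind(size, 2:(size - 1L)),
    g = cbind(mid, 2:(size - 1L)),
    f = cbind(2:(mid - 1L), 1L),
    b = cbind(2:(mid - 1L), size),
    e = cbind((mid + 1L):(size - 1L), 1L),
    c = cbind((mid + 1L):(size - 1L), size)
  )
  lapply(seven_segment_map(), function(segs) {
    m <- matrix(0, size, size)
    for (s in segs) m[seg_cells[[s]]] <- 1
    m
  })
}

#' Generate translated-glyph images
#'
#' Each sample is a blank canvas with one class template stamped at a
#' uniform random in-bounds offset; labels are balanced to within one.
#'
#' @param n Number of samples.
#' @param canvas Length-2 canvas size (default 60 x 60).
#' @param num_classes Number of classes (<= 10).
#' @param template_size Glyph edge length (default 12).
#' @param seed Optional seed.
#' @return List of [signal_epoch()] objects with attribute `offsets`
#'   (n x 2 matrix of 1-based top-left stamp positions).
#' @export
gen_translated_glyphs <- function(n, canvas = c(60L, 60L), num_classes = 10L,
                                  template_size = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  canvas <- as.integer(canvas)
  if (any(canvas < template_size)) stop("canvas smaller than glyph template")
  if (num_classes < 2L || num_classes > 10L) stop("num_classes must be in 2..10")
  tmpl <- glyph_templates(template_size)[seq_len(num_classes)]
  labels <- balanced_labels(n, num_classes)
  offsets <- cbind(sample.int(canvas[1] - template_size + 1L, n, replace = TRUE),
                   sample.int(canvas[2] - template_size + 1L, n, replace = TRUE))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matrix(0, canvas[1], canvas[2])
    r <- offsets[i, 1]; cc <- offsets[i, 2]
    m[r:(r + template_size - 1L), cc:(cc + template_size - 1L)] <-
      tmpl[[labels[i] + 1L]]
    out[[i]] <- signal_epoch(m, labels[i], trial = i)
  }
  attr(out, "offsets") <- offsets
  out
}

## ---- oscillatory-burst EEG -----------------------------------------------

#' Class-discriminative burst specification
#'
#' Describes the localized oscillatory burst injected for one class: a
#' Hann-windowed sinusoid at `carrier_freq` Hz, centred at
#' (`center_channel`, `center_time`), spread over a small channel group.
#'
#' @param center_channel,center_time Burst locus (1-based channel index,
#'   sample index).
#' @param duration Burst length in samples.
#' @param carrier_freq Carrier frequency in Hz.
#' @param amplitude Peak amplitude (in noise-sd units before z-scoring).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param channel_spread Half-width of the channel group (default 1: three
#'   channels, tapered).
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(center_channel, center_time, duration = 250L,
                       carrier_freq = 10, amplitude = 2, noise_sd = 1,
                       channel_spread = 1L) {
  if (amplitude < 0 || noise_sd < 0) stop("amplitude and noise_sd must be >= 0")
  if (duration < 2L) stop("duration must be >= 2 samples")
  structure(list(center_channel = as.integer(center_channel),
                 center_time = as.integer(center_time),
                 duration = as.integer(duration),
                 carrier_freq = as.numeric(carrier_freq),
                 amplitude = as.numeric(amplitude),
                 noise_sd = as.numeric(noise_sd),
                 channel_spread = as.integer(channel_spread)),
            class = "burst_spec")
}

#' Default burst specifications
#'
#' Loci are spread over channels and time; carriers sit in the 8-30 Hz
#' band characteristic of motor-imagery-reactive rhythms.
#'
#' @param n_classes Number of classes (2 or 4).
#' @param channels,timepoints Epoch geometry.
#' @param amplitude,noise_sd Shared burst amplitude and noise level.
#' @return List of [burst_spec()] objects, one per class.
#' @export
default_burst_specs <- function(n_classes = 4L, channels = 22L,
                                timepoints = 1000L, amplitude = 2,
                                noise_sd = 1) {
  freqs <- c(10, 22, 14, 27)
  ch <- round(seq(0.25, 0.75, length.out = n_classes) * channels)
  tm <- round(c(0.3, 0.7, 0.45, 0.6)[seq_len(n_classes)] * timepoints)
  lapply(seq_len(n_classes), function(ci)
    burst_spec(ch[ci], tm[ci], duration = round(timepoints / 4),
               carrier_freq = freqs[ci], amplitude = amplitude,
               noise_sd = noise_sd))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Add the class burst (with locus jitter) into a noise matrix; in place.
inject_burst <- function(m, spec, fs, jitter_time, jitter_channel) {
  nch <- nrow(m); ntp <- ncol(m)
  if (spec$center_channel < 1L || spec$center_channel > nch ||
      spec$center_time < 1L || spec$center_time > ntp)
    stop("burst locus outside the epoch")
  ct <- spec$center_time +
    if (jitter_time > 0) sample.int(2L * jitter_time + 1L, 1L) - jitter_time - 1L else 0L
  cc <- spec$center_channel +
    if (jitter_channel > 0) sample.int(2L * jitter_channel + 1L, 1L) - jitter_channel - 1L else 0L
  half <- spec$duration %/% 2L
  t0 <- max(1L, ct - half); t1 <- min(ntp, ct - half + spec$duration - 1L)
  if (t1 < t0) return(m)                 # jittered fully off the epoch edge
  tt <- t0:t1
  env <- hann_window(spec$duration)[tt - (ct - half) + 1L]
  phase <- stats::runif(1L, 0, 2 * pi)
  carrier <- sin(2 * pi * spec$carrier_freq * (tt - 1) / fs + phase)
  chans <- (cc - spec$channel_spread):(cc + spec$channel_spread)
  taper <- 1 - abs(seq(-spec$channel_spread, spec$channel_spread)) /
    (spec$channel_spread + 1)
  keep <- chans >= 1L & chans <= nch
  for (j in which(keep))
    m[chans[j], tt] <- m[chans[j], tt] + spec$amplitude * taper[j] * env * carrier
  m
}

#' Generate EEG-like epochs with class-specific oscillatory bursts
#'
#' Each epoch is Gaussian noise plus one Hann-windowed sinusoidal burst at
#' the class locus (with small channel/time jitter and random carrier
#' phase), then z-scored over the whole epoch. With `amplitude = 0` the
#' samples are pure noise; with `noise_sd = 0` the burst is the only signal.
#'
#' @param n Number of epochs.
#' @param channels,timepoints Epoch geometry (default 22 x 1000: 4 s at
#'   250 Hz).
#' @param specs List of [burst_spec()], one per class; default
#'   [default_burst_specs()] for 4 classes.
#' @param fs Sampling frequency in Hz.
#' @param jitter_time,jitter_channel Maximum absolute locus jitter.
#' @param subject,session,run Metadata ids stamped on every epoch.
#' @param zscore Standardize each epoch to mean 0, sd 1.
#' @param seed Optional seed.
#' @return List of [signal_epoch()] objects.
#' @export
gen_burst_eeg <- function(n, channels = 22L, timepoints = 1000L, specs = NULL,
                          fs = 250, jitter_time = 25L, jitter_channel = 1L,
                          subject = 1L, session = 1L, run = 1L, zscore = TRUE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(specs)) specs <- default_burst_specs(4L, channels, timepoints)
  if (!all(vapply(specs, inherits, logical(1), "burst_spec")))
    stop("specs must be a list of burst_spec objects")
  n_classes <- length(specs)
  labels <- balanced_labels(n, n_classes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[labels[i] + 1L]]
    m <- matrix(stats::rnorm(channels * timepoints, sd = sp$noise_sd),
                channels, timepoints)
    if (sp$amplitude > 0)
      m <- inject_burst(m, sp, fs, jitter_time, jitter_channel)
    if (zscore) {
      s <- stats::sd(m)
      if (s > 0) m <- (m - mean(m)) / s
    }
    out[[i]] <- signal_epoch(m, labels[i], subject = subject,
                             session = session, run = run, trial = i)
  }
  out
}

#' Generate a BCI-IV-2a-shaped synthetic dataset
#'
#' The full structural scaffold of the motor-imagery competition recordings:
#' 9 subjects x 2 sessions x 6 runs x 48 trials (5,184 epochs; 288 per
#' subject-session), 4 balanced classes per run, 22 channels, 4 s at 250 Hz.
#' Inter-subject variability is emulated by per-subject random perturbations
#' of each class's burst locus and amplitude.
#'
#' @param channels,timepoints Epoch geometry (defaults 22 x 1000).
#' @param amplitude,noise_sd Base burst amplitude and noise level.
#' @param subject_sd Scale of per-subject locus/amplitude perturbations
#'   (channels shift up to ~2, time shift up to ~50 samples at the default).
#' @param seed Optional master seed.
#' @return List of 5,184 [signal_epoch()] objects with full metadata;
#'   attribute `specs` holds the per-subject burst specifications.
#' @export
gen_bci2a_shaped_dataset <- function(channels = 22L, timepoints = 1000L,
                                     amplitude = 2, noise_sd = 1,
                                     subject_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_subjects <- 9L; n_sessions <- 2L; n_runs <- 6L; n_trials <- 48L
  base <- default_burst_specs(4L, channels, timepoints, amplitude, noise_sd)
  subj_specs <- lapply(seq_len(n_subjects), function(s) {
    lapply(base, function(sp) {
      sp$center_channel <- as.integer(min(max(
        sp$center_channel + round(stats::rnorm(1, 0, 1.2 * subject_sd)), 2L),
        channels - 1L))
      sp$center_time <- as.integer(min(max(
        sp$center_time + round(stats::rnorm(1, 0, 30 * subject_sd)),
        sp$duration %/% 2L + 1L), timepoints - sp$duration %/% 2L))
      sp$amplitude <- sp$amplitude * exp(stats::rnorm(1, 0, 0.1 * subject_sd))
      sp
    })
  })
  out <- vector("list", n_subjects * n_sessions * n_runs * n_trials)
  i <- 0L
  for (s in seq_len(n_subjects)) for (se in seq_len(n_sessions))
    for (r in seq_len(n_runs)) {
      run_eps <- gen_burst_eeg(n_trials, channels, timepoints,
                               specs = subj_specs[[s]], subject = s,
                               session = se, run = r)
      for (j in seq_len(n_trials)) {
        i <- i + 1L
        ep <- run_eps[[j]]
        ep$trial <- j
        out[[i]] <- ep
      }
    }
  attr(out, "specs") <- subj_specs
  out
}

#' Dataset metadata as a data frame
#'
#' @param dataset List of [signal_epoch()] objects.
#' @return data.frame with one row per epoch: label, subject, session, run,
#'   trial.
#' @export
epoch_manifest <- function(dataset) {
  data.frame(
    label = vapply(dataset, `[[`, integer(1), "label"),
    subject = vapply(dataset, `[[`, integer(1), "subject"),
    session = vapply(dataset, `[[`, integer(1), "session"),
    run = vapply(dataset, `[[`, integer(1), "run"),
    trial = vapply(dataset, `[[`, integer(1), "trial")
  )
}
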