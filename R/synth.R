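#' Configuration for the synthetic iEEG generator
#'
#' The generator emulates an intracranial EEG corpus for validating the
#' detector end to end: 1/f ("pink") background activity, 50 Hz mains
#' interference, and four ground-truth event classes -- ripples (80-250 Hz),
#' fast ripples (250-500 Hz), interictal spikes and broadband artifacts.
#'
#' `snr_db` is defined, for every event kind, as the ratio of event RMS to
#' local background RMS *within the 80-500 Hz detection band*: it is the
#' signal-to-noise ratio the short-time-energy stage actually sees. Event
#' rates are per minute per channel.
#'
#' @param n_channels Number of channels.
#' @param duration_s Recording duration in seconds.
#' @param fs_hz Sampling rate in Hz; must be at least 1000 so the 500 Hz
#'   fast-ripple band is below Nyquist.
#' @param background_scale RMS amplitude of the pink background, in uV.
#' @param line_noise_amp Amplitude of the additive 50 Hz sinusoid, in uV.
#' @param event_rates Named numeric vector of events/minute/channel for kinds
#'   `ripple`, `fast_ripple`, `spike`, `artifact`.
#' @param snr_db Named numeric vector of in-band SNR targets (dB), same names.
#' @param seed Integer seed; fully determines the generated recording.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 4,
                         duration_s = 600,
                         fs_hz = 2560,
                         background_scale = 1,
                         line_noise_amp = 1,
                         event_rates = c(ripple = 2.5, fast_ripple = 2.5,
                                         spike = 5, artifact = 2.5),
                         snr_db = c(ripple = 15, fast_ripple = 15,
                                    spike = 15, artifact = 15),
                         seed = 42) {
  kinds <- c("ripple", "fast_ripple", "spike", "artifact")
  if (!is.numeric(fs_hz) || fs_hz < 1000) {
    abort("`fs_hz` must be >= 1000 Hz (Nyquist must cover 500 Hz).",
          class = "hfo_config_error")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "hfo_config_error")
  }
  if (n_channels < 1) abort("`n_channels` must be >= 1.", class = "hfo_config_error")
  event_rates <- event_rates[kinds]; names(event_rates) <- kinds
  snr_db <- snr_db[kinds]; names(snr_db) <- kinds
  if (anyNA(event_rates) || any(event_rates < 0)) {
    abort("`event_rates` must be non-negative for all four kinds.",
          class = "hfo_config_error")
  }
  if (anyNA(snr_db)) abort("`snr_db` must be given for all four kinds.",
                           class = "hfo_config_error")
  structure(
    list(n_channels = as.integer(n_channels), duration_s = duration_s,
         fs_hz = fs_hz, background_scale = background_scale,
         line_noise_amp = line_noise_amp, event_rates = event_rates,
         snr_db = snr_db, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate background iEEG activity
#'
#' Pink (1/f power) noise per channel, scaled to `background_scale` RMS, plus
#' an additive 50 Hz sinusoid of amplitude `line_noise_amp`. The output is a
#' pure function of the configuration (seeded internally).
#'
#' @param config A [synth_config()].
#' @return An [ieeg_recording()].
#' @examples
#' bg <- generate_background(synth_config(n_channels = 1, duration_s = 2))
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration_s * config$fs_hz)
  with_seed(config$seed, {
    x <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      x[ch, ] <- pink_noise(n, config$fs_hz) * config$background_scale
    }
    if (config$line_noise_amp != 0) {
      tt <- (seq_len(n) - 1) / config$fs_hz
      line <- config$line_noise_amp * sin(2 * pi * 50 * tt)
      x <- sweep(x, 2, line, "+")
    }
    ieeg_recording(x, fs_hz = config$fs_hz)
  })
}

# unit-RMS pink noise by spectral shaping of white Gaussian noise
pink_noise <- function(n, fs) {
  if (n < 2) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))     # flatten below 1 Hz, kill DC next
  shape[1] <- 0
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  s <- rms(x)
  if (s > 0) x / s else x
}

#' Build a table of event specifications
#'
#' Validates kinds, frequency bands and in-bounds placement. Oscillatory kinds
#' (`ripple`, `fast_ripple`) require `freq_hz` in their band; `spike` and
#' `artifact` ignore `freq_hz`.
#'
#' @param kind Character vector in `ripple`, `fast_ripple`, `spike`, `artifact`.
#' @param channel Integer channel index (1-based).
#' @param center_s Event centre in seconds.
#' @param duration_ms Event duration in milliseconds (> 0).
#' @param freq_hz Oscillation frequency (oscillatory kinds; NA otherwise).
#' @param amplitude Peak amplitude (oscillatory/spike) or RMS (artifact), in
#'   the units of the background signal.
#' @return A tibble of class `event_specs`.
#' @export
event_specs <- function(kind, channel, center_s, duration_ms,
                        freq_hz = NA_real_, amplitude = 1) {
  kinds <- c("ripple", "fast_ripple", "spike", "artifact")
  if (!all(kind %in% kinds)) {
    abort(sprintf("Unknown event kind(s): %s",
                  paste(setdiff(kind, kinds), collapse = ", ")))
  }
  ev <- tibble(kind = kind, channel = as.integer(channel),
               center_s = center_s, duration_ms = duration_ms,
               freq_hz = freq_hz, amplitude = amplitude)
  if (any(ev$duration_ms <= 0)) abort("`duration_ms` must be positive.")
  rip <- ev$kind == "ripple"
  fr <- ev$kind == "fast_ripple"
  if (any(rip & (is.na(ev$freq_hz) | ev$freq_hz < 80 | ev$freq_hz >= 250))) {
    abort("ripple `freq_hz` must lie in [80, 250).")
  }
  if (any(fr & (is.na(ev$freq_hz) | ev$freq_hz < 250 | ev$freq_hz > 500))) {
    abort("fast_ripple `freq_hz` must lie in [250, 500].")
  }
  class(ev) <- c("event_specs", class(ev))
  ev
}

# unit-normalized event waveform sampled at fs; returns values centred on the
# event (odd support length). Oscillatory: Gaussian-windowed sinusoid with
# sigma = duration/6, unit peak envelope. Spike: biphasic transient (sharp
# apex with Laplacian cusp + slow rebound), unit peak. Artifact: brown-noise
# burst (integrated white noise), Tukey-tapered, unit RMS. `noise_seed` pins
# the artifact noise realization so calibration and injection agree.
event_waveform <- function(kind, duration_ms, freq_hz, fs, phase = 0,
                           noise_seed = NULL) {
  dur <- duration_ms / 1000
  half <- ceiling(dur / 2 * fs)
  t <- (-half:half) / fs
  if (kind %in% c("ripple", "fast_ripple")) {
    sigma <- dur / 6
    env <- exp(-t^2 / (2 * sigma^2))
    return(env * sin(2 * pi * freq_hz * t + phase))
  }
  if (kind == "spike") {
    half <- ceiling(dur * fs)           # wider support for the rebound wave
    t <- (-half:half) / fs
    s1 <- dur / 6
    main <- exp(-t^2 / (2 * s1^2))
    cusp <- 0.4 * exp(-abs(t) / 0.003)  # sharp apex, broadband tail
    rebound <- -0.6 * exp(-(t - 0.35 * dur)^2 / (2 * (dur / 3.5)^2))
    w <- main + cusp + rebound
    return(w / max(abs(w)))
  }
  if (kind == "artifact") {
    n <- length(t)
    b <- if (is.null(noise_seed)) cumsum(rnorm(n)) else
      with_seed(noise_seed, cumsum(rnorm(n)))
    b <- b - mean(b)
    # Tukey taper (20% cosine lobes) to avoid wrap-around steps
    taper <- rep(1, n)
    m <- max(2L, round(0.2 * n))
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
    taper[seq_len(m)] <- ramp
    taper[n + 1 - seq_len(m)] <- ramp
    b <- b * taper
    return(b / rms(b))
  }
  abort(paste("unknown kind", kind))
}

#' Inject ground-truth events into a recording
#'
#' Adds each event's waveform to the recording at its channel and centre time
#' and returns the modified recording together with an annotation table in a
#' stable order (channel, then centre sample).
#'
#' @param rec An [ieeg_recording()].
#' @param events An [event_specs()] table.
#' @param rng_seed Seed for the random oscillation phases and artifact noise.
#' @return A list with elements `recording` and `annotations` (tibble with
#'   columns channel, center_sample, kind, center_s, duration_ms, freq_hz,
#'   amplitude).
#' @export
inject_events <- function(rec, events, rng_seed = 1) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (nrow(events) == 0) {
    return(list(recording = rec, annotations = empty_annotations()))
  }
  fs <- rec$fs_hz
  n <- n_samples(rec)
  half_dur <- events$duration_ms / 2000
  bad <- which(events$center_s - half_dur < 0 |
                 events$center_s + half_dur > n / fs |
                 events$channel < 1 | events$channel > n_channels(rec))
  if (length(bad) > 0) {
    abort(sprintf("Event(s) outside recording bounds at index: %s",
                  paste(bad, collapse = ", ")),
          class = "hfo_bounds_error")
  }
  x <- rec$samples
  # phases / artifact-noise seeds: honour columns supplied by the caller
  # (make_benchmark pre-draws them so SNR calibration sees the same
  # realization), otherwise draw them deterministically from rng_seed
  if (!all(c("phase", "noise_seed") %in% names(events))) {
    drawn <- with_seed(rng_seed, list(
      phase = runif(nrow(events), 0, 2 * pi),
      noise_seed = sample.int(.Machine$integer.max - 1L, nrow(events))
    ))
    if (!"phase" %in% names(events)) events$phase <- drawn$phase
    if (!"noise_seed" %in% names(events)) events$noise_seed <- drawn$noise_seed
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    w <- event_waveform(ev$kind, ev$duration_ms, ev$freq_hz, fs,
                        phase = ev$phase, noise_seed = ev$noise_seed)
    w <- w * ev$amplitude
    c0 <- round(ev$center_s * fs) + 1L
    halfw <- (length(w) - 1L) %/% 2L
    idx <- (c0 - halfw):(c0 + halfw)
    keep <- idx >= 1 & idx <= n
    x[ev$channel, idx[keep]] <- x[ev$channel, idx[keep]] + w[keep]
  }
  ann <- tibble(
    channel = events$channel,
    center_sample = round(events$center_s * fs) + 1L,
    kind = events$kind,
    center_s = events$center_s,
    duration_ms = events$duration_ms,
    freq_hz = events$freq_hz,
    amplitude = events$amplitude
  )
  ann <- ann[order(ann$channel, ann$center_sample), ]
  list(recording = ieeg_recording(x, fs, rec$channel_labels),
       annotations = ann)
}

empty_annotations <- function() {
  tibble(channel = integer(), center_sample = integer(), kind = character(),
         center_s = numeric(), duration_ms = numeric(), freq_hz = numeric(),
         amplitude = numeric())
}

#' Generate the synthetic benchmark recording
#'
#' Draws event counts per channel and kind from Poisson distributions at the
#' configured rates, places them uniformly in time with a minimum on-channel
#' spacing of 300 ms (so each event owns one 150 ms analysis segment), sizes
#' amplitudes to reach the configured in-band SNR against the local background
#' RMS, and injects them into the generated background.
#'
#' Frequencies are drawn from truncated normals -- ripples N(140, 25) on
#' 100-200 Hz, fast ripples N(350, 40) on 280-430 Hz -- and durations
#' from uniform ranges: ripple 70-120 ms, fast ripple 60-100 ms, spike
#' 40-70 ms, artifact 20-50 ms.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording`, `annotations` and `background`
#'   (the event-free recording, kept for SNR verification).
#' @examples
#' bm <- make_benchmark(synth_config(n_channels = 1, duration_s = 30, seed = 7))
#' nrow(bm$annotations)
#' @export
make_benchmark <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  bg <- generate_background(config)
  fs <- config$fs_hz
  dur_min <- config$duration_s / 60
  kinds <- names(config$event_rates)

  specs <- with_seed(config$seed + 1L, {
    rows <- list()
    for (ch in seq_len(config$n_channels)) {
      kind_v <- character(0); cen <- numeric(0)
      dur <- numeric(0); frq <- numeric(0)
      for (k in kinds) {
        cnt <- rpois(1, config$event_rates[[k]] * dur_min)
        if (cnt == 0) next
        d <- switch(k,
          ripple = runif(cnt, 70, 120),
          fast_ripple = runif(cnt, 60, 100),
          spike = runif(cnt, 40, 70),
          artifact = runif(cnt, 20, 50))
        margin <- max(d) / 1000 + 0.2   # keep clear of the recording edges
        cc <- runif(cnt, margin, config$duration_s - margin)
        f <- switch(k,
          ripple = rtruncnorm(cnt, 140, 25, 100, 200),
          fast_ripple = rtruncnorm(cnt, 350, 40, 280, 430),
          rep(NA_real_, cnt))
        kind_v <- c(kind_v, rep(k, cnt)); cen <- c(cen, cc)
        dur <- c(dur, d); frq <- c(frq, f)
      }
      if (length(cen) == 0) next
      o <- order(cen)
      kind_v <- kind_v[o]; cen <- cen[o]; dur <- dur[o]; frq <- frq[o]
      # greedy 300 ms minimum spacing per channel
      keep <- logical(length(cen)); last <- -Inf
      for (i in seq_along(cen)) {
        if (cen[i] - last >= 0.3) { keep[i] <- TRUE; last <- cen[i] }
      }
      rows[[ch]] <- tibble(kind = kind_v[keep], channel = ch,
                           center_s = cen[keep], duration_ms = dur[keep],
                           freq_hz = frq[keep])
    }
    dplyr::bind_rows(rows)
  })

  if (nrow(specs) == 0) {
    return(list(recording = bg, annotations = empty_annotations(),
                background = bg))
  }

  # in-band SNR calibration: scale each unit template so that its band-passed
  # RMS over the event support reaches snr_db above the band-passed local
  # background RMS (+/- 0.5 s neighbourhood of the clean background)
  draws <- with_seed(config$seed + 2L, list(
    phase = runif(nrow(specs), 0, 2 * pi),
    noise_seed = sample.int(.Machine$integer.max - 1L, nrow(specs))
  ))
  bg_band <- t(apply(bg$samples, 1, bandpass_filter, fs = fs))
  amp <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    w <- event_waveform(sp$kind, sp$duration_ms, sp$freq_hz, fs,
                        phase = draws$phase[i],
                        noise_seed = draws$noise_seed[i])
    wb <- bandpass_filter(w, fs)
    ev_rms <- rms(wb)
    c0 <- round(sp$center_s * fs) + 1L
    nb <- max(1L, c0 - round(0.5 * fs)):min(n_samples(bg), c0 + round(0.5 * fs))
    local_rms <- rms(bg_band[sp$channel, nb])
    amp[i] <- 10^(config$snr_db[[sp$kind]] / 20) * local_rms / ev_rms
  }
  ev <- event_specs(specs$kind, specs$channel, specs$center_s,
                    specs$duration_ms, specs$freq_hz, amp)
  ev$phase <- draws$phase
  ev$noise_seed <- draws$noise_seed
  out <- inject_events(bg, ev, rng_seed = config$seed + 2L)
  out$background <- bg
  out
}

#' Generate labelled stand-alone candidate windows
#'
#' Draws 150 ms pink-noise windows with one event of the requested kind
#' injected at the centre at the given in-band SNR -- a fast way to build
#' labelled R-TFM datasets for the imaging, auto-encoder and clustering
#' stages without simulating a full recording.
#'
#' @param n_per_kind Number of windows per kind.
#' @param kinds Event kinds to include.
#' @param fs_hz Sampling rate.
#' @param snr_db In-band SNR (dB) of each event.
#' @param window_ms Window length.
#' @param seed Integer seed.
#' @return A tibble with columns `kind`, `fs_hz` and list-columns
#'   `raw_window`, `filtered_window` (band-passed), shuffled, plus
#'   `truth_hfo`.
#' @export
synth_candidate_windows <- function(n_per_kind = 50,
                                    kinds = c("ripple", "fast_ripple",
                                              "spike", "artifact"),
                                    fs_hz = 2560, snr_db = 15,
                                    window_ms = 150, seed = 1) {
  n <- round(window_ms / 1000 * fs_hz)
  with_seed(seed, {
    rows <- list()
    for (k in kinds) {
      for (i in seq_len(n_per_kind)) {
        bg <- pink_noise(n, fs_hz)
        dur <- switch(k, ripple = runif(1, 70, 120),
                      fast_ripple = runif(1, 60, 100),
                      spike = runif(1, 40, 70), artifact = runif(1, 20, 50))
        frq <- switch(k, ripple = rtruncnorm(1, 140, 25, 100, 200),
                      fast_ripple = rtruncnorm(1, 350, 40, 280, 430),
                      NA_real_)
        w <- event_waveform(k, dur, frq, fs_hz, phase = runif(1, 0, 2 * pi))
        amp <- 10^(snr_db / 20) * rms(bandpass_filter(bg, fs_hz)) /
          rms(bandpass_filter(w, fs_hz))
        x <- bg
        halfw <- (length(w) - 1L) %/% 2L
        c0 <- n %/% 2L
        idx <- (c0 - halfw):(c0 + halfw)
        keep <- idx >= 1 & idx <= n
        x[idx[keep]] <- x[idx[keep]] + amp * w[keep]
        rows[[length(rows) + 1]] <-
          tibble(kind = k, fs_hz = fs_hz, raw_window = list(x),
                 filtered_window = list(bandpass_filter(x, fs_hz)))
      }
    }
    out <- dplyr::bind_rows(rows)
    out <- out[sample.int(nrow(out)), ]
    out$truth_hfo <- out$kind %in% c("ripple", "fast_ripple")
    out
  })
}

#' Write and read annotation tables
#'
#' CSV round-trip for ground-truth/detected event tables. The first three
#' columns are always `channel`, `center_sample`, `kind`.
#' @param annotations A tibble as returned by [make_benchmark()].
#' @param path CSV file path.
#' @return `read_annotations()` returns a tibble.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
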