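test_that("degenerate configuration yields an all-zero recording", {
  cfg <- synth_config(n_channels = 2, duration_s = 1, background_scale = 0,
                      line_noise_amp = 0, seed = 1)
  bg <- generate_background(cfg)
  expect_true(all(bg$samples == 0))
})

test_that("background generation is deterministic under the seed", {
  cfg <- synth_config(n_channels = 2, duration_s = 2, seed = 1)
  expect_identical(generate_background(cfg)$samples,
                   generate_background(cfg)$samples)
  cfg2 <- synth_config(n_channels = 2, duration_s = 2, seed = 2)
  expect_false(identical(generate_background(cfg)$samples,
                         generate_background(cfg2)$samples))
})

test_that("line interference shows as a 50 Hz periodogram peak", {
  cfg <- synth_config(n_channels = 1, duration_s = 4, background_scale = 1,
                      line_noise_amp = 10, seed = 3)
  bg <- generate_background(cfg)
  x <- bg$samples[1, ]
  p <- Mod(fft(x))^2
  n <- length(x); fs <- cfg$fs_hz
  bin50 <- round(50 * n / fs) + 1
  neighbours <- c(bin50 - (10:3), bin50 + (3:10))
  gain_db <- 10 * log10(p[bin50] / max(p[neighbours]))
  expect_gt(gain_db, 20)
})

test_that("config validation rejects invalid sampling and durations", {
  expect_error(synth_config(fs_hz = 800), class = "hfo_config_error")
  expect_error(synth_config(duration_s = 0), class = "hfo_config_error")
  expect_error(synth_config(event_rates = c(ripple = -1, fast_ripple = 1,
                                            spike = 1, artifact = 1)),
               class = "hfo_config_error")
})

test_that("event spec validation enforces the ripple and fast-ripple bands", {
  expect_error(event_specs("ripple", 1, 1, 80, freq_hz = 260), "ripple")
  expect_error(event_specs("fast_ripple", 1, 1, 80, freq_hz = 200),
               "fast_ripple")
  expect_error(event_specs("buzz", 1, 1, 80), "buzz")
  expect_silent(event_specs("ripple", 1, 1, 80, freq_hz = 120))
})

test_that("an injected ripple dominates the periodogram of its window", {
  fs <- 2560
  zero <- ieeg_recording(matrix(0, 1, 2 * fs), fs)
  ev <- event_specs("ripple", 1, center_s = 1, duration_ms = 100,
                    freq_hz = 120, amplitude = 1)
  out <- inject_events(zero, ev, rng_seed = 4)
  c0 <- out$annotations$center_sample[1]
  win <- out$recording$samples[1, (c0 - 128):(c0 + 127)]
  dom <- hfocluster:::dominant_frequency(win, fs)
  expect_lte(abs(dom - 120), fs / length(win))
})

test_that("band-pass keeps a 400 Hz burst but rejects a 30 Hz slow wave", {
  fs <- 2560
  w400 <- hfocluster:::event_waveform("fast_ripple", 80, 400, fs)
  w30 <- hfocluster:::event_waveform("ripple", 80, 30, fs)  # same envelope
  pad <- function(w) c(rep(0, fs %/% 4), w, rep(0, fs %/% 4))
  ratio_db <- function(w) {
    x <- pad(w)
    20 * log10(hfocluster:::rms(bandpass_filter(x, fs)) /
                 hfocluster:::rms(x))
  }
  expect_gt(ratio_db(w400), -3)
  expect_lt(ratio_db(w30), -20)
})

test_that("injecting an empty event list leaves the recording unchanged", {
  cfg <- synth_config(n_channels = 1, duration_s = 1, seed = 5)
  bg <- generate_background(cfg)
  out <- inject_events(bg, event_specs(character(), integer(), numeric(),
                                       numeric()))
  expect_identical(out$recording$samples, bg$samples)
  expect_equal(nrow(out$annotations), 0)
})

test_that("out-of-bounds events are rejected with their index", {
  cfg <- synth_config(n_channels = 1, duration_s = 1, seed = 5)
  bg <- generate_background(cfg)
  ev <- event_specs(c("ripple", "ripple"), c(1, 1), c(0.5, 0.999),
                    c(80, 80), freq_hz = c(120, 120))
  expect_error(inject_events(bg, ev), "2", class = "hfo_bounds_error")
})

test_that("benchmark with zero rates has zero annotations", {
  cfg <- synth_config(n_channels = 1, duration_s = 30,
                      event_rates = c(ripple = 0, fast_ripple = 0,
                                      spike = 0, artifact = 0), seed = 6)
  bm <- make_benchmark(cfg)
  expect_equal(nrow(bm$annotations), 0)
})

test_that("benchmark event count falls inside the Poisson 99% interval", {
  cfg <- synth_config(n_channels = 1, duration_s = 300,
                      event_rates = c(ripple = 4, fast_ripple = 0,
                                      spike = 4, artifact = 0), seed = 7)
  bm <- make_benchmark(cfg)
  lambda <- 8 * 5   # 8 events/min for 5 minutes
  expect_gte(nrow(bm$annotations), qpois(0.005, lambda))
  expect_lte(nrow(bm$annotations), qpois(0.995, lambda))
})

test_that("the same seed reproduces the benchmark bit for bit", {
  cfg <- synth_config(n_channels = 1, duration_s = 30, seed = 8)
  a <- make_benchmark(cfg); b <- make_benchmark(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("events on a channel are at least 300 ms apart", {
  bm <- small_benchmark()$bm
  gaps <- unlist(tapply(bm$annotations$center_s, bm$annotations$channel,
                        function(v) diff(sort(v))))
  expect_true(all(gaps >= 0.3 - 1e-9))
})

test_that("realized in-band SNR is within 1 dB of the target", {
  cfg <- synth_config(n_channels = 1, duration_s = 60, seed = 9)
  bm <- make_benchmark(cfg)
  fs <- cfg$fs_hz
  diff_sig <- bm$recording$samples[1, ] - bm$background$samples[1, ]
  bp_diff <- bandpass_filter(diff_sig, fs)
  bp_bg <- bandpass_filter(bm$background$samples[1, ], fs)
  ann <- bm$annotations
  for (i in seq_len(nrow(ann))) {
    support <- which(abs(diff_sig) > 0)
    c0 <- ann$center_sample[i]
    sup <- support[abs(support - c0) < 0.3 * fs]
    nb <- max(1, c0 - round(0.5 * fs)):min(length(bp_bg), c0 + round(0.5 * fs))
    snr <- 20 * log10(hfocluster:::rms(bp_diff[sup]) /
                        hfocluster:::rms(bp_bg[nb]))
    expect_lt(abs(snr - 15), 1)
  }
})

test_that("EDF files round-trip recordings and annotations round-trip CSV", {
  cfg <- synth_config(n_channels = 2, duration_s = 2, seed = 10)
  bm <- make_benchmark(cfg)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(bm$recording, f)
  rt <- read_edf(f)
  expect_equal(rt$fs_hz, bm$recording$fs_hz)
  expect_identical(rt$channel_labels, bm$recording$channel_labels)
  span <- max(bm$recording$samples) - min(bm$recording$samples)
  expect_lt(max(abs(rt$samples - bm$recording$samples)), span / 65536 * 1.01)
  g <- withr::local_tempfile(fileext = ".csv")
  write_annotations(bm$annotations, g)
  back <- read_annotations(g)
  expect_equal(back$center_sample, bm$annotations$center_sample)
  expect_equal(back$kind, bm$annotations$kind)
})
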