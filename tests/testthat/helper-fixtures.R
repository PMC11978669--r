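# Shared fixtures, computed lazily and cached for the whole test run.
# All inputs are generated in code under fixed seeds; nothing is read from
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small two-channel benchmark used across module tests (~2 min of signal)
small_benchmark <- function() {
  fixture("small_benchmark", {
    bm <- make_benchmark(synth_config(n_channels = 2, duration_s = 120,
                                      seed = 42))
    filtered <- preprocess_recording(bm$recording)
    cands <- match_candidates(detect_candidates_recording(filtered,
                                                          bm$recording),
                              bm$annotations)
    list(bm = bm, filtered = filtered, candidates = cands)
  })
}

# labelled stand-alone windows (fast R-TFM source for imaging/CVAE tests)
small_windows <- function() {
  fixture("small_windows",
          synth_candidate_windows(n_per_kind = 15, seed = 11))
}

small_rtfms <- function() {
  fixture("small_rtfms", {
    w <- small_windows()
    lapply(w$raw_window, window_rtfm, fs = w$fs_hz[1])
  })
}

# the full default benchmark + pipeline (the end-to-end acceptance state);
# heavy, so computed once and shared between acceptance blocks
acceptance_state <- function() {
  fixture("acceptance_state", {
    bm <- make_benchmark(synth_config(seed = 42))
    cfg <- pipeline_config(cvae = cvae_config(latent_dim = 50, epochs = 50,
                                              seed = 1))
    rep <- run_pipeline(bm$recording, cfg, annotations = bm$annotations)
    list(bm = bm, report = rep)
  })
}
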