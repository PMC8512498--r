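# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A single continuous self-paced walk: the steady-state condition used for
# detector-accuracy checks (no turns, no speed changes).
steady_walk <- function(duration_s = 45) {
  environment_preset("indoor",
                     bouts = data.frame(duration_s = duration_s,
                                        speed_kmh = NA_real_,
                                        speed_factor = 1),
                     gap_s = 0)
}

# Noise-free YA subject on a steady walk, with detections from both
# algorithms; reused by several files.
clean_ya_subject <- function() {
  fixture("clean_ya_subject", function() {
    sub <- simulate_subject("YA", steady_walk(), fs = 100, seed = 42,
                            noise = list(lumbar_sd = 0, shank_sd = 0,
                                         drift_rate = 0, tilt_deg = c(0, 0)))
    res <- suppressWarnings(analyze_subject(sub))
    list(subject = sub, result = res)
  })
}

# Ground-truth event series of a script, as one event_series per side.
truth_series <- function(script) {
  list(L = event_series("shank_left", "L", script$ic$L, script$fc$L),
       R = event_series("shank_right", "R", script$ic$R, script$fc$R))
}
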