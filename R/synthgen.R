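#' Configuration of the synthetic session generator
#'
#' The generator emulates the structure of rehabilitation movement
#' signals: bursty voluntary movements separated by rest, person- and
#' exercise-dependent amplitudes, slow drift across the session (fatigue or
#' game-level changes), additive sensor noise, and optional directional
#' asymmetry for unbalanced deficits.
#'
#' Defaults describe a plausible impaired-upper-limb session: a movement
#' roughly every three seconds (20 bursts/min, the cadence of continuous
#' game-driven exercise); stereotyped repetitions (log-normal burst
#' amplitudes, median 30 sensor units, sdlog 0.3 -- a patient's successive
#' movements are similar, with the best only modestly larger than the
#' typical); a large per-session amplitude scale spread (sdlog 0.6,
#' reflecting patient-to-patient and exercise-to-exercise differences in
#' impairment -- the variability that defeats any single fixed threshold);
#' 600 ms raised-cosine bursts (large voluntary movements take roughly
#' 300 ms each way); a quarter of the session spent at rest; mild
#' amplitude drift; and a noise floor combining sensor noise with resting
#' tremor.
#'
#' @param seed Integer seed; the whole session is a deterministic function
#'   of it.
#' @param duration Session length in seconds (>= 30, mirroring the minimum
#'   analysed session length).
#' @param sampling_rate Sampling rate in Hz (default 60).
#' @param signal_kind `"rotation"` (signed bursts), `"force"` or
#'   `"touch_speed"` (positive bursts).
#' @param burst_rate Movement bursts per minute.
#' @param amp_meanlog,amp_sdlog Log-normal burst amplitude parameters in
#'   raw sensor units.
#' @param burst_width Full width of the raised-cosine burst kernel in
#'   seconds.
#' @param session_scale_sd Log-scale standard deviation of a per-session
#'   amplitude multiplier (drawn once per session), emulating
#'   person-/exercise-dependent movement amplitude. 0 disables it.
#' @param rest_fraction Fraction of the session occupied by rest blocks,
#'   in `[0, 1)`.
#' @param drift Fractional amplitude change across the session (0.1 = 10%
#'   larger bursts at the end than at the start; negative for fatigue).
#' @param asymmetry Ratio of negative- to positive-direction burst
#'   amplitude (rotation only; 1 = balanced).
#' @param noise_sd Additive Gaussian noise standard deviation in raw
#'   sensor units.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, duration = 120, sampling_rate = 60,
                         signal_kind = c("rotation", "force", "touch_speed"),
                         burst_rate = 20, amp_meanlog = log(30),
                         amp_sdlog = 0.3, burst_width = 0.6,
                         session_scale_sd = 0.6, rest_fraction = 0.25,
                         drift = 0.1, asymmetry = 1, noise_sd = 1.5) {
  signal_kind <- match.arg(signal_kind)
  stop_if_not_scalar_number(duration, "duration", 30)
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  stop_if_not_scalar_number(burst_rate, "burst_rate", 0)
  stop_if_not_scalar_number(burst_width, "burst_width", 0, strict = TRUE)
  stop_if_not_scalar_number(session_scale_sd, "session_scale_sd", 0)
  stop_if_not_scalar_number(rest_fraction, "rest_fraction", 0)
  if (rest_fraction >= 1) stop("`rest_fraction` must be < 1", call. = FALSE)
  stop_if_not_scalar_number(asymmetry, "asymmetry", 0, strict = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  structure(
    list(seed = as.integer(seed), duration = duration,
         sampling_rate = sampling_rate, signal_kind = signal_kind,
         burst_rate = burst_rate, amp_meanlog = amp_meanlog,
         amp_sdlog = amp_sdlog, burst_width = burst_width,
         session_scale_sd = session_scale_sd,
         rest_fraction = rest_fraction, drift = drift,
         asymmetry = asymmetry, noise_sd = noise_sd),
    class = "synth_config"
  )
}

channel_for_kind <- function(kind) {
  switch(kind,
         rotation = list(label = "rotation_x", units = "degrees"),
         force = list(label = "force", units = "grams"),
         touch_speed = list(label = "touch_speed", units = "mm"))
}

#' Generate a synthetic rehabilitation session
#'
#' Builds the raw signal as a sum of raised-cosine burst kernels whose
#' onsets follow a Poisson process thinned by randomly placed rest blocks,
#' whose amplitudes are log-normal (scaled by a linear drift envelope and,
#' for rotation, signed with the configured asymmetry), plus additive
#' Gaussian noise. Deterministic given `config$seed`; the caller's RNG
#' state is untouched.
#'
#' @param config A [synth_config()].
#'
#' @return An object of class `synth_session`: list with `signal` (a
#'   [raw_signal()]), `annotations` (data frame of ground-truth bursts:
#'   `onset_s`, `peak_s`, `amplitude` after drift, `sign`), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    dur <- config$duration
    n <- as.integer(round(dur * fs)) + 1L
    t <- (0:(n - 1L)) / fs
    w <- config$burst_width
    # Per-session amplitude scale: who is exercising, and on what exercise,
    # sets the overall movement magnitude.
    session_scale <- if (config$session_scale_sd > 0) {
      rlnorm(1, 0, config$session_scale_sd)
    } else 1

    # Rest blocks of ~15 s covering roughly rest_fraction of the session.
    total_rest <- config$rest_fraction * dur
    rest <- NULL
    if (total_rest > 0) {
      n_rest <- max(1L, as.integer(round(total_rest / 15)))
      len <- total_rest / n_rest
      starts <- runif(n_rest, 0, max(0, dur - len))
      rest <- cbind(starts, starts + len)
    }
    in_rest <- function(x) {
      if (is.null(rest)) return(rep(FALSE, length(x)))
      out <- rep(FALSE, length(x))
      for (r in seq_len(nrow(rest))) {
        out <- out | (x >= rest[r, 1] & x <= rest[r, 2])
      }
      out
    }

    # Poisson onsets, rate compensated so the post-thinning count matches
    # burst_rate on average.
    lam <- config$burst_rate / 60 / max(1e-12, 1 - config$rest_fraction)
    n_cand <- rpois(1, lam * dur)
    onsets <- sort(runif(n_cand, 0, max(0, dur - w)))
    onsets <- onsets[!in_rest(onsets + w / 2)]
    m <- length(onsets)

    amp <- session_scale * rlnorm(m, config$amp_meanlog, config$amp_sdlog)
    sgn <- rep(1, m)
    if (config$signal_kind == "rotation" && m > 0) {
      sgn <- sample(c(1, -1), m, replace = TRUE)
      amp[sgn < 0] <- amp[sgn < 0] * config$asymmetry
    }
    peak_t <- onsets + w / 2
    env <- 1 + config$drift * (peak_t / dur)
    amp <- amp * env

    values <- numeric(n)
    for (b in seq_len(m)) {
      i0 <- max(1L, as.integer(ceiling(onsets[b] * fs)) + 1L)
      i1 <- min(n, as.integer(floor((onsets[b] + w) * fs)) + 1L)
      if (i1 < i0) next
      tt <- t[i0:i1] - onsets[b]
      values[i0:i1] <- values[i0:i1] +
        sgn[b] * amp[b] * 0.5 * (1 - cos(2 * pi * tt / w))
    }
    if (config$noise_sd > 0) values <- values + rnorm(n, 0, config$noise_sd)

    ch <- channel_for_kind(config$signal_kind)
    structure(
      list(signal = new_raw_signal(t, values, ch$label, fs, ch$units),
           annotations = data.frame(onset_s = onsets, peak_s = peak_t,
                                    amplitude = sgn * amp, sign = sgn),
           config = config),
      class = "synth_session"
    )
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> seed %d: %s, %.0f s at %g Hz, %d burst(s)\n",
    x$config$seed, x$config$signal_kind, x$config$duration,
    x$config$sampling_rate, nrow(x$annotations)))
  invisible(x)
}

#' Generate an at-rest calibration recording
#'
#' Noise-only signal (no movement bursts) emulating a control subject
#' holding the controller with the arm at rest; used to calibrate the
#' movement minimum.
#'
#' @param config A [synth_config()]; only its seed, duration, sampling
#'   rate, signal kind and noise level are used.
#'
#' @return A [raw_signal()].
#' @export
generate_rest_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- as.integer(round(config$duration * fs)) + 1L
    t <- (0:(n - 1L)) / fs
    values <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd)
              else numeric(n)
    ch <- channel_for_kind(config$signal_kind)
    new_raw_signal(t, values, ch$label, fs, ch$units)
  })
}

#' Calibrate the movement minimum for a synthetic configuration
#'
#' Generates `n_recordings` seeded rest recordings with the same noise
#' level as `config`, preprocesses them, and returns the mean of their
#' maximum absolute rates of change (see [estimate_movement_minimum()]).
#'
#' The first `settle` seconds of each preprocessed recording are discarded:
#' the causal smoothing and gradient windows are still growing there, so
#' the rate-of-change values reflect nearly unfiltered noise rather than
#' the steady-state noise floor the movement minimum is meant to capture.
#'
#' @param config A [synth_config()].
#' @param n_recordings Number of rest recordings (default 3).
#' @param seed Base seed for the rest recordings.
#' @param window_ms Preprocessing window in milliseconds.
#' @param settle Filter settling time to discard, in seconds (default 1).
#'
#' @return Movement minimum in rate-of-change units.
#' @export
calibrate_movement_minimum <- function(config, n_recordings = 3, seed = 1000,
                                       window_ms = 300, settle = 1) {
  rocs <- lapply(seq_len(n_recordings), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    cfg$duration <- 30
    raw <- generate_rest_recording(cfg)
    roc <- rate_of_change(smooth_signal(raw, window_ms), window_ms)
    keep <- roc$timestamps >= roc$timestamps[1] + settle
    roc_signal(roc$timestamps[keep], roc$values[keep],
               window_ms = roc$window_ms, source_channel = roc$source_channel,
               sampling_rate = roc$sampling_rate)
  })
  estimate_movement_minimum(rocs)
}

#' Generate a seeded cohort of synthetic sessions
#'
#' @param n_sessions Number of sessions.
#' @param seed Base seed; session i uses `seed + i`.
#' @param config Template [synth_config()]; its seed is overridden per
#'   session.
#'
#' @return List of `synth_session` objects.
#' @export
generate_cohort <- function(n_sessions, seed = 1, config = synth_config()) {
  lapply(seq_len(n_sessions), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    generate_session(cfg)
  })
}

#' Simulated therapist observer
#'
#' Models a trained observer who presses a stimulation button when a large
#' movement is seen: movements above a fraction of the largest movement
#' observed so far are candidates, each is missed with some probability,
#' the button press lags the movement peak by a reaction latency, and
#' consecutive presses are at least `min_isi` seconds apart.
#'
#' @param detection_fraction_of_max Candidate threshold as a fraction of
#'   the running maximum movement (default 0.4: a human observer rewards
#'   clearly-visible movements, not only near-maximal ones).
#' @param latency_mean,latency_sd Reaction latency distribution in seconds
#'   (normal, truncated at 0; defaults 1.0 and 0.4, a realistic
#'   see-decide-press delay).
#' @param min_isi Minimum interval between presses in seconds (default 5).
#' @param miss_probability Probability a candidate movement goes
#'   unstimulated (default 0.2: attention is shared with coaching the
#'   exercise).
#'
#' @return An object of class `therapist_model`.
#' @export
therapist_model <- function(detection_fraction_of_max = 0.4,
                            latency_mean = 1.0, latency_sd = 0.4,
                            min_isi = 5, miss_probability = 0.2) {
  stop_if_not_scalar_number(detection_fraction_of_max,
                            "detection_fraction_of_max", 0)
  if (detection_fraction_of_max > 1) {
    stop("`detection_fraction_of_max` must be in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(min_isi, "min_isi", 0)
  stop_if_not_scalar_number(miss_probability, "miss_probability", 0)
  if (miss_probability > 1) {
    stop("`miss_probability` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(detection_fraction_of_max = detection_fraction_of_max,
         latency_mean = latency_mean, latency_sd = latency_sd,
         min_isi = min_isi, miss_probability = miss_probability),
    class = "therapist_model"
  )
}

#' Simulate manually triggered stimulations
#'
#' Applies a [therapist_model()] to a rate-of-change signal: local movement
#' peaks above the detection threshold are stimulated with probability
#' `1 - miss_probability`, at the peak time plus a sampled reaction
#' latency, subject to the minimum inter-stimulus interval.
#'
#' @param roc A [roc_signal()] (gated signals restrict candidate peaks to
#'   supra-minimum samples).
#' @param model A [therapist_model()].
#' @param seed Seed for the miss/latency randomness.
#'
#' @return Trigger data frame with `algorithm = "manual"`; `paired_value`
#'   is `NA` until paired.
#' @export
simulate_manual_triggers <- function(roc, model, seed = 1) {
  stopifnot(inherits(roc, "roc_signal"), inherits(model, "therapist_model"))
  with_seed(seed, {
    a <- abs(roc$values)
    t <- roc$timestamps
    n <- length(a)
    if (n < 3L) return(trigger_events())
    supra <- roc$supra_minimum %||% rep(TRUE, n)
    runmax <- cummax(a)
    i <- 2:(n - 1L)
    is_peak <- c(FALSE, a[i] > a[i - 1L] & a[i] >= a[i + 1L], FALSE)
    cand <- which(is_peak & supra &
                    a >= model$detection_fraction_of_max * runmax)
    end_t <- t[n]
    times <- numeric(0)
    last <- -Inf
    for (j in cand) {
      if (runif(1) < model$miss_probability) next
      lat <- max(0, rnorm(1, model$latency_mean, model$latency_sd))
      tt <- t[j] + lat
      if (tt > end_t) next
      if (tt - last >= model$min_isi - 1e-9) {
        times <- c(times, tt)
        last <- tt
      }
    }
    k <- length(times)
    trigger_events(
      time = times, paired_value = rep(NA_real_, k),
      threshold = rep(NA_real_, k), algorithm = rep("manual", k),
      direction = rep("n/a", k), buffer_rank = rep(NA_real_, k)
    )
  })
}

#' Pick the static multiplier whose median rate matches a target
#'
#' Mirrors the rate-matching used when comparing algorithms: among the
#' candidate movement-minimum multipliers, choose the one whose cohort
#' median triggering rate is closest to the target (e.g. the dynamic
#' algorithm's median rate).
#'
#' @param rocs List of gated [roc_signal()] sessions.
#' @param movement_minimum Calibrated noise floor (> 0).
#' @param target_rate Target median rate in triggers/minute.
#' @param candidates Candidate multipliers (default `c(1, 2, 4, 8, 16,
#'   32)`).
#' @param min_isi Minimum inter-stimulus interval passed to the static
#'   algorithm.
#'
#' @return The selected multiplier.
#' @export
match_static_multiplier <- function(rocs, movement_minimum, target_rate,
                                    candidates = c(1, 2, 4, 8, 16, 32),
                                    min_isi = 5) {
  med_rates <- vapply(candidates, function(m) {
    p <- static_params(multiplier = m, movement_minimum = movement_minimum,
                       min_isi = min_isi)
    stats::median(vapply(rocs, function(r) {
      triggering_rate(run_static(r, p), diff(range(r$timestamps)))
    }, numeric(1)))
  }, numeric(1))
  candidates[which.min(abs(med_rates - target_rate))]
}
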