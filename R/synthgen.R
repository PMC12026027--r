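#' Generate a balanced, randomized motor-imagery paradigm schedule
#'
#' Builds the trial schedule of a cued motor-imagery session: `sets` blocks
#' of `trials_per_set` trials, each trial one imagery cue followed by a rest
#' period. Within every set each task appears exactly
#' `trials_per_set / length(tasks)` times, in seeded random order.
#'
#' @param sets Number of sets (blocks). Default 5.
#' @param trials_per_set Trials per set; must be divisible by the number of
#'   tasks. Default 40.
#' @param tasks Character vector of task labels. Default the four classical
#'   imagery classes.
#' @param imagery_s Imagery (cue) duration in seconds. Default 7.
#' @param rest_s Rest duration in seconds. Default 5.
#' @param seed Integer seed controlling the task order.
#' @return An object of class `paradigm_schedule`: a list with a `trials`
#'   data.frame (`set`, `task`, `imagery_s`, `rest_s`) plus the call
#'   parameters.
#' @export
#' @examples
#' sched <- generate_paradigm(seed = 1)
#' nrow(sched$trials)        # 200
#' table(sched$trials$task)  # 50 each
generate_paradigm <- function(sets = 5, trials_per_set = 40,
                              tasks = c("left_hand", "right_hand", "foot", "tongue"),
                              imagery_s = 7, rest_s = 5, seed = 1) {
  stopifnot(sets >= 1, trials_per_set >= 1, length(tasks) >= 1,
            imagery_s > 0, rest_s >= 0)
  if (trials_per_set %% length(tasks) != 0) {
    stop("trials_per_set (", trials_per_set, ") must be divisible by the ",
         "number of tasks (", length(tasks), ") to balance the schedule")
  }
  per_task <- trials_per_set %/% length(tasks)
  trials <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(sets), function(s) {
      order <- sample(rep(tasks, per_task))
      data.frame(set = s, task = order,
                 imagery_s = imagery_s, rest_s = rest_s,
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(trials = trials, sets = sets,
                 trials_per_set = trials_per_set, tasks = tasks,
                 imagery_s = imagery_s, rest_s = rest_s, seed = seed),
            class = "paradigm_schedule")
}

#' Specification of a synthetic EEG recording
#'
#' Describes everything needed to simulate one subject: the montage,
#' sampling rate, ground-truth phase-lagged couplings, event-related
#' desynchronization (ERD) entries, and the pink-noise background.
#'
#' @param montage Ordered channel names.
#' @param fs Sampling rate in Hz; must exceed twice the highest coupling
#'   band edge.
#' @param coupling `data.frame` with columns `from`, `to`, `f_lo`, `f_hi`,
#'   `phase_lag` (radians), `strength` (0-1 mixing weight of the lagged copy
#'   into `to`), and `task` (`NA` = always on; otherwise active only during
#'   that task's imagery windows).
#' @param erd `data.frame` with columns `task`, `channels` (list-column or
#'   comma-separated string), `f_lo`, `f_hi`, `attenuation` (0-1 multiplier
#'   applied to the oscillatory band amplitude inside matching imagery
#'   windows; 1 = fully suppressed).
#' @param oscillations `data.frame` with columns `f_lo`, `f_hi`, `amplitude`
#'   describing the background band-limited rhythms present on every
#'   channel. Default: one 8-30 Hz rhythm of unit amplitude.
#' @param noise_exponent Pink-noise spectral slope (power ~ 1/f^exponent).
#' @param snr Linear ratio of oscillatory RMS to noise RMS.
#' @param amp_jitter_sd Log-normal standard deviation of the slowly varying
#'   (about 1 s timescale) amplitude envelope each oscillation waxes and
#'   wanes with; 0 disables it.
#' @param seed Integer seed.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(montage = standard_montage(), fs = 1000,
                       coupling = NULL, erd = NULL,
                       oscillations = data.frame(f_lo = 8, f_hi = 30, amplitude = 1),
                       noise_exponent = 1, snr = 1, amp_jitter_sd = 0.5,
                       seed = 1) {
  if (is.null(coupling)) {
    coupling <- data.frame(from = character(), to = character(),
                           f_lo = numeric(), f_hi = numeric(),
                           phase_lag = numeric(), strength = numeric(),
                           task = character(), stringsAsFactors = FALSE)
  }
  if (is.null(erd)) {
    erd <- data.frame(task = character(), channels = character(),
                      f_lo = numeric(), f_hi = numeric(),
                      attenuation = numeric(), stringsAsFactors = FALSE)
  }
  bad <- setdiff(c(coupling$from, coupling$to), montage)
  if (length(bad)) stop("coupling channels not in montage: ",
                        paste(bad, collapse = ", "))
  erd_chans <- unlist(strsplit(as.character(erd$channels), ","))
  bad <- setdiff(trimws(erd_chans), montage)
  if (length(bad)) stop("erd channels not in montage: ",
                        paste(bad, collapse = ", "))
  if (nrow(coupling) && any(coupling$strength < 0 | coupling$strength > 1))
    stop("coupling strength must lie in [0, 1]")
  if (nrow(erd) && any(erd$attenuation < 0 | erd$attenuation > 1))
    stop("erd attenuation must lie in [0, 1]")
  fmax <- max(c(oscillations$f_hi, coupling$f_hi, 0))
  if (fs <= 2 * fmax)
    stop("fs (", fs, " Hz) must exceed twice the highest band edge (",
         fmax, " Hz)")
  structure(list(montage = montage, fs = fs, coupling = coupling, erd = erd,
                 oscillations = oscillations, noise_exponent = noise_exponent,
                 snr = snr, amp_jitter_sd = amp_jitter_sd, seed = seed),
            class = "synth_spec")
}

#' Construct a recording container
#'
#' A continuous multi-channel signal with channel names, sampling rate and
#' imagery-onset event markers.
#'
#' @param data channels x samples numeric matrix (nominal microvolts).
#' @param channel_names one name per row of `data`.
#' @param fs sampling rate, Hz.
#' @param events `data.frame` with columns `sample` (1-based onset index,
#'   strictly increasing) and `task`.
#' @return Object of class `recording`.
#' @export
recording <- function(data, channel_names, fs, events = NULL) {
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") must equal the number of data rows (", nrow(data), ")")
  if (is.null(events))
    events <- data.frame(sample = integer(), task = character())
  if (nrow(events)) {
    if (is.unsorted(events$sample, strictly = TRUE))
      stop("event sample indices must be strictly increasing")
    if (any(events$sample < 1 | events$sample > ncol(data)))
      stop("event sample indices out of bounds")
  }
  structure(list(data = data, channel_names = as.character(channel_names),
                 fs = fs, events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise,
# normalized to unit RMS.
pink_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                   # mirror for negative freqs
  spec <- spec / f^(exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited oscillator: sinusoid whose instantaneous frequency wanders
# uniformly inside [f_lo, f_hi] (random-phase-walk model). Returns the
# instantaneous phase so that lagged copies share the same phase track.
oscillator_phase <- function(n, fs, f_lo, f_hi) {
  freq <- stats::runif(ceiling(n / fs) + 1, f_lo, f_hi)
  # interpolate the slowly-varying frequency track to sample resolution
  freq_t <- stats::approx(seq(0, length(freq) - 1) * fs + 1, freq,
                          xout = seq_len(n), rule = 2)$y
  cumsum(2 * pi * freq_t / fs) + stats::runif(1, 0, 2 * pi)
}

# Slowly varying log-normal amplitude envelope (~1 s timescale), modelling
# the waxing and waning of spontaneous rhythms.
oscillator_envelope <- function(n, fs, sd) {
  if (sd <= 0) return(rep(1, n))
  z <- stats::rnorm(ceiling(n / fs) + 1, 0, sd)
  zt <- stats::approx(seq(0, length(z) - 1) * fs + 1, z,
                      xout = seq_len(n), rule = 2)$y
  exp(zt - sd^2 / 2)
}

#' Simulate a synthetic EEG recording for a paradigm schedule
#'
#' Each channel is pink noise plus band-limited oscillations. Coupling
#' entries mix a phase-lagged copy of the source channel's band oscillation
#' into the target channel (optionally only inside one task's imagery
#' windows), giving a known ground-truth phase-lag structure that the WPLI
#' estimator should recover. ERD entries attenuate a band's amplitude on
#' selected channels during matching imagery windows, giving
#' class-discriminable power patterns.
#'
#' @param schedule A [generate_paradigm()] schedule.
#' @param spec A [synth_spec()].
#' @return A [recording()] covering the full schedule, with one event per
#'   imagery onset.
#' @export
simulate_recording <- function(schedule, spec) {
  stopifnot(inherits(schedule, "paradigm_schedule"), inherits(spec, "synth_spec"))
  fs <- spec$fs
  tr <- schedule$trials
  trial_samps <- round((tr$imagery_s + tr$rest_s) * fs)
  onsets <- cumsum(c(1, trial_samps[-length(trial_samps)]))
  n <- sum(trial_samps)
  if (n > 2^31 - 1) stop("schedule too long to represent at fs = ", fs)
  nch <- length(spec$montage)

  # per-task imagery-window masks
  task_mask <- function(task) {
    m <- logical(n)
    idx <- which(tr$task == task)
    for (i in idx) {
      m[onsets[i]:(onsets[i] + round(tr$imagery_s[i] * fs) - 1)] <- TRUE
    }
    m
  }
  masks <- lapply(unique(tr$task), task_mask)
  names(masks) <- unique(tr$task)

  with_seed(spec$seed, {
    data <- matrix(0, nch, n)
    rownames(data) <- spec$montage
    # oscillatory components kept separately per channel per band so ERD and
    # coupling can act on them before summation
    for (b in seq_len(nrow(spec$oscillations))) {
      f_lo <- spec$oscillations$f_lo[b]
      f_hi <- spec$oscillations$f_hi[b]
      amp <- spec$oscillations$amplitude[b]
      phases <- lapply(seq_len(nch), function(i) oscillator_phase(n, fs, f_lo, f_hi))
      envs <- lapply(seq_len(nch), function(i)
        oscillator_envelope(n, fs, spec$amp_jitter_sd))
      comp <- lapply(seq_len(nch), function(i)
        amp * envs[[i]] * cos(phases[[i]]))

      # coupling: replace part of the target's band component with a
      # phase-lagged copy of the source's (the source's own envelope and
      # phase track, so sources must not themselves be coupling targets)
      cp <- spec$coupling
      if (nrow(cp)) {
        if (length(intersect(cp$from, cp$to)))
          warning("coupling sources that are also targets keep their ",
                  "original phase track as sources")
        for (k in seq_len(nrow(cp))) {
          if (!(cp$f_lo[k] >= f_lo && cp$f_hi[k] <= f_hi)) next
          ia <- match(cp$from[k], spec$montage)
          ib <- match(cp$to[k], spec$montage)
          lagged <- amp * envs[[ia]] * cos(phases[[ia]] - cp$phase_lag[k])
          s <- cp$strength[k]
          mixed <- (1 - s) * comp[[ib]] + s * lagged
          tk <- cp$task[k]
          if (is.na(tk) || tk == "") {
            comp[[ib]] <- mixed
          } else {
            m <- masks[[tk]]
            comp[[ib]][m] <- mixed[m]
          }
        }
      }

      # ERD: attenuate band amplitude inside matching imagery windows
      ed <- spec$erd
      if (nrow(ed)) {
        for (k in seq_len(nrow(ed))) {
          if (!(ed$f_lo[k] >= f_lo && ed$f_hi[k] <= f_hi)) next
          chans <- trimws(unlist(strsplit(as.character(ed$channels[k]), ",")))
          m <- masks[[ed$task[k]]]
          gain <- 1 - ed$attenuation[k]
          for (ch in chans) {
            i <- match(ch, spec$montage)
            comp[[i]][m] <- comp[[i]][m] * gain
          }
        }
      }
      for (i in seq_len(nch)) data[i, ] <- data[i, ] + comp[[i]]
    }
    osc_rms <- stats::sd(as.vector(data[1, ]))
    noise_amp <- if (spec$snr > 0) osc_rms / spec$snr else 0
    for (i in seq_len(nch)) {
      data[i, ] <- data[i, ] + noise_amp * pink_noise(n, spec$noise_exponent)
    }
    recording(data, spec$montage, fs,
              events = data.frame(sample = onsets, task = tr$task,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate a cohort of subjects
#'
#' Generates one recording per subject. `spec_generator` maps the subject
#' index to a [synth_spec()]; varying, e.g., coupling strength across
#' subjects creates a ground-truth adaptability gradient for recovery tests.
#' Per-subject seeds are derived from `seed` by a fixed counter scheme, so
#' cohorts are reproducible and subjects mutually independent.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param spec_generator `function(i)` returning a [synth_spec()]; its `seed`
#'   field is overridden by the derived substream seed.
#' @param schedule Shared paradigm schedule (default the full paradigm).
#' @param seed Master integer seed.
#' @return List of [recording()] objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects, spec_generator,
                            schedule = generate_paradigm(), seed = 1) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec_generator(i)
    stopifnot(inherits(sp, "synth_spec"))
    sp$seed <- substream_seed(seed, i)
    simulate_recording(schedule, sp)
  })
}

#' Write / read a recording as a plain tab-separated table
#'
#' Debug-friendly text round-trip: one row per sample, one column per
#' channel, with `# key=value` metadata lines (sampling rate, events) ahead
#' of the header.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  ev <- paste(sprintf("%d:%s", rec$events$sample, rec$events$task),
              collapse = ";")
  writeLines(paste0("# events=", ev), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_names, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("^# fs=", "", hdr[1]))
  evs <- sub("^# events=", "", hdr[2])
  events <- NULL
  if (nzchar(evs)) {
    parts <- strsplit(strsplit(evs, ";")[[1]], ":")
    events <- data.frame(sample = as.integer(vapply(parts, `[`, "", 1)),
                         task = vapply(parts, `[`, "", 2),
                         stringsAsFactors = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                           check.names = FALSE)
  recording(t(as.matrix(tab)), colnames(tab), fs, events)
}
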