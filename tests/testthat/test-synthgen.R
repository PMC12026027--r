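test_that("paradigm schedules are balanced, sized and deterministic", {
  sched <- generate_paradigm(sets = 5, trials_per_set = 40, seed = 7)
  expect_equal(nrow(sched$trials), 200)
  expect_true(all(table(sched$trials$task) == 50))
  # exact balance within every set
  per_set <- table(sched$trials$set, sched$trials$task)
  expect_true(all(per_set == 10))

  tiny <- generate_paradigm(sets = 1, trials_per_set = 4, seed = 1)
  expect_true(all(table(tiny$trials$task) == 1))

  a <- generate_paradigm(seed = 42)
  b <- generate_paradigm(seed = 42)
  expect_identical(a, b)
  c <- generate_paradigm(seed = 43)
  expect_false(identical(a$trials$task, c$trials$task))

  expect_error(generate_paradigm(trials_per_set = 39), "divisible")
})

test_that("simulated recordings match the montage, rate and schedule", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 4,
                             imagery_s = 2, rest_s = 1, seed = 1)
  sp <- synth_spec(fs = 1000, seed = 2)
  rec <- simulate_recording(sched, sp)
  expect_s3_class(rec, "recording")
  expect_equal(nrow(rec$data), 60)
  expect_equal(rec$fs, 1000)
  expect_equal(ncol(rec$data), 4 * 3 * 1000)
  expect_equal(nrow(rec$events), 4)
  expect_identical(rec$events$task, sched$trials$task)
  expect_true(!is.unsorted(rec$events$sample, strictly = TRUE))
})

test_that("synth spec validates channels, strengths and Nyquist", {
  expect_error(synth_spec(coupling = data.frame(
    from = "XX", to = "C4", f_lo = 8, f_hi = 12, phase_lag = 0,
    strength = 1, task = NA)), "not in montage")
  expect_error(synth_spec(coupling = data.frame(
    from = "C3", to = "C4", f_lo = 8, f_hi = 12, phase_lag = 0,
    strength = 1.4, task = NA)), "strength")
  expect_error(synth_spec(fs = 50), "Nyquist|twice")
})

test_that("planted phase-lag coupling is recovered by the WPLI estimator", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 8,
                             imagery_s = 4, rest_s = 1, seed = 3)
  cp <- data.frame(from = "C3", to = "C4", f_lo = 8, f_hi = 12,
                   phase_lag = pi / 2, strength = 1, task = NA,
                   stringsAsFactors = FALSE)
  mont <- standard_montage()[21:36]   # 16-channel strip, keeps it fast
  sp <- synth_spec(montage = mont, fs = 250, coupling = cp,
                   oscillations = data.frame(f_lo = 8, f_hi = 12,
                                             amplitude = 1),
                   snr = 2, seed = 4)
  rec <- simulate_recording(sched, sp)
  ep <- extract_epochs(rec, c(0.5, 3), per_task_keep = NULL)
  W <- wpli_matrix(ep, c(8, 12))$W
  expect_gt(W["C3", "C4"], 0.8)
  others <- W[upper.tri(W)]
  others <- others[others < W["C3", "C4"]]
  expect_lt(stats::median(others), 0.2)
})

test_that("ERD entries attenuate band power during matching task windows", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 8,
                             imagery_s = 3, rest_s = 3, seed = 5)
  erd <- data.frame(task = "left_hand", channels = "C3,C5",
                    f_lo = 8, f_hi = 12, attenuation = 0.8,
                    stringsAsFactors = FALSE)
  mont <- c("C3", "C5", "C4")
  sp <- synth_spec(montage = mont, fs = 250, erd = erd,
                   oscillations = data.frame(f_lo = 8, f_hi = 12,
                                             amplitude = 1),
                   snr = 10, amp_jitter_sd = 0, seed = 6)
  rec <- simulate_recording(sched, sp)
  band_var <- function(idx) {
    seg <- rec$data["C3", idx]
    stats::var(miadapt:::fir_apply_zerophase(
      seg, miadapt:::design_fir_bandpass(250, 8, 12, 2)))
  }
  ev <- rec$events
  lh <- which(ev$task == "left_hand")
  other <- which(ev$task == "foot")
  v_lh <- mean(sapply(lh, function(i) band_var(ev$sample[i] + 0:749)))
  v_ot <- mean(sapply(other, function(i) band_var(ev$sample[i] + 0:749)))
  # attenuation 0.8 scales amplitude by 0.2 -> power by 0.04; allow noise slack
  expect_lt(v_lh / v_ot, 0.25)
})

test_that("cohorts are reproducible and subject count is honoured", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 4,
                             imagery_s = 1, rest_s = 0.5, seed = 1)
  gen <- function(i) synth_spec(montage = c("C3", "C4"), fs = 250,
                                oscillations = data.frame(
                                  f_lo = 8, f_hi = 12, amplitude = 1))
  co1 <- simulate_cohort(3, gen, schedule = sched, seed = 9)
  co2 <- simulate_cohort(3, gen, schedule = sched, seed = 9)
  co3 <- simulate_cohort(3, gen, schedule = sched, seed = 10)
  expect_length(co1, 3)
  expect_identical(co1, co2)
  expect_false(identical(co1[[1]]$data, co3[[1]]$data))
  # subjects are distinct substreams
  expect_false(identical(co1[[1]]$data, co1[[2]]$data))
  # single subject equals direct simulation with the derived seed
  sp <- gen(1); sp$seed <- miadapt:::substream_seed(9, 1)
  expect_identical(co1[[1]], simulate_recording(sched, sp))
})

test_that("recordings round-trip through the tabular text export", {
  rec <- recording(matrix(round(stats::rnorm(60), 6), 3, 20),
                   c("C3", "CZ", "C4"), 250,
                   data.frame(sample = c(3L, 11L),
                              task = c("left_hand", "tongue")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$events, rec$events)
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-6)
})

test_that("recording container validates events and channel names", {
  expect_error(recording(matrix(0, 2, 10), "C3", 250), "channel_names")
  expect_error(recording(matrix(0, 2, 10), c("C3", "C4"), 250,
                         data.frame(sample = c(5L, 2L),
                                    task = c("a", "b"))),
               "increasing")
  expect_error(recording(matrix(0, 2, 10), c("C3", "C4"), 250,
                         data.frame(sample = 99L, task = "a")),
               "bounds")
})
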