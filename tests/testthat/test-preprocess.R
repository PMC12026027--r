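make_rec <- function(nch = 4, ns = 1000, fs = 250, seed = 1) {
  set.seed(seed)
  recording(matrix(stats::rnorm(nch * ns), nch, ns),
            standard_montage()[seq_len(nch)], fs,
            data.frame(sample = 100L, task = "left_hand"))
}

test_that("average re-reference zeroes the channel mean and is idempotent", {
  rec <- make_rec(5)
  rr <- rereference_average(rec)
  expect_lt(max(abs(colMeans(rr$data))), 1e-12)
  rr2 <- rereference_average(rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  # two-channel closed form: ((a-b)/2, (b-a)/2)
  two <- recording(rbind(a = 1:5, b = rep(0, 5)) * 1.0, c("C3", "C4"), 250)
  rr3 <- rereference_average(two)
  expect_equal(unname(rr3$data[1, ]), (1:5) / 2)
  expect_equal(unname(rr3$data[2, ]), -(1:5) / 2)
  expect_error(rereference_average(recording(matrix(0, 1, 10), "CZ", 250)),
               "single channel")
})

test_that("FIR design follows the order rule and band behaviour", {
  b <- miadapt:::design_fir_bandpass(1000, 1, 40, 1)
  expect_length(b, 3001)          # order 3 * 1000 / 1 = 3000
  b2 <- miadapt:::design_fir_bandpass(250, 8, 12, 2)
  expect_length(b2, 376 + 1)      # 3 * 250 / 2 = 375 -> nearest even 376

  fs <- 1000
  tt <- seq_len(8 * fs) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * tt)), "CZ", fs)
  out <- bandpass_fir(rec, 1, 40, 1)
  mid <- out$data[1, 3000:5000]
  expect_lt(abs(max(abs(mid)) - 1), 0.05)     # passband amplitude within 5%

  rec50 <- recording(rbind(sin(2 * pi * 50 * tt)), "CZ", fs)
  out50 <- bandpass_fir(rec50, 1, 40, 1)
  expect_lt(stats::sd(out50$data[1, 3000:5000]) /
              stats::sd(rec50$data[1, 3000:5000]), 0.10)

  expect_error(bandpass_fir(rec, 40, 1), "band edges")
  expect_error(bandpass_fir(rec, 1, 600), "band edges")
})

test_that("zero-phase filtering introduces no delay", {
  fs <- 250
  tt <- seq_len(4 * fs) / fs
  x <- sin(2 * pi * 10 * tt)
  y <- miadapt:::fir_apply_zerophase(
    x, miadapt:::design_fir_bandpass(fs, 8, 12, 2))
  cc <- stats::ccf(y[200:800], x[200:800], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("downsampling divides sample counts and preserves spectra", {
  rec <- make_rec(2, ns = 4000, fs = 1000)
  ds <- downsample(rec, 250)
  expect_equal(ncol(ds$data), 1000)
  expect_equal(ds$fs, 250)
  expect_equal(ds$events$sample, 25L)
  expect_identical(downsample(rec, 1000), rec)
  expect_error(downsample(rec, 300), "integer multiple")

  fs <- 1000
  tt <- seq_len(4 * fs) / fs
  tone <- recording(rbind(sin(2 * pi * 20 * tt)), "CZ", fs)
  dtone <- downsample(tone, 250)
  spec <- Mod(stats::fft(dtone$data[1, ]))[1:500]
  peak_hz <- (which.max(spec) - 1) * 250 / ncol(dtone$data)
  expect_equal(peak_hz, 20, tolerance = 0.5)
})

test_that("channel selection orders channels and interpolates bad ones", {
  full <- standard_montage()
  set.seed(2)
  rec <- recording(matrix(stats::rnorm(60 * 500), 60, 500), full, 250)
  out <- select_and_interpolate(rec, keep = full)
  expect_identical(out$channel_names, full)
  expect_equal(out$data, rec$data[match(full, rec$channel_names), ],
               ignore_attr = TRUE)

  # bad channel rebuilt from neighbours carrying a common sinusoid
  tt <- seq_len(500) / 250
  sine <- sin(2 * pi * 10 * tt)
  rec2 <- rec
  for (ch in c("C5", "C1", "FC3", "CP3")) rec2$data[match(ch, full), ] <- sine
  out2 <- select_and_interpolate(rec2, keep = full, bad = "C3")
  expect_equal(unname(out2$data["C3", ]), sine, tolerance = 1e-9)

  expect_warning(select_and_interpolate(rec, keep = c("C3", "C4", "CZ"),
                                        bad = "O1"), "skipped")
  expect_error(select_and_interpolate(rec, keep = c("C3", "NOPE")),
               "absent")
})

test_that("epoch extraction yields the requested window and retention", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 8,
                             imagery_s = 4, rest_s = 1, seed = 1)
  sp <- synth_spec(montage = c("C3", "CZ", "C4"), fs = 250,
                   oscillations = data.frame(f_lo = 8, f_hi = 12,
                                             amplitude = 1), seed = 2)
  rec <- simulate_recording(sched, sp)
  ep <- extract_epochs(rec, window = c(1, 3), per_task_keep = 2)
  expect_equal(dim(ep$data), c(8, 3, 750))
  expect_true(all(table(ep$labels) == 2))
  # retention is deterministic
  ep2 <- extract_epochs(rec, window = c(1, 3), per_task_keep = 2)
  expect_identical(ep$data, ep2$data)
  # retention prefers low peak-to-peak epochs
  rec_art <- rec
  i1 <- rec$events$sample[rec$events$task == rec$events$task[1]][1]
  rec_art$data[1, i1 + 300] <- 1e4        # artifact in first matching trial
  ep3 <- extract_epochs(rec_art, window = c(1, 3), per_task_keep = 1)
  expect_true(max(abs(ep3$data)) < 1e3)
  expect_error(extract_epochs(rec, window = c(1, 10)), "outside")
  expect_error(extract_epochs(rec, window = c(1, 3), per_task_keep = 5),
               "only")
})

test_that("re-referencing and filtering commute (both linear)", {
  rec <- make_rec(4, ns = 2000, fs = 250, seed = 3)
  a <- bandpass_fir(rereference_average(rec), 8, 12, 2)
  b <- rereference_average(bandpass_fir(rec, 8, 12, 2))
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("the full preprocessing chain reproduces the canonical block", {
  sched <- generate_paradigm(sets = 1, trials_per_set = 4,
                             imagery_s = 4, rest_s = 1, seed = 4)
  sp <- synth_spec(fs = 1000, seed = 5)
  rec <- simulate_recording(sched, sp)
  ep <- preprocess_recording(rec, per_task_keep = 1, window = c(1, 3))
  expect_equal(dim(ep$data), c(4, 60, 750))   # 3 s at 250 Hz = 750 samples
  expect_equal(ep$fs, 250)
  expect_identical(ep$channel_names, standard_montage())
})
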