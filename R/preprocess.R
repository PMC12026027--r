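#' Average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel
#' (whole-electrode average reference). After the operation the per-sample
#' channel mean is zero; applying it twice equals applying it once.
#'
#' @param rec A [recording()] with at least two channels.
#' @return Re-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2)
    stop("average reference is degenerate for a single channel")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# Hanning-windowed linear-phase FIR band-pass design following the
# order rule: order = 3 * fs / transition_bw, rounded to the nearest even
# integer (type-I symmetric filter, exactly compensable group delay).
design_fir_bandpass <- function(fs, f_lo, f_hi, transition_bw = 1) {
  if (!(0 < f_lo && f_lo < f_hi && f_hi < fs / 2))
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2 (got ",
         f_lo, "-", f_hi, " at fs ", fs, ")")
  order <- 3 * fs / transition_bw
  order <- 2 * round(order / 2)
  w <- c(f_lo, f_hi) / (fs / 2)
  signal::fir1(order, w, type = "pass",
               window = signal::hanning(order + 1))
}

# Zero-phase application of a symmetric odd-length FIR: single FFT-based
# convolution with exact group-delay (order/2) compensation. Edges are
# reflection-padded to curb boundary transients.
fir_apply_zerophase <- function(x, b) {
  as.vector(fir_apply_zerophase_mat(matrix(x, nrow = 1), b))
}

# Matrix form: rows are signals, filtered jointly by one FFT batch.
fir_apply_zerophase_mat <- function(X, b) {
  n <- ncol(X)
  L <- length(b)
  half <- (L - 1) / 2
  pad <- min(half, n - 1)
  Xe <- cbind(X[, (pad + 1):2, drop = FALSE], X,
              X[, (n - 1):(n - pad), drop = FALSE])
  ne <- ncol(Xe)
  nfft <- stats::nextn(ne + L - 1, 2)
  Bf <- stats::fft(c(b, numeric(nfft - L)))
  Xf <- stats::mvfft(rbind(t(Xe), matrix(0, nfft - ne, nrow(X))))
  Y <- Re(stats::mvfft(Xf * Bf, inverse = TRUE)) / nfft
  t(Y)[, (half + pad + 1):(half + pad + n), drop = FALSE]
}

#' FIR band-pass filtering of a recording
#'
#' Hanning-windowed finite impulse response band-pass with filter order
#' three times the ratio of sampling rate to transition bandwidth (rounded
#' to the nearest even integer), applied with zero phase so that epoch
#' timing is preserved.
#'
#' @param rec A [recording()].
#' @param f_lo,f_hi Pass-band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param transition_bw Transition bandwidth in Hz (default 1).
#' @return Filtered [recording()].
#' @export
bandpass_fir <- function(rec, f_lo = 1, f_hi = 40, transition_bw = 1) {
  stopifnot(inherits(rec, "recording"))
  b <- design_fir_bandpass(rec$fs, f_lo, f_hi, transition_bw)
  rec$data <- fir_apply_zerophase_mat(rec$data, b)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Downsample a recording by an integer factor
#'
#' Keeps every `fs / target_fs`-th sample and rescales event indices. The
#' signal is assumed already low-passed below the target Nyquist (the
#' standard pipeline band-passes to 1-40 Hz before decimating to 250 Hz).
#'
#' @param rec A [recording()].
#' @param target_fs Target rate; `fs` must be an integer multiple.
#' @return Downsampled [recording()].
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "recording"))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs (", rec$fs, ") must be an integer multiple of target_fs (",
         target_fs, ")")
  ratio <- round(ratio)
  if (ratio == 1) return(rec)
  keep <- seq(1, ncol(rec$data), by = ratio)
  ev <- rec$events
  if (nrow(ev)) ev$sample <- pmax(1L, as.integer(ceiling(ev$sample / ratio)))
  recording(rec$data[, keep, drop = FALSE], rec$channel_names, target_fs, ev)
}

#' Channel selection and bad-channel interpolation
#'
#' Restricts a recording to the `keep` channels in the given (canonical)
#' order, replacing each `bad` channel by the inverse-distance-weighted
#' average of its 4 nearest neighbours in the projected 10-20 layout.
#'
#' @param rec A [recording()].
#' @param keep Channels to retain, in output order (default the standard
#'   60-channel montage).
#' @param bad Channels within `keep` to reconstruct from neighbours.
#' @param n_neighbors Number of nearest good channels used (default 4).
#' @return [recording()] with channels exactly `keep`.
#' @export
select_and_interpolate <- function(rec, keep = standard_montage(),
                                   bad = character(), n_neighbors = 4) {
  stopifnot(inherits(rec, "recording"))
  missing <- setdiff(keep, rec$channel_names)
  if (length(missing))
    stop("keep channels absent from recording: ",
         paste(missing, collapse = ", "))
  not_kept <- setdiff(bad, keep)
  if (length(not_kept)) {
    warning("bad channels not in keep list, skipped: ",
            paste(not_kept, collapse = ", "))
    bad <- intersect(bad, keep)
  }
  data <- rec$data[match(keep, rec$channel_names), , drop = FALSE]
  rownames(data) <- keep
  if (length(bad)) {
    xy <- montage_coordinates(keep)
    good <- setdiff(keep, bad)
    for (ch in bad) {
      d <- sqrt(rowSums(sweep(xy[good, , drop = FALSE], 2, xy[ch, ])^2))
      nb <- names(sort(d))[seq_len(min(n_neighbors, length(good)))]
      w <- 1 / d[nb]
      w <- w / sum(w)
      data[ch, ] <- as.vector(w %*% data[nb, , drop = FALSE])
    }
  }
  recording(data, keep, rec$fs, rec$events)
}

#' Epoched, task-labelled data block
#'
#' @param data epochs x channels x samples array.
#' @param labels task label per epoch.
#' @param fs sampling rate, Hz.
#' @param channel_names channel names, length = dim 2.
#' @param window `(offset_s, length_s)` of the epoch window relative to
#'   imagery onset.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_names, window) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels),
            dim(data)[2] == length(channel_names),
            dim(data)[3] == round(window[2] * fs))
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 channel_names = as.character(channel_names),
                 window = window),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Extract task epochs from a continuous recording
#'
#' Cuts a fixed window relative to each imagery onset and retains, per task,
#' the `per_task_keep` epochs with the smallest peak-to-peak amplitude (a
#' deterministic, artifact-motivated proxy for manual trial rejection),
#' tie-broken by trial order.
#'
#' @param rec A [recording()] with events.
#' @param window `c(offset_s, length_s)` relative to imagery onset; default
#'   `c(1, 3)`, i.e. seconds 1-4 of imagery (skipping a 1-s reaction
#'   period).
#' @param per_task_keep Epochs retained per task (default 35); `NULL` keeps
#'   all.
#' @param seed Unused by the default deterministic retention rule; kept so
#'   alternative stochastic retention rules stay reproducible.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, window = c(1, 3), per_task_keep = 35,
                           seed = NULL) {
  stopifnot(inherits(rec, "recording"), nrow(rec$events) > 0)
  fs <- rec$fs
  len <- round(window[2] * fs)
  starts <- rec$events$sample + round(window[1] * fs)
  if (any(starts < 1) || any(starts + len - 1 > ncol(rec$data)))
    stop("epoch window extends outside the recording")
  tasks <- unique(rec$events$task)
  keep_idx <- integer()
  for (tk in tasks) {
    idx <- which(rec$events$task == tk)
    if (!is.null(per_task_keep)) {
      if (length(idx) < per_task_keep)
        stop("task '", tk, "' has only ", length(idx),
             " trials; cannot keep ", per_task_keep)
      ptp <- vapply(idx, function(i) {
        seg <- rec$data[, starts[i]:(starts[i] + len - 1), drop = FALSE]
        max(apply(seg, 1, function(v) diff(range(v))))
      }, 0)
      idx <- idx[order(ptp, seq_along(idx))][seq_len(per_task_keep)]
      idx <- sort(idx)
    }
    keep_idx <- c(keep_idx, idx)
  }
  keep_idx <- sort(keep_idx)
  nep <- length(keep_idx)
  arr <- array(0, c(nep, nrow(rec$data), len))
  for (k in seq_len(nep)) {
    i <- keep_idx[k]
    arr[k, , ] <- rec$data[, starts[i]:(starts[i] + len - 1)]
  }
  epoch_set(arr, rec$events$task[keep_idx], fs, rec$channel_names, window)
}

#' Subset an epoch set by task label
#'
#' @param epochs An [epoch_set()].
#' @param tasks Labels to retain.
#' @return An [epoch_set()] containing only the matching epochs.
#' @export
epochs_for_tasks <- function(epochs, tasks) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$labels %in% tasks
  if (!any(sel)) stop("no epochs with labels: ", paste(tasks, collapse = ", "))
  epoch_set(epochs$data[sel, , , drop = FALSE], epochs$labels[sel],
            epochs$fs, epochs$channel_names, epochs$window)
}

#' Subset an epoch set by channel
#'
#' @param epochs An [epoch_set()].
#' @param channels Channel names to retain, in the requested order.
#' @return An [epoch_set()].
#' @export
epochs_select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx))
    stop("channels absent from epoch set: ",
         paste(channels[is.na(idx)], collapse = ", "))
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
            channels, epochs$window)
}

#' Denoising hook
#'
#' Placeholder for an independent-component noise-removal step. The default
#' is the identity; supply `fun` to plug in a custom denoiser.
#'
#' @param rec A [recording()].
#' @param fun `function(recording) -> recording`, or `NULL` for pass-through.
#' @return The (possibly denoised) recording.
#' @export
denoise_hook <- function(rec, fun = NULL) {
  if (is.null(fun)) rec else fun(rec)
}

#' Standard preprocessing chain
#'
#' Fixed stage order: channel selection/interpolation, average re-reference,
#' band-pass FIR filter, downsampling, denoise hook, epoch extraction.
#' Filtering is done before decimation so the decimated signal is already
#' band-limited below the target Nyquist.
#'
#' @param rec Raw [recording()].
#' @param keep Channels to retain (default full 60-channel montage).
#' @param bad Bad channels to interpolate.
#' @param f_lo,f_hi,transition_bw Band-pass parameters (defaults 1-40 Hz,
#'   1 Hz transition).
#' @param target_fs Decimation target (default 250 Hz).
#' @param window,per_task_keep Epoching parameters (defaults: seconds 1-4
#'   after onset, 35 epochs per task).
#' @param denoise Optional denoiser passed to [denoise_hook()].
#' @return An [epoch_set()].
#' @export
preprocess_recording <- function(rec, keep = standard_montage(),
                                 bad = character(),
                                 f_lo = 1, f_hi = 40, transition_bw = 1,
                                 target_fs = 250, window = c(1, 3),
                                 per_task_keep = 35, denoise = NULL) {
  rec <- select_and_interpolate(rec, keep, bad)
  rec <- rereference_average(rec)
  rec <- bandpass_fir(rec, f_lo, f_hi, transition_bw)
  rec <- downsample(rec, target_fs)
  rec <- denoise_hook(rec, denoise)
  extract_epochs(rec, window, per_task_keep)
}
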