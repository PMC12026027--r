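# Discrete prolate spheroidal (Slepian) tapers via the classical symmetric
# tridiagonal formulation: the DPSS are the eigenvectors of the matrix with
# diagonal ((N-1-2t)/2)^2 cos(2*pi*W) and off-diagonal t(N-t)/2. Results are
# cached per (n, nw, k) since the eigendecomposition dominates the cost.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign: each taper has unit energy, positive mean
  # (or positive initial slope for antisymmetric tapers)
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) > 1e-10) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density of one signal
#'
#' Thomson multitaper estimate: the eigenspectra over `k` Slepian tapers
#' with time-bandwidth product `nw` are averaged; one-sided density
#' normalization (integrating the returned PSD over 0..fs/2 recovers the
#' signal variance).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return List with `freq` (Hz, 0..fs/2) and `psd` (power per Hz).
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 2 * nw - 1) {
  n <- length(x)
  tap <- dpss_tapers(n, nw, k)
  x <- x - mean(x)
  eig <- vapply(seq_len(k), function(j) {
    Mod(stats::fft(x * tap[, j]))^2 / fs
  }, numeric(n))
  psd2 <- rowMeans(eig)                        # two-sided
  nh <- floor(n / 2) + 1
  psd <- psd2[seq_len(nh)]
  # fold negative frequencies into the one-sided estimate
  psd[2:(nh - 1)] <- 2 * psd[2:(nh - 1)]
  if (n %% 2 == 1) psd[nh] <- 2 * psd[nh]
  list(freq = (seq_len(nh) - 1) * fs / n, psd = psd)
}

#' Band-mean multitaper PSD features
#'
#' For every epoch and every selected channel, the multitaper PSD averaged
#' over the analysis band (default 8-30 Hz, the mu/beta range relevant to
#' motor imagery). With the default 21-channel sensorimotor subset the
#' output is epochs x 21.
#'
#' @param epochs An [epoch_set()].
#' @param band `c(f_lo, f_hi)` in Hz, inside Nyquist.
#' @param channels Channel subset (default [sensorimotor_channels()]).
#' @param nw,k Multitaper parameters.
#' @return A [feature_matrix()] tagged `"PSD"`.
#' @export
psd_features <- function(epochs, band = c(8, 30),
                         channels = sensorimotor_channels(),
                         nw = 4, k = 2 * nw - 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (band[2] >= epochs$fs / 2)
    stop("band upper edge (", band[2], " Hz) must be below Nyquist (",
         epochs$fs / 2, " Hz)")
  sub <- epochs_select_channels(epochs, channels)
  nep <- dim(sub$data)[1]
  nch <- dim(sub$data)[2]
  n <- dim(sub$data)[3]
  freq <- (seq_len(floor(n / 2) + 1) - 1) * sub$fs / n
  in_band <- which(freq >= band[1] & freq <= band[2])
  tap <- dpss_tapers(n, nw, k)
  feats <- matrix(0, nep, nch)
  for (i in seq_len(nep)) {
    x <- t(matrix(sub$data[i, , ], nrow = nch))   # samples x channels
    x <- sweep(x, 2, colMeans(x))
    acc <- matrix(0, length(in_band), nch)
    for (j in seq_len(k)) {
      X <- stats::mvfft(x * tap[, j])
      acc <- acc + Mod(X[in_band, , drop = FALSE])^2 / sub$fs
    }
    # one-sided band mean (band excludes DC and Nyquist)
    feats[i, ] <- 2 * colMeans(acc) / k
  }
  feature_matrix(feats, sub$labels, "PSD", paste0("psd_", channels))
}
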