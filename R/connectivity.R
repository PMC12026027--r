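# Analytic signal (zero the negative frequencies of the FFT) of every
# channel of a channels x samples matrix.
analytic_signal <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  X <- sweep(X, 2, h, `*`)
  t(stats::mvfft(t(X), inverse = TRUE)) / n
}

#' Weighted phase lag index connectivity matrix
#'
#' For every channel pair, band-passes each epoch, forms the analytic
#' signals, and estimates the weighted phase lag index
#' \deqn{WPLI_{xy} = \frac{|\frac{1}{N}\sum_n |\Im S_{xy}^n|
#'   \,\mathrm{sign}(\Im S_{xy}^n)|}{\frac{1}{N}\sum_n |\Im S_{xy}^n|}}
#' where the cross-spectral observations \eqn{S_{xy}^n = x_n \bar y_n} are
#' the instantaneous analytic cross-spectra pooled over all time points of
#' all retained epochs. A pair with no imaginary cross-spectral mass (e.g.
#' zero lag) is defined as 0 (the 0/0 convention). Values lie in \[0, 1\],
#' are symmetric, amplitude-scale invariant, and invariant to a common
#' phase rotation of both channels.
#'
#' @param epochs An [epoch_set()] (>= 2 epochs).
#' @param band `c(f_lo, f_hi)` Hz, inside Nyquist. Canonical analysis bands:
#'   alpha 8-12, beta1 13-20, beta2 20-30 Hz.
#' @param transition_bw FIR transition bandwidth for the band-pass
#'   (default 1 Hz, same design rule as preprocessing).
#' @param band_tag,task_tag Optional labels stored on the result.
#' @return Object of class `connectivity_matrix`: list with `W` (channels x
#'   channels symmetric, zero diagonal), `band`, `band_tag`, `task_tag`,
#'   `n_epochs`, `channel_names`.
#' @export
wpli_matrix <- function(epochs, band, transition_bw = 1,
                        band_tag = NULL, task_tag = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (band[2] >= epochs$fs / 2)
    stop("band upper edge above Nyquist")
  nep <- dim(epochs$data)[1]
  if (nep < 2) stop("need at least 2 epochs to estimate WPLI")
  nch <- dim(epochs$data)[2]
  if (all(epochs$data == 0))
    warning("all-zero signals; WPLI defined as 0 everywhere")
  b <- design_fir_bandpass(epochs$fs, band[1], band[2], transition_bw)
  num <- matrix(0, nch, nch)   # sum of Im S (sign-weighted magnitudes)
  den <- matrix(0, nch, nch)   # sum of |Im S|
  for (e in seq_len(nep)) {
    seg <- fir_apply_zerophase_mat(matrix(epochs$data[e, , ], nrow = nch), b)
    z <- analytic_signal(seg)
    A <- Re(z); B <- Im(z)
    for (i in seq_len(nch)) {
      # Im(z_i * Conj(z_j)) over all time points, all j at once
      imS <- B[i, ] * t(A) - A[i, ] * t(B)       # samples x channels
      num[i, ] <- num[i, ] + colSums(imS)
      den[i, ] <- den[i, ] + colSums(abs(imS))
    }
  }
  W <- ifelse(den > 0, abs(num) / den, 0)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(epochs$channel_names, epochs$channel_names)
  structure(list(W = W, band = band, band_tag = band_tag,
                 task_tag = task_tag, n_epochs = nep,
                 channel_names = epochs$channel_names),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, band %g-%g Hz, %d epochs\n",
              nrow(x$W), ncol(x$W), x$band[1], x$band[2], x$n_epochs))
  invisible(x)
}

#' Proportional threshold to a binary network
#'
#' Retains the `round(fraction * P)` largest of the `P = N(N-1)/2`
#' off-diagonal upper-triangle weights (for the 60-channel montage at the
#' default 10\% this is 177 edges), symmetrizes and binarizes. Ties at the
#' cut are broken by ascending (row, column) lexicographic order.
#'
#' @param W A `connectivity_matrix` or a symmetric numeric matrix.
#' @param fraction Fraction of strongest connections kept, in (0, 1\].
#' @return Object of class `binary_network`: list with `A` (0/1 adjacency,
#'   zero diagonal), `fraction`, `n_edges`, `band_tag`, `task_tag`,
#'   `channel_names`.
#' @export
threshold_top_fraction <- function(W, fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  band_tag <- task_tag <- NULL
  channel_names <- NULL
  if (inherits(W, "connectivity_matrix")) {
    band_tag <- W$band_tag; task_tag <- W$task_tag
    channel_names <- W$channel_names
    W <- W$W
  } else {
    W <- as.matrix(W)
    channel_names <- rownames(W)
  }
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  k <- round(fraction * length(w))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n)
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- list(channel_names, channel_names)
  structure(list(A = A, fraction = fraction, n_edges = k,
                 band_tag = band_tag, task_tag = task_tag,
                 channel_names = channel_names),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (top %.0f%%)\n",
              nrow(x$A), x$n_edges, 100 * x$fraction))
  invisible(x)
}

#' Write a connectivity matrix or binary network to a delimited file
#'
#' Connectivity matrices are written as square tab-separated tables with
#' channel-name headers; binary networks as two-column edge lists.
#'
#' @param x A `connectivity_matrix` or `binary_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path) {
  if (inherits(x, "connectivity_matrix")) {
    utils::write.table(x$W, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else if (inherits(x, "binary_network")) {
    idx <- which(upper.tri(x$A) & x$A == 1, arr.ind = TRUE)
    edges <- data.frame(channel_a = x$channel_names[idx[, 1]],
                        channel_b = x$channel_names[idx[, 2]])
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
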