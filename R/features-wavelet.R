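# Orthogonal wavelet decomposition filters (scaling coefficients, sqrt(2)
# normalization). The quadrature mirror high-pass is derived as
# g[k] = (-1)^k h[L-1-k].
wavelet_filter <- function(name) {
  h <- switch(tolower(name),
    haar = ,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415,
            0.6308807679295904, -0.02798376941698385,
            -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    sym4 = c(-0.07576571478927333, -0.02963552764599851,
             0.49761866763201545, 0.8037387518059161,
             0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427),
    coif1 = c(-0.01565572813546454, -0.0727326195128539,
              0.38486484686420286, 0.8525720202122554,
              0.3378976624578092, -0.0727326195128539),
    stop("unsupported mother wavelet '", name, "'; supported families: ",
         "Daubechies (db1, db2, db4), Symlets (sym4), Haar, Coiflets (coif1)")
  )
  L <- length(h)
  g <- rev(h) * (-1)^(0:(L - 1))
  list(h = h, g = g)
}

# One periodized analysis step; odd-length inputs are extended by repeating
# the final sample. Returns list(a = approximation, d = detail).
dwt_step <- function(x, filt) {
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
  n <- length(x)
  half <- n / 2
  L <- length(filt$h)
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + 0:(L - 1)) %% n) + 1
    a[k] <- sum(filt$h * x[idx])
    d[k] <- sum(filt$g * x[idx])
  }
  list(a = a, d = d)
}

#' Discrete wavelet transform (periodized, multi-level)
#'
#' @param x Numeric signal (length at least `2^levels`).
#' @param mother Mother wavelet name (see [wavelet_filter()] families).
#' @param levels Decomposition depth.
#' @return Named list of coefficient vectors: details `d1` (finest) ..
#'   `d<levels>`, then the final approximation `a<levels>`.
#' @export
dwt <- function(x, mother = "db4", levels = 5) {
  if (length(x) < 2^levels)
    stop("signal length ", length(x), " too short for ", levels, " levels")
  filt <- wavelet_filter(mother)
  out <- list()
  a <- x
  for (lev in seq_len(levels)) {
    s <- dwt_step(a, filt)
    out[[paste0("d", lev)]] <- s$d
    a <- s$a
  }
  out[[paste0("a", levels)]] <- a
  out
}

# Inverse-Gray-code permutation: natural (filter-path) leaf index ->
# frequency rank, accounting for the spectral reversal of high-pass
# branches in a wavelet packet tree.
wpd_frequency_rank <- function(path_idx, levels) {
  r <- 0L
  g <- path_idx
  while (g > 0) {
    r <- bitwXor(r, g)
    g <- bitwShiftR(g, 1)
  }
  r
}

#' Wavelet packet decomposition (full tree, periodized)
#'
#' @inheritParams dwt
#' @return List of `2^levels` leaf-coefficient vectors in natural
#'   (filter-path) order; attribute `freq_rank` gives each leaf's frequency
#'   rank (0 = lowest band).
#' @export
wpd <- function(x, mother = "db4", levels = 3) {
  if (length(x) < 2^levels)
    stop("signal length ", length(x), " too short for ", levels, " levels")
  filt <- wavelet_filter(mother)
  nodes <- list(x)
  for (lev in seq_len(levels)) {
    nodes <- unlist(lapply(nodes, function(v) {
      s <- dwt_step(v, filt)
      list(s$a, s$d)
    }), recursive = FALSE)
  }
  attr(nodes, "freq_rank") <-
    vapply(seq_along(nodes) - 1L, wpd_frequency_rank, 0L, levels = levels)
  nodes
}

# The wpd leaves (natural order indices) with greatest spectral overlap
# with [f_lo, f_hi] at sampling rate fs; ties broken by ascending band.
wpd_select_leaves <- function(fs, levels, band, n_keep) {
  width <- (fs / 2) / 2^levels
  ranks <- vapply(seq_len(2^levels) - 1L, wpd_frequency_rank, 0L,
                  levels = levels)
  lo <- ranks * width
  hi <- lo + width
  overlap <- pmax(0, pmin(hi, band[2]) - pmax(lo, band[1]))
  ord <- order(-overlap, ranks)
  sort(ord[seq_len(n_keep)])          # natural-order indices, ascending
}

#' Wavelet time-frequency features (DWT + WPD statistics)
#'
#' Epochs are first averaged over the selected channel subset, then
#' decomposed with a 5-level discrete wavelet transform (sub-bands A5,
#' D5..D1) and a 3-level wavelet packet decomposition, of which the 6
#' leaves with greatest spectral overlap with `band` are retained. Each of
#' the 12 sub-bands contributes three statistics of its coefficients --
#' mean, standard deviation, and mean power -- for 36 features per epoch.
#'
#' @param epochs An [epoch_set()].
#' @param mother Mother wavelet (default `"db4"`).
#' @param dwt_levels,wpd_levels Decomposition depths (defaults 5 and 3).
#' @param band Band used to pick wavelet-packet leaves (default 8-30 Hz).
#' @param channels Channel subset averaged before decomposition (default
#'   [sensorimotor_channels()]); pass a single channel for per-channel use.
#' @return A [feature_matrix()] tagged `"WPD+DWT"` with 36 columns.
#' @export
wavelet_features <- function(epochs, mother = "db4", dwt_levels = 5,
                             wpd_levels = 3, band = c(8, 30),
                             channels = sensorimotor_channels()) {
  stopifnot(inherits(epochs, "epoch_set"))
  sub <- epochs_select_channels(epochs, channels)
  nep <- dim(sub$data)[1]
  leaves <- wpd_select_leaves(sub$fs, wpd_levels, band, 6)
  stats3 <- function(v) c(mean(v), stats::sd(v), mean(v^2))
  feats <- t(vapply(seq_len(nep), function(i) {
    x <- colMeans(matrix(sub$data[i, , ], nrow = dim(sub$data)[2]))
    dw <- dwt(x, mother, dwt_levels)
    dwt_bands <- dw[c(paste0("a", dwt_levels), paste0("d", dwt_levels:1))]
    wp <- wpd(x, mother, wpd_levels)[leaves]
    unlist(lapply(c(dwt_bands, wp), stats3))
  }, numeric(36)))
  band_names <- c(paste0("dwt_", c(paste0("a", dwt_levels),
                                   paste0("d", dwt_levels:1))),
                  paste0("wpd_leaf", leaves))
  fn <- as.vector(t(outer(band_names, c("mean", "sd", "power"), paste, sep = "_")))
  feature_matrix(feats, sub$labels, "WPD+DWT", fn)
}
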