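#' Histogram mutual information between a feature and binary labels
#'
#' Plug-in estimate of I(feature; label) in bits, with the feature
#' discretized into `n_bins` equal-frequency (quantile) bins. Quantile
#' binning makes the estimate invariant to monotone rescaling of the
#' feature.
#'
#' @param feature Numeric vector.
#' @param labels Vector with exactly two distinct values, same length.
#' @param n_bins Number of quantile bins (default 8).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(feature, labels, n_bins = 8) {
  stopifnot(length(feature) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("mutual information needs two classes; got a single class")
  qs <- stats::quantile(feature, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs <- unique(qs)
  bins <- cut(feature, breaks = qs, include.lowest = TRUE)
  joint <- table(bins, labels) / length(feature)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  max(0, mi)
}

#' Filter-bank CSP features
#'
#' Band-passes the two-class epochs into each filter-bank sub-band, fits
#' CSP filters per band, and concatenates the per-band log-variance
#' features: 6 bands x 2 pairs x 2 = 24 columns with the defaults. Per-band
#' mutual information of each feature with the class label is attached as
#' attribute `mi_report` (bands are ranked but none are dropped by
#' default).
#'
#' @param epochs Two-class [epoch_set()].
#' @param bands Filter bank (default [filter_bank()]).
#' @param n_pairs CSP filter pairs per band (default 2).
#' @param eps Covariance regularization ridge.
#' @param filters Optional pre-fitted per-band filter list (from
#'   [fbcsp_fit()]); when supplied the epochs are only transformed, which is
#'   how cross-validation avoids leakage.
#' @return A [feature_matrix()] tagged `"FBCSP"`.
#' @export
fbcsp_features <- function(epochs, bands = filter_bank(), n_pairs = 2,
                           eps = 1e-6, filters = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  fit_here <- is.null(filters)
  if (fit_here) {
    classes <- sort(unique(epochs$labels))
    if (length(classes) != 2) stop("FBCSP expects exactly two classes")
    filters <- vector("list", nrow(bands))
  }
  parts <- lapply(seq_len(nrow(bands)), function(b) {
    fb <- epochs_bandpass(epochs, bands[b, 1], bands[b, 2])
    if (fit_here) {
      filters[[b]] <<- csp_fit(epochs_for_tasks(fb, classes[1]),
                               epochs_for_tasks(fb, classes[2]),
                               n_pairs, eps)
    }
    fm <- csp_features(fb, filters[[b]])
    colnames(fm$values) <- paste0("band", b, "_", colnames(fm$values))
    fm$values
  })
  values <- do.call(cbind, parts)
  fm <- feature_matrix(values, epochs$labels, "FBCSP")
  nb <- nrow(bands)
  mi <- vapply(seq_len(nb), function(b) {
    cols <- ((b - 1) * 2 * n_pairs + 1):(b * 2 * n_pairs)
    mean(apply(values[, cols, drop = FALSE], 2, mutual_information,
               labels = epochs$labels))
  }, 0)
  attr(fm, "mi_report") <- data.frame(band = seq_len(nb),
                                      f_lo = bands[, 1], f_hi = bands[, 2],
                                      mean_mi_bits = mi)
  fm
}

#' Fit per-band CSP filters for FBCSP
#'
#' @inheritParams fbcsp_features
#' @return List of [csp_fit()] results, one per band.
#' @export
fbcsp_fit <- function(epochs, bands = filter_bank(), n_pairs = 2,
                      eps = 1e-6) {
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2) stop("FBCSP expects exactly two classes")
  lapply(seq_len(nrow(bands)), function(b) {
    fb <- epochs_bandpass(epochs, bands[b, 1], bands[b, 2])
    csp_fit(epochs_for_tasks(fb, classes[1]),
            epochs_for_tasks(fb, classes[2]), n_pairs, eps)
  })
}
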