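# Symmetric eigendecomposition helpers for SPD matrices.
spd_check <- function(M, tol = 0) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) <= tol)
    stop("matrix is not positive definite (min eigenvalue ",
         format(min(ev$values)), "); regularize first")
  list(M = M, values = ev$values, vectors = ev$vectors)
}

spd_fun <- function(M, f) {
  e <- spd_check(M)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_sqrt <- function(M) spd_fun(M, sqrt)
spd_invsqrt <- function(M) spd_fun(M, function(v) 1 / sqrt(v))
spd_log <- function(M) spd_fun(M, log)
spd_exp <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(A, B) = sqrt(sum(log(lambda_i)^2))` over the generalized
#' eigenvalues `lambda_i` of `(A, B)`. Invariant under congruence
#' `A -> G A t(G)` and under inversion.
#'
#' @param A,B Symmetric positive-definite matrices of equal size.
#' @return Non-negative scalar distance.
#' @export
riemann_distance <- function(A, B) {
  iv <- spd_invsqrt(A)
  M <- iv %*% B %*% iv
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' Intrinsic mean under the affine-invariant metric, computed by iterated
#' tangent-space averaging: log-map all matrices at the current estimate,
#' average, exp-map back. Converged when the Frobenius norm of the mean
#' tangent vector drops below `tol`.
#'
#' @param covs List of SPD matrices of equal size.
#' @param tol Convergence threshold on the mean tangent norm (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return The SPD mean matrix.
#' @export
riemann_mean <- function(covs, tol = 1e-8, max_iter = 200) {
  stopifnot(length(covs) >= 1)
  if (length(covs) == 1) return(covs[[1]])
  G <- Reduce(`+`, covs) / length(covs)     # arithmetic-mean initialization
  step <- 1                                  # halved whenever the tangent
  prev <- Inf                                # norm fails to decrease
  for (it in seq_len(max_iter)) {
    Gs <- spd_sqrt(G)
    Gis <- spd_invsqrt(G)
    Tm <- Reduce(`+`, lapply(covs, function(C) spd_log(Gis %*% C %*% Gis))) /
      length(covs)
    nrm <- sqrt(sum(Tm^2))
    if (nrm < tol) return(G)
    if (nrm >= prev) step <- max(step / 2, 1 / 64)
    prev <- nrm
    G <- Gs %*% spd_exp(step * Tm) %*% Gs
    G <- (G + t(G)) / 2
  }
  stop("Karcher mean did not converge in ", max_iter,
       " iterations (last tangent norm ", format(nrm), ")")
}

#' Tangent-space mapping of SPD matrices
#'
#' Projects each covariance onto the tangent space at `reference`:
#' `vec_upper(logm(ref^{-1/2} C ref^{-1/2}))` with off-diagonal entries
#' scaled by `sqrt(2)` so the Euclidean norm of the vector equals the
#' Riemannian distance `delta(C, reference)`.
#'
#' @param covs List of SPD matrices (p x p).
#' @param reference SPD reference point (typically the [riemann_mean()]).
#' @return Matrix `length(covs) x p(p+1)/2` of tangent vectors.
#' @export
tangent_map <- function(covs, reference) {
  iv <- spd_invsqrt(reference)
  p <- nrow(reference)
  ut <- upper.tri(diag(p), diag = FALSE)
  t(vapply(covs, function(C) {
    L <- spd_log(iv %*% C %*% iv)
    c(diag(L), sqrt(2) * L[ut])
  }, numeric(p * (p + 1) / 2)))
}

# Band-pass filter every epoch x channel signal of an epoch set (reflection
# padded zero-phase FIR; see design_fir_bandpass). transition_bw defaults
# to 2 Hz so the filter stays shorter than a 3-s epoch.
epochs_bandpass <- function(epochs, f_lo, f_hi, transition_bw = 2) {
  b <- design_fir_bandpass(epochs$fs, f_lo, f_hi, transition_bw)
  out <- epochs
  nch <- dim(epochs$data)[2]
  for (i in seq_len(dim(epochs$data)[1])) {
    out$data[i, , ] <- fir_apply_zerophase_mat(
      matrix(epochs$data[i, , ], nrow = nch), b)
  }
  out
}

#' Default 6-band filter bank
#'
#' Contiguous 4-Hz sub-bands spanning 8-32 Hz, the standard bank for
#' filter-bank spatial-pattern and Riemannian pipelines over the mu/beta
#' range.
#'
#' @return 6 x 2 matrix of band edges (Hz).
#' @export
filter_bank <- function() {
  cbind(f_lo = seq(8, 28, by = 4), f_hi = seq(12, 32, by = 4))
}

#' Fit per-band Riemannian class means
#'
#' For each filter-bank band, band-passes the (two-class) training epochs,
#' computes per-epoch covariances on the channel subset, and the Karcher
#' mean of each class.
#'
#' @param epochs Two-class [epoch_set()] (training folds only, to avoid
#'   leakage into cross-validation).
#' @param bands Band matrix (default [filter_bank()]).
#' @param channels Channel subset (default [sensorimotor_channels()]).
#' @param eps Covariance regularization ridge.
#' @return Object of class `riemann_model`: per band, the two class means.
#' @export
riemann_fit <- function(epochs, bands = filter_bank(),
                        channels = sensorimotor_channels(), eps = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"))
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2) stop("riemann_fit expects exactly two classes")
  sub <- epochs_select_channels(epochs, channels)
  per_band <- lapply(seq_len(nrow(bands)), function(b) {
    fb <- epochs_bandpass(sub, bands[b, 1], bands[b, 2])
    means <- lapply(classes, function(cl) {
      idx <- which(fb$labels == cl)
      covs <- lapply(idx, function(i) epoch_covariance(fb$data[i, , ], eps))
      riemann_mean(covs)
    })
    names(means) <- classes
    means
  })
  structure(list(bands = bands, channels = channels, classes = classes,
                 means = per_band, eps = eps),
            class = "riemann_model")
}

#' Riemannian distance features
#'
#' For every epoch and every filter-bank band, the affine-invariant
#' distances from the epoch's band covariance to the two fitted class
#' means: 6 bands x 2 distances = 12 features per epoch.
#'
#' @param epochs An [epoch_set()].
#' @param model A fitted [riemann_fit()].
#' @return A [feature_matrix()] tagged `"RF"` with 12 columns.
#' @export
riemann_features <- function(epochs, model) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(model, "riemann_model"))
  sub <- epochs_select_channels(epochs, model$channels)
  nep <- dim(sub$data)[1]
  nb <- nrow(model$bands)
  feats <- matrix(0, nep, 2 * nb)
  for (b in seq_len(nb)) {
    fb <- epochs_bandpass(sub, model$bands[b, 1], model$bands[b, 2])
    for (i in seq_len(nep)) {
      C <- epoch_covariance(fb$data[i, , ], model$eps)
      feats[i, 2 * b - 1] <- riemann_distance(C, model$means[[b]][[1]])
      feats[i, 2 * b] <- riemann_distance(C, model$means[[b]][[2]])
    }
  }
  fn <- as.vector(t(outer(paste0("band", seq_len(nb)),
                          paste0("dist_", model$classes), paste, sep = "_")))
  feature_matrix(feats, sub$labels, "RF", fn)
}
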