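#' Feature matrix container
#'
#' @param values samples x features numeric matrix (finite entries).
#' @param labels task label per row.
#' @param extractor Tag: one of `"PSD"`, `"WPD+DWT"`, `"RF"`, `"FBCSP"` (or a
#'   custom tag).
#' @param feature_names Optional column names.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, extractor,
                           feature_names = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels))
  if (!all(is.finite(values))) stop("feature matrix contains non-finite entries")
  if (!is.null(feature_names)) colnames(values) <- feature_names
  structure(list(values = values, labels = as.character(labels),
                 extractor = extractor),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d samples x %d features\n",
              x$extractor, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Sample covariance of one epoch (channels x samples), regularized to SPD:
# C + eps * (trace(C)/p) * I.
epoch_covariance <- function(x, eps = 1e-6) {
  p <- nrow(x)
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / (ncol(x) - 1)
  C + eps * (sum(diag(C)) / p) * diag(p)
}

# Mean covariance over the epochs of one class.
class_covariance <- function(epochs, label, eps = 1e-6) {
  idx <- which(epochs$labels == label)
  covs <- lapply(idx, function(i) epoch_covariance(epochs$data[i, , ], eps))
  Reduce(`+`, covs) / length(covs)
}

#' Fit common spatial pattern (CSP) filters
#'
#' Solves the generalized eigenproblem of `(C1, C1 + C2)`: filters whose
#' projected variance ratio between the two classes is extremal. The
#' returned filters jointly whiten the pooled covariance,
#' `t(W) %*% (C1 + C2) %*% W = I`, and the associated eigenvalues are the
#' class-1 variance fractions in `[0, 1]`, sorted descending. The
#' `2 * n_pairs` retained filters come from both ends of the spectrum.
#'
#' @param epochs_a,epochs_b [epoch_set()]s (one class each) with equal
#'   channel counts, or channels x channels covariance matrices.
#' @param n_pairs Filter pairs retained from each end (default 2).
#' @param eps Covariance regularization (relative ridge); see
#'   [epoch_covariance()].
#' @return Object of class `spatial_filters`: list with `W` (channels x
#'   2*n_pairs), `eigenvalues` (all, descending), `classes`.
#' @export
csp_fit <- function(epochs_a, epochs_b, n_pairs = 2, eps = 1e-6) {
  as_cov <- function(x) {
    if (inherits(x, "epoch_set")) {
      covs <- lapply(seq_len(dim(x$data)[1]),
                     function(i) epoch_covariance(x$data[i, , ], eps))
      Reduce(`+`, covs) / length(covs)
    } else as.matrix(x)
  }
  classes <- c(if (inherits(epochs_a, "epoch_set")) unique(epochs_a$labels) else "a",
               if (inherits(epochs_b, "epoch_set")) unique(epochs_b$labels) else "b")
  C1 <- as_cov(epochs_a)
  C2 <- as_cov(epochs_b)
  stopifnot(all(dim(C1) == dim(C2)))
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= .Machine$double.eps * max(ec$values) * nrow(Cc))
    stop("pooled covariance is rank-deficient; increase the regularization ",
         "ridge eps (shrinkage) before fitting CSP")
  # whiten, then eigendecompose the whitened class-1 covariance
  P <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S1 <- P %*% C1 %*% P
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W_full <- P %*% e1$vectors                     # all generalized eigvecs
  lam <- e1$values                               # descending
  p <- ncol(W_full)
  n_pairs <- min(n_pairs, floor(p / 2))
  sel <- c(seq_len(n_pairs), p - seq_len(n_pairs) + 1)
  structure(list(W = W_full[, sel, drop = FALSE],
                 eigenvalues = lam, classes = classes,
                 n_pairs = n_pairs),
            class = "spatial_filters")
}

#' Log-variance CSP features
#'
#' Projects every epoch through the spatial filters and returns, per filter,
#' the log of its share of the total projected variance,
#' `log(var_f / sum(var))`. Scale-invariant by construction:
#' `sum(exp(feature))` is 1 for every epoch.
#'
#' @param epochs An [epoch_set()].
#' @param filters A [csp_fit()] result with matching channel count.
#' @return A [feature_matrix()] with `2 * n_pairs` columns.
#' @export
csp_features <- function(epochs, filters) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(filters, "spatial_filters"))
  W <- filters$W
  if (nrow(W) != dim(epochs$data)[2])
    stop("filter channel count (", nrow(W), ") does not match epochs (",
         dim(epochs$data)[2], ")")
  nep <- dim(epochs$data)[1]
  feats <- t(vapply(seq_len(nep), function(i) {
    proj <- t(W) %*% epochs$data[i, , ]
    v <- apply(proj, 1, stats::var)
    if (any(v <= 0)) stop("zero-variance projection in epoch ", i)
    log(v / sum(v))
  }, numeric(ncol(W))))
  feature_matrix(feats, epochs$labels, "CSP",
                 paste0("csp", seq_len(ncol(W))))
}
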