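#' Canonical motor-imagery task-pair order
#'
#' @return Character matrix 6 x 2: (left hand, right hand), (left hand,
#'   foot), (left hand, tongue), (right hand, foot), (right hand, tongue),
#'   (foot, tongue).
#' @export
task_pairs <- function() {
  rbind(c("left_hand", "right_hand"),
        c("left_hand", "foot"),
        c("left_hand", "tongue"),
        c("right_hand", "foot"),
        c("right_hand", "tongue"),
        c("foot", "tongue"))
}

#' Trainable feature extractor for leakage-free cross-validation
#'
#' Wraps an epoch set together with a fold-trainable extractor (Riemannian
#' class-mean distances or filter-bank CSP). Band-pass filtering and
#' per-epoch covariances are label-independent and precomputed once; the
#' label-dependent parts (Karcher class means, CSP filters) are re-fitted
#' inside every training fold by [pairwise_accuracy()].
#'
#' @param epochs Two-class [epoch_set()].
#' @param type `"riemann"` or `"fbcsp"`.
#' @param bands Filter bank (default [filter_bank()]).
#' @param channels Channel subset for the Riemannian covariances (default
#'   [sensorimotor_channels()]); FBCSP uses all channels of `epochs`.
#' @param n_pairs CSP pairs per band (FBCSP only; default 2).
#' @param eps Covariance regularization ridge.
#' @return Object of class `trainable_features`.
#' @export
trainable_features <- function(epochs, type = c("riemann", "fbcsp"),
                               bands = filter_bank(),
                               channels = sensorimotor_channels(),
                               n_pairs = 2, eps = 1e-6) {
  type <- match.arg(type)
  stopifnot(inherits(epochs, "epoch_set"))
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2) stop("trainable_features expects two classes")
  # per-band per-epoch covariances; band-pass filtering and covariance
  # estimation are label-independent, so precomputing them leaks nothing
  sub <- if (type == "riemann") epochs_select_channels(epochs, channels)
         else epochs
  state <- lapply(seq_len(nrow(bands)), function(b) {
    fb <- epochs_bandpass(sub, bands[b, 1], bands[b, 2])
    lapply(seq_len(dim(fb$data)[1]),
           function(i) epoch_covariance(fb$data[i, , ], eps))
  })
  structure(list(type = type, bands = bands, labels = epochs$labels,
                 classes = classes, state = state, n_pairs = n_pairs,
                 eps = eps, n = dim(epochs$data)[1]),
            class = "trainable_features")
}

tf_fit <- function(tf, train_idx) {
  if (tf$type == "riemann") {
    lapply(tf$state, function(covs) {
      means <- lapply(tf$classes, function(cl) {
        idx <- intersect(train_idx, which(tf$labels == cl))
        riemann_mean(covs[idx])
      })
      names(means) <- tf$classes
      means
    })
  } else {
    lapply(tf$state, function(covs) {
      mean_cov <- function(cl) {
        idx <- intersect(train_idx, which(tf$labels == cl))
        Reduce(`+`, covs[idx]) / length(idx)
      }
      csp_fit(mean_cov(tf$classes[1]), mean_cov(tf$classes[2]),
              tf$n_pairs, tf$eps)
    })
  }
}

tf_transform <- function(tf, model, idx) {
  nb <- length(tf$state)
  if (tf$type == "riemann") {
    out <- matrix(0, length(idx), 2 * nb)
    for (b in seq_len(nb)) {
      for (k in seq_along(idx)) {
        C <- tf$state[[b]][[idx[k]]]
        out[k, 2 * b - 1] <- riemann_distance(C, model[[b]][[1]])
        out[k, 2 * b] <- riemann_distance(C, model[[b]][[2]])
      }
    }
    out
  } else {
    # CSP log-variance features straight from the epoch covariance:
    # var of the f-th projection = diag(t(W) C W)
    do.call(cbind, lapply(seq_len(nb), function(b) {
      W <- model[[b]]$W
      t(vapply(idx, function(i) {
        v <- diag(t(W) %*% tf$state[[b]][[i]] %*% W)
        log(v / sum(v))
      }, numeric(ncol(W))))
    }))
  }
}

# numeric checksum of a fitted fold model, for leakage instrumentation
tf_checksum <- function(model) {
  v <- suppressWarnings(as.numeric(unlist(model)))
  sum(v[is.finite(v)])
}

# seeded stratified fold assignment: within each class, a random permutation
# is dealt round-robin over folds
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- (sample(seq_along(idx)) %% folds) + 1L
    }
  })
  assign
}

#' Cross-validated pairwise classification accuracy
#'
#' Stratified k-fold cross-validation of a linear maximum-margin classifier
#' (support vector machine, linear kernel, cost 1). Feature standardization
#' -- and, for [trainable_features()], Karcher class means or CSP filters --
#' is fitted on the training folds only, so no test-fold information leaks
#' into the transform. Returns the mean fold accuracy, with per-fold
#' accuracies and fitted-transform checksums as attributes.
#'
#' @param x A two-class [feature_matrix()] or a [trainable_features()].
#' @param folds Number of folds (default 10); every class needs at least
#'   `folds` samples.
#' @param seed Seed for the fold assignment.
#' @param cost SVM regularization constant (default 1).
#' @param repeats Number of independent fold assignments averaged over
#'   (repeated cross-validation; default 1). Repeats reduce the variance of
#'   the accuracy estimate at proportional cost.
#' @return Accuracy fraction in \[0, 1\].
#' @export
pairwise_accuracy <- function(x, folds = 10, seed = 1, cost = 1,
                              repeats = 1) {
  if (repeats > 1) {
    runs <- lapply(seq_len(repeats), function(r)
      pairwise_accuracy(x, folds, substream_seed(seed, r), cost))
    return(structure(mean(unlist(runs)),
                     fold_accuracies = unlist(lapply(runs, attr,
                                                     "fold_accuracies")),
                     fold_checksums = unlist(lapply(runs, attr,
                                                    "fold_checksums"))))
  }
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels
    trainable <- FALSE
  } else if (inherits(x, "trainable_features")) {
    labels <- x$labels
    trainable <- TRUE
  } else stop("x must be a feature_matrix or trainable_features")
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("pairwise accuracy needs exactly two classes")
  counts <- table(labels)
  if (any(counts < folds))
    stop("class '", names(counts)[which.min(counts)], "' has ",
         min(counts), " samples (< ", folds,
         " folds); reduce the number of folds")
  assign <- stratified_folds(labels, folds, seed)
  y <- factor(labels, levels = classes)
  acc <- numeric(folds)
  checksums <- numeric(folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assign == f)
    train_idx <- which(assign != f)
    if (trainable) {
      model <- tf_fit(x, train_idx)
      checksums[f] <- tf_checksum(model)
      Xtr <- tf_transform(x, model, train_idx)
      Xte <- tf_transform(x, model, test_idx)
    } else {
      Xtr <- x$values[train_idx, , drop = FALSE]
      Xte <- x$values[test_idx, , drop = FALSE]
      checksums[f] <- sum(colMeans(Xtr))
    }
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- scale(Xtr, mu, sg)
    Xte <- scale(Xte, mu, sg)
    fit <- e1071::svm(Xtr, y[train_idx], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte)
    acc[f] <- mean(pred == y[test_idx])
  }
  structure(mean(acc), fold_accuracies = acc, fold_checksums = checksums)
}

#' Assemble an adaptability score from six pairwise accuracies
#'
#' Adaptability is the arithmetic mean of the six pairwise accuracies in
#' the canonical [task_pairs()] order. `variant3` is the mean over the
#' three hand/foot pairs only (left-right, left-foot, right-foot),
#' excluding every pair that involves the tongue task.
#'
#' @param per_pair_accuracies Numeric vector of exactly 6 accuracies in
#'   canonical pair order.
#' @param subject Optional subject identifier.
#' @param method Optional extractor tag.
#' @return Object of class `adaptability_score`: list with `pairwise`,
#'   `mean`, `variant3`, `subject`, `method`.
#' @export
adaptability_score <- function(per_pair_accuracies, subject = NA,
                               method = NA) {
  if (length(per_pair_accuracies) != 6)
    stop("expected 6 pairwise accuracies (canonical order), got ",
         length(per_pair_accuracies))
  if (any(per_pair_accuracies < 0 | per_pair_accuracies > 1))
    stop("accuracies must lie in [0, 1]")
  pp <- as.numeric(per_pair_accuracies)
  names(pp) <- apply(task_pairs(), 1, paste, collapse = "-")
  structure(list(subject = subject, method = method, pairwise = pp,
                 mean = mean(pp), variant3 = mean(pp[c(1, 2, 4)])),
            class = "adaptability_score")
}

#' @export
print.adaptability_score <- function(x, ...) {
  cat(sprintf("<adaptability_score> subject=%s method=%s mean=%.3f variant3=%.3f\n",
              x$subject, x$method, x$mean, x$variant3))
  print(round(x$pairwise, 3))
  invisible(x)
}

#' Adaptability of one subject under one feature-extraction method
#'
#' Runs the six pairwise classifications for an epoched recording and one
#' extractor, returning the [adaptability_score()].
#'
#' @param epochs Four-task [epoch_set()].
#' @param method `"PSD"`, `"WPD+DWT"`, `"RF"` or `"FBCSP"`.
#' @param folds,seed Cross-validation parameters.
#' @param channels Channel subset for PSD/wavelet/Riemannian extractors.
#' @param bands Filter bank for RF/FBCSP.
#' @param subject Subject identifier carried into the score.
#' @return An [adaptability_score()].
#' @export
subject_adaptability <- function(epochs, method = c("PSD", "WPD+DWT", "RF", "FBCSP"),
                                 folds = 10, seed = 1,
                                 channels = sensorimotor_channels(),
                                 bands = filter_bank(), subject = NA,
                                 repeats = 1) {
  method <- match.arg(method)
  pairs <- task_pairs()
  # fixed (untrainable) extractors are computed once over all epochs and
  # subset per pair; trainable ones must be rebuilt per two-class problem
  fixed <- if (method == "PSD") psd_features(epochs, channels = channels)
           else if (method == "WPD+DWT") wavelet_features(epochs, channels = channels)
           else NULL
  acc <- vapply(seq_len(nrow(pairs)), function(p) {
    x <- if (!is.null(fixed)) {
      sel <- fixed$labels %in% pairs[p, ]
      feature_matrix(fixed$values[sel, , drop = FALSE], fixed$labels[sel],
                     fixed$extractor)
    } else {
      pe <- epochs_for_tasks(epochs, pairs[p, ])
      trainable_features(pe, if (method == "RF") "riemann" else "fbcsp",
                         bands, channels)
    }
    as.numeric(pairwise_accuracy(x, folds, seed = substream_seed(seed, p),
                                 repeats = repeats))
  }, 0)
  adaptability_score(acc, subject = subject, method = method)
}

#' Cross-method consistency of adaptability scores
#'
#' Pairwise Pearson correlations (with two-sided p-values) between the
#' per-subject adaptability scores of different feature-extraction methods.
#'
#' @param scores Numeric subjects x methods matrix (>= 3 subjects).
#' @return List with matrices `r` and `p` (methods x methods).
#' @export
method_consistency <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3) stop("need at least 3 subjects")
  if (any(apply(scores, 2, stats::sd) == 0))
    stop("constant score column; correlation undefined")
  m <- ncol(scores)
  r <- diag(1, m)
  p <- matrix(0, m, m)
  dimnames(r) <- dimnames(p) <- list(colnames(scores), colnames(scores))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ct <- pearson_cor(scores[, i], scores[, j])
    r[i, j] <- r[j, i] <- ct$r
    p[i, j] <- p[j, i] <- ct$p
  }
  list(r = r, p = p)
}
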