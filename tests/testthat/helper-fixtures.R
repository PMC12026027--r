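# Fixture builders shared across test files. Everything is generated in
# code at test time; sizes are deliberately small.

# Epoch set of white noise, optionally with a band-limited sinusoid planted
# on `planted_channels` for the second class (distinct spatial band-power
# pattern -> CSP/PSD separability).
make_two_class_epochs <- function(n_per_class = 35, nch = 60, ns = 750,
                                  fs = 250, planted_channels = NULL,
                                  amp = 3, freq = 10, seed = 1,
                                  labels = c("left_hand", "right_hand")) {
  if (is.null(planted_channels)) {
    planted_channels <- if (nch >= 31) 26:31 else
      seq(max(1, nch %/% 2), min(nch, nch %/% 2 + 2))
  }
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(stats::rnorm(n * nch * ns), c(n, nch, ns))
  tt <- seq_len(ns) / fs
  for (i in (n_per_class + 1):n) {
    for (ch in planted_channels) {
      arr[i, ch, ] <- arr[i, ch, ] +
        amp * sin(2 * pi * freq * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  epoch_set(arr, rep(labels, each = n_per_class), fs,
            standard_montage()[seq_len(nch)], c(0, ns / fs))
}

# Epoch set whose channels 1 and 2 are a pure oscillator and its
# phase-lagged copy; remaining channels independent noise.
make_lagged_epochs <- function(n_epochs = 10, nch = 4, ns = 750, fs = 250,
                               freq = 10, lag = pi / 2, seed = 1) {
  set.seed(seed)
  arr <- array(stats::rnorm(n_epochs * nch * ns), c(n_epochs, nch, ns))
  tt <- seq_len(ns) / fs
  for (i in seq_len(n_epochs)) {
    ph <- stats::runif(1, 0, 2 * pi)
    arr[i, 1, ] <- sin(2 * pi * freq * tt + ph)
    arr[i, 2, ] <- sin(2 * pi * freq * tt + ph - lag)
  }
  epoch_set(arr, rep("tongue", n_epochs), fs,
            standard_montage()[seq_len(nch)], c(0, ns / fs))
}

random_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.5
}

random_graph <- function(n, p_edge = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  A + t(A)
}

# ---- independent brute-force graph oracle (n <= 8) ----------------------
# Distances by Floyd-Warshall; betweenness by exhaustive enumeration of all
# simple paths. Entirely independent of the igraph-based implementation.

fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# all simple paths from s to t, as list of vertex vectors
enumerate_paths <- function(A, s, t) {
  paths <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1)) {
      if (!(w %in% path)) recurse(c(path, w))
    }
  }
  recurse(s)
  paths
}

oracle_metrics <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  k <- rowSums(A)
  clustering <- sapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    pairs <- utils::combn(nb, 2)
    sum(A[t(pairs)]) / ncol(pairs)
  })
  path_length <- sapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) NaN else mean(d)
  })
  local_eff <- sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    Ds <- fw_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / Ds[upper.tri(Ds)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  })
  betweenness <- sapply(seq_len(n), function(v) {
    total <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      paths <- enumerate_paths(A, s, t)
      lens <- vapply(paths, length, 0L) - 1L
      shortest <- paths[lens == D[s, t]]
      if (!length(shortest)) next
      through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
      total <- total + through / length(shortest)
    }
    total
  })
  data.frame(degree = as.numeric(k), clustering = clustering,
             path_length = path_length, local_efficiency = local_eff,
             betweenness = betweenness)
}
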