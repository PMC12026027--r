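test_that("WPLI saturates on constant 90-degree lags and vanishes at zero lag", {
  ep <- make_lagged_epochs(6, nch = 3, lag = pi / 2, seed = 71)
  W <- wpli_matrix(ep, c(8, 12))$W
  expect_equal(W[1, 2], 1, tolerance = 1e-6)

  ep0 <- make_lagged_epochs(6, nch = 3, lag = 0, seed = 72)
  W0 <- wpli_matrix(ep0, c(8, 12))$W
  expect_equal(W0[1, 2], 0, tolerance = 1e-6)   # 0/0 convention

  expect_error(wpli_matrix(ep, c(8, 200)), "Nyquist")
  one <- epoch_set(ep$data[1, , , drop = FALSE], ep$labels[1], ep$fs,
                   ep$channel_names, ep$window)
  expect_error(wpli_matrix(one, c(8, 12)), "2 epochs")
})

test_that("WPLI is bounded, symmetric and invariant to scale and rotation", {
  set.seed(73)
  ep <- make_lagged_epochs(8, nch = 4, lag = pi / 3, seed = 73)
  M <- wpli_matrix(ep, c(8, 12))
  W <- M$W
  expect_true(all(W >= 0 & W <= 1))
  expect_true(isSymmetric(unname(W)))
  expect_true(all(diag(W) == 0))

  # per-channel amplitude scaling
  sc <- ep
  for (j in seq_len(4)) sc$data[, j, ] <- sc$data[, j, ] * (j * 2)
  expect_equal(wpli_matrix(sc, c(8, 12))$W, W, tolerance = 1e-9)

  # common time shift rotates both phases together
  rot <- ep
  rot$data <- rot$data[, , c(11:750, 1:10)]
  W2 <- wpli_matrix(rot, c(8, 12))$W
  expect_equal(W2[1, 2], W[1, 2], tolerance = 0.05)
})

test_that("WPLI numerator never exceeds its denominator", {
  ep <- make_lagged_epochs(5, nch = 5, lag = pi / 4, seed = 74)
  nch <- 5
  b <- miadapt:::design_fir_bandpass(ep$fs, 8, 12, 1)
  num <- den <- matrix(0, nch, nch)
  for (e in 1:5) {
    seg <- miadapt:::fir_apply_zerophase_mat(matrix(ep$data[e, , ], nch), b)
    z <- miadapt:::analytic_signal(seg)
    for (i in 1:nch) {
      imS <- Im(z[i, ] * Conj(t(z)))
      num[i, ] <- num[i, ] + colSums(imS)
      den[i, ] <- den[i, ] + colSums(abs(imS))
    }
  }
  expect_true(all(abs(num) <= den + 1e-9))
})

test_that("null WPLI on independent signals stays low", {
  set.seed(75)
  n_ep <- 20
  arr <- array(stats::rnorm(n_ep * 6 * 750), c(n_ep, 6, 750))
  ep <- epoch_set(arr, rep("tongue", n_ep), 250,
                  standard_montage()[1:6], c(0, 3))
  W <- wpli_matrix(ep, c(8, 12))$W
  expect_lt(mean(W[upper.tri(W)]), 0.1)
})

test_that("proportional thresholding keeps the exact top fraction", {
  set.seed(76)
  n <- 60
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2)
  W <- W + t(W)
  rownames(W) <- colnames(W) <- standard_montage()
  net <- threshold_top_fraction(W, 0.10)
  expect_equal(net$n_edges, 177)              # round(0.10 * 1770)
  expect_equal(sum(net$A) / 2, 177)
  expect_true(isSymmetric(unname(net$A)))
  expect_true(all(diag(net$A) == 0))

  # brute-force sort oracle on distinct weights
  w <- W[upper.tri(W)]
  cut <- sort(w, decreasing = TRUE)[177]
  expect_true(all(W[net$A == 1] >= cut))

  full <- threshold_top_fraction(W, 1)
  expect_equal(sum(full$A) / 2, 1770)

  expect_error(threshold_top_fraction(W, 0), "fraction")
  expect_error(threshold_top_fraction(W, 1.2), "fraction")
})

test_that("threshold ties break deterministically by (row, column) order", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.1)  # four-way tie at cut
  W <- W + t(W)
  n1 <- threshold_top_fraction(W, 0.5)   # keep round(0.5*6) = 3 edges
  n2 <- threshold_top_fraction(W, 0.5)
  expect_identical(n1$A, n2$A)
  expect_equal(sum(n1$A) / 2, 3)
  # ties resolved lexicographically: (1,2) 0.9 then (1,3) and (1,4)
  expect_equal(n1$A[1, 2], 1L)
  expect_equal(n1$A[1, 3], 1L)
  expect_equal(n1$A[1, 4], 1L)
})

test_that("networks and matrices write to readable delimited files", {
  set.seed(77)
  W <- matrix(stats::runif(16), 4); W <- (W + t(W)) / 2; diag(W) <- 0
  rownames(W) <- colnames(W) <- c("C3", "CZ", "C4", "FZ")
  cm <- structure(list(W = W, band = c(8, 12), band_tag = "alpha",
                       task_tag = "tongue", n_epochs = 5,
                       channel_names = rownames(W)),
                  class = "connectivity_matrix")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_network(cm, f1)
  back <- as.matrix(utils::read.table(f1, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(W), tolerance = 1e-9)

  net <- threshold_top_fraction(cm, 0.5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f2)
  edges <- utils::read.table(f2, sep = "\t", header = TRUE)
  expect_equal(nrow(edges), net$n_edges)
})
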