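test_that("the four extractors honour the dimensional contract", {
  ep <- make_two_class_epochs(35, seed = 10)
  expect_equal(dim(psd_features(ep)$values), c(70, 21))
  expect_equal(dim(wavelet_features(ep)$values), c(70, 36))
  expect_equal(dim(riemann_features(ep, riemann_fit(ep))$values), c(70, 12))
  expect_equal(dim(fbcsp_features(ep)$values), c(70, 24))
})

test_that("CSP solves the generalized eigenproblem with known answers", {
  # identical class covariances: every eigenvalue 1/2
  A <- random_spd(4, seed = 1)
  f_eq <- csp_fit(A, A, 2)
  expect_equal(f_eq$eigenvalues, rep(0.5, 4), tolerance = 1e-10)

  # axis-aligned closed form: eigenvalues 4/(4+1) and 1/(1+4)
  f <- csp_fit(diag(c(4, 1)), diag(c(1, 4)), 1)
  expect_equal(f$eigenvalues, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(f$W) > 1e-8, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))

  # whitening constraint on random instances
  for (s in 1:3) {
    C1 <- random_spd(5, seed = 100 + s)
    C2 <- random_spd(5, seed = 200 + s)
    ff <- csp_fit(C1, C2, 2)
    expect_lt(max(abs(t(ff$W) %*% (C1 + C2) %*% ff$W - diag(4))), 1e-6)
  }
})

test_that("CSP log-variance features are scale invariant and normalized", {
  ep <- make_two_class_epochs(12, nch = 8, ns = 500, seed = 3)
  f <- csp_fit(epochs_for_tasks(ep, "left_hand"),
               epochs_for_tasks(ep, "right_hand"), 2)
  fm <- csp_features(ep, f)
  expect_equal(dim(fm$values), c(24, 4))
  scaled <- ep
  scaled$data <- scaled$data * 10
  fm10 <- csp_features(scaled, f)
  expect_equal(fm$values, fm10$values, tolerance = 1e-10)
  expect_equal(rowSums(exp(fm$values)), rep(1, 24), tolerance = 1e-10)
})

test_that("CSP discriminates synthetic spatial band-power patterns", {
  ep <- make_two_class_epochs(20, nch = 10, planted_channels = 3:5,
                              seed = 4)
  fb <- miadapt:::epochs_bandpass(ep, 8, 12)
  f <- csp_fit(epochs_for_tasks(fb, "left_hand"),
               epochs_for_tasks(fb, "right_hand"), 1)
  # top filter variance ratio between classes exceeds 2
  lam <- f$eigenvalues
  ratio <- max(lam[1] / (1 - lam[1]), (1 - lam[length(lam)]) / lam[length(lam)])
  expect_gt(ratio, 2)
})

test_that("multitaper PSD localizes tones and matches flat-noise level", {
  fs <- 250
  n <- 750
  tt <- seq_len(n) / fs
  p <- multitaper_psd(sin(2 * pi * 20 * tt), fs)
  expect_equal(p$freq[which.max(p$psd)], 20, tolerance = 1)

  set.seed(11)
  sigma2 <- 4
  lev <- replicate(20, {
    pw <- multitaper_psd(stats::rnorm(n, sd = 2), fs)
    mean(pw$psd[pw$freq >= 8 & pw$freq <= 30])
  })
  expect_equal(mean(lev), sigma2 / (fs / 2), tolerance = 0.2)

  ep <- make_two_class_epochs(3, seed = 5)
  expect_error(psd_features(ep, band = c(8, 200)), "Nyquist")

  # the batched feature path agrees with the scalar estimator
  fm <- psd_features(ep)
  chans <- sensorimotor_channels()
  idx <- match(chans[1:3], ep$channel_names)
  for (j in 1:3) {
    pw <- multitaper_psd(ep$data[2, idx[j], ], ep$fs)
    want <- mean(pw$psd[pw$freq >= 8 & pw$freq <= 30])
    expect_equal(unname(fm$values[2, j]), want, tolerance = 1e-10)
  }
})

test_that("wavelet decompositions match hand-computed Haar results", {
  # Haar on [1,1,-1,-1]: only the level-2 detail survives
  d <- dwt(c(1, 1, -1, -1), "haar", levels = 2)
  expect_equal(d$d1, c(0, 0), tolerance = 1e-12)
  expect_equal(abs(d$d2), 2, tolerance = 1e-12)
  expect_equal(d$a2, 0, tolerance = 1e-12)

  # details of a constant signal vanish at every level
  dc <- dwt(rep(3, 64), "db4", levels = 5)
  for (lev in 1:5) expect_lt(max(abs(dc[[paste0("d", lev)]])), 1e-10)

  ep <- make_two_class_epochs(2, nch = 60, ns = 256, seed = 6)
  ep$data[] <- 1
  fm <- wavelet_features(ep)
  sd_cols <- grep("_sd$", colnames(fm$values))
  dwt_detail_sd <- grep("^dwt_d", colnames(fm$values)[sd_cols], value = TRUE)
  expect_true(all(abs(fm$values[, paste0(sub("_sd$", "", dwt_detail_sd),
                                         "_sd")]) < 1e-10))

  expect_error(dwt(1:64, "nope"), "supported families")
})

test_that("wavelet packet leaves are selected by spectral overlap", {
  # at fs 250, level 3: leaf width 15.625 Hz; 8-30 Hz touches the two
  # lowest-frequency leaves, ties resolved by ascending band
  leaves <- miadapt:::wpd_select_leaves(250, 3, c(8, 30), 6)
  ranks <- sapply(leaves - 1L, miadapt:::wpd_frequency_rank, levels = 3)
  expect_true(all(c(0, 1) %in% ranks))
  expect_length(leaves, 6)
  # frequency ranks of the full tree are a permutation of 0..7
  all_ranks <- sapply(0:7, miadapt:::wpd_frequency_rank, levels = 3)
  expect_setequal(all_ranks, 0:7)
})

test_that("Riemannian mean obeys closed forms and equivariance", {
  A <- random_spd(3, seed = 21)
  expect_equal(riemann_mean(list(A, A)), A, tolerance = 1e-7)

  # commuting case: elementwise geometric mean
  expect_equal(riemann_mean(list(diag(c(1, 1)), diag(c(4, 4)))),
               diag(c(2, 2)), tolerance = 1e-7)

  # congruence equivariance on random instances
  B <- random_spd(3, seed = 22)
  G <- matrix(stats::rnorm(9), 3); G <- G + diag(3) * 3
  m1 <- riemann_mean(list(G %*% A %*% t(G), G %*% B %*% t(G)))
  m2 <- G %*% riemann_mean(list(A, B)) %*% t(G)
  expect_equal(m1, m2, tolerance = 1e-6)

  # two-matrix closed form: the geodesic midpoint A #_1/2 B
  As <- miadapt:::spd_sqrt(A)
  Ais <- miadapt:::spd_invsqrt(A)
  mid <- As %*% miadapt:::spd_sqrt(Ais %*% B %*% Ais) %*% As
  expect_equal(riemann_mean(list(A, B)), mid, tolerance = 1e-6)
})

test_that("Riemannian distance and tangent maps are mutually consistent", {
  A <- random_spd(4, seed = 31)
  expect_equal(riemann_distance(A, A), 0, tolerance = 1e-7)
  expect_equal(riemann_distance(diag(2), diag(c(exp(2), exp(2)))),
               2 * sqrt(2), tolerance = 1e-10)

  B <- random_spd(4, seed = 32)
  tv <- tangent_map(list(A, B), A)
  expect_equal(ncol(tv), 4 * 5 / 2)
  expect_equal(unname(tv[1, ]), rep(0, 10), tolerance = 1e-8)
  # isometry at the reference point: norm equals the distance
  expect_equal(sqrt(sum(tv[2, ]^2)), riemann_distance(A, B),
               tolerance = 1e-8)
})

test_that("mutual information behaves on separating and null features", {
  labels <- rep(c("a", "b"), each = 35)
  sep <- c(stats::rnorm(35, -10), stats::rnorm(35, 10))
  expect_equal(mutual_information(sep, labels), 1, tolerance = 0.05)
  # the plug-in estimate of a label-independent feature sits near its
  # finite-sample bias, (bins - 1) / (2 n ln 2) ~ 0.072 bits at n = 70,
  # far below the 1-bit separating case
  set.seed(41)
  nulls <- replicate(20, mutual_information(stats::rnorm(70), labels))
  expect_lt(stats::median(nulls), 0.12)
  expect_gt(mutual_information(sep, labels) / stats::median(nulls), 5)
  # monotone rescaling with quantile bins leaves MI unchanged
  x <- stats::rnorm(70)
  expect_equal(mutual_information(x, labels),
               mutual_information(exp(x), labels), tolerance = 1e-12)
  expect_error(mutual_information(x, rep("a", 70)), "single class")
})

test_that("FBCSP reduces to CSP per band and permutes with the bank", {
  ep <- make_two_class_epochs(10, nch = 8, ns = 500, seed = 51)
  one <- matrix(c(8, 12), 1)
  fm1 <- fbcsp_features(ep, bands = one)
  fb <- miadapt:::epochs_bandpass(ep, 8, 12)
  f <- csp_fit(epochs_for_tasks(fb, "left_hand"),
               epochs_for_tasks(fb, "right_hand"), 2)
  expect_equal(unname(fm1$values), unname(csp_features(fb, f)$values),
               tolerance = 1e-10)

  two <- rbind(c(8, 12), c(12, 16))
  fm2 <- fbcsp_features(ep, bands = two)
  fm2r <- fbcsp_features(ep, bands = two[2:1, , drop = FALSE])
  expect_equal(unname(fm2$values), unname(fm2r$values[, c(5:8, 1:4)]),
               tolerance = 1e-10)
  expect_s3_class(attr(fm2, "mi_report"), "data.frame")
})
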