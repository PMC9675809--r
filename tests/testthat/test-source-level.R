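# shared small geometry for the beamformer tests
bf_setup <- function(n_pos = 24, spacing = 0.016) {
  sens <- make_sensor_array(n_pos, 0.09, 0.102)
  grid <- tiny_grid(spacing = spacing)
  list(sens = sens, grid = grid, lf = compute_lead_field(grid, sens))
}

test_that("covariance estimation: near-diagonal on white noise, duplication invariant", {
  withr::with_seed(21, {
    arr <- array(rnorm(20 * 10 * 50), c(20, 10, 50))
  })
  ep <- structure(list(data = arr, fs = 150, times = seq_len(50) / 150,
                       events = data.frame(condition = rep("a", 20)),
                       band = "broadband"),
                  class = "epoch_set")
  C <- data_covariance(ep, 0)
  offdiag <- C - diag(diag(C))
  expect_lt(max(abs(offdiag)), 0.2)          # large-sample near-diagonality
  expect_equal(mean(diag(C)), 1, tolerance = 0.1)
  # duplicated epochs give the same covariance
  ep2 <- ep; ep2$data <- ep$data[c(1:20, 1:20), , ]
  C2 <- data_covariance(ep2, 0)
  expect_equal(unclass(C2), unclass(C), tolerance = 1e-2, ignore_attr = TRUE)
  # rank-deficient data without loading is flagged
  ep3 <- ep; ep3$data <- ep3$data * 0
  expect_warning(C3 <- data_covariance(ep3, 0), "positive definite")
  expect_false(attr(C3, "pd"))
  ep4 <- ep; ep4$data[1, 1, 1] <- NaN
  expect_error(data_covariance(ep4), class = "nonfinite_data")
})

test_that("LCMV satisfies unit gain and recovers a noiseless dipole exactly", {
  setup <- bf_setup()
  lf <- setup$lf; grid <- setup$grid
  d <- which(grid$roi == "auditory_R")[2]
  fr <- attr(lf, "frames")[[d]]
  tt <- seq(0, 1, by = 1 / 150)
  moment <- 30e-9
  l <- lf[, d, 1]
  X <- outer(l, sin(2 * pi * 3 * tt) * moment)
  C <- tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)
  C <- C + diag(1e-10 * mean(diag(C)), nrow(C))
  attr(C, "pd") <- TRUE; attr(C, "lambda") <- 0
  w <- suppressMessages(lcmv_weights(lf, C))
  # unit gain at the oriented lead-field column for every dipole
  withr::with_seed(1, check <- sample(which(seq_len(dim(lf)[2]) != 0), 25))
  for (dd in check) {
    if (all(w$W[dd, ] == 0)) next
    ldd <- lf[, dd, 1] * w$orientation[dd, 1] + lf[, dd, 2] * w$orientation[dd, 2]
    expect_equal(sum(w$W[dd, ] * ldd), 1, tolerance = 1e-6)
  }
  # amplitude round trip within 1%
  ev <- structure(list(data = X, times = tt, fs = 150, n_trials = 1,
                       condition = "memorized_tonal", band = "slow"),
                  class = "evoked")
  src <- reconstruct(w, ev)
  expect_equal(max(abs(src$data[d, ])), moment, tolerance = 0.01)
  # localization: output power peaks at the true dipole
  pw <- source_power(w, C)
  expect_equal(which.max(pw), d)
  # zero input, zero output; linearity
  ev0 <- ev; ev0$data <- ev0$data * 0
  expect_true(all(reconstruct(w, ev0)$data == 0))
  ev2 <- ev; ev2$data <- 2 * ev2$data
  expect_equal(reconstruct(w, ev2)$data, 2 * src$data, tolerance = 1e-12)
})

test_that("LCMV localizes a single dipole within two grid steps at 20 dB SNR", {
  setup <- bf_setup()
  lf <- setup$lf; grid <- setup$grid
  d <- which(grid$roi == "auditory_L")[3]
  tt <- seq(0, 2, by = 1 / 150)
  l <- lf[, d, 1]
  X <- outer(l, sin(2 * pi * 3 * tt) * 30e-9)
  sig_pow <- mean(X^2)
  withr::with_seed(33, {
    N <- matrix(rnorm(length(X), 0, sqrt(sig_pow / 100)), nrow(X))
  })
  Xn <- X + N
  C <- tcrossprod(Xn - rowMeans(Xn)) / (ncol(Xn) - 1)
  C <- C + diag(0.001 * mean(diag(C)), nrow(C))
  attr(C, "pd") <- TRUE; attr(C, "lambda") <- 0
  w <- suppressMessages(lcmv_weights(lf, C))
  pw <- source_power(w, C)
  loc <- which.max(pw)
  dist <- sqrt(sum((as.numeric(grid[loc, c("x", "y", "z")]) -
                      as.numeric(grid[d, c("x", "y", "z")]))^2))
  expect_lte(dist, 2 * attr(grid, "spacing") + 1e-9)
})

test_that("first-level contrast is the condition difference with optional peak alignment", {
  withr::with_seed(13, {
    m <- matrix(rnorm(50), 10, 5)
    n <- matrix(rnorm(50), 10, 5)
  })
  sm <- structure(list(data = m, times = (0:4) / 150), class = "source_estimate")
  sn <- structure(list(data = n, times = (0:4) / 150), class = "source_estimate")
  expect_equal(first_level(sm, sn), m - n)
  # identical conditions cancel
  expect_true(all(first_level(sm, sm) == 0))
  # orientation flip of both conditions flips the contrast sign only
  smf <- sm; smf$data <- -smf$data
  snf <- sn; snf$data <- -snf$data
  expect_equal(abs(first_level(smf, snf)), abs(first_level(sm, sn)))
  # peak alignment leaves the magnitude unchanged
  expect_equal(abs(first_level(smf, snf, align = "peak")),
               abs(first_level(sm, sn, align = "peak")))
  expect_error(first_level(sm, structure(list(data = m[1:5, ]),
                                         class = "source_estimate")),
               class = "missing_condition")
})

test_that("group-level maps are calibrated under the null and flag degeneracy", {
  grid <- tiny_grid()
  n_dip <- nrow(grid)
  withr::with_seed(17, {
    contrasts <- lapply(1:10, function(i) matrix(rnorm(n_dip * 6), n_dip, 6))
  })
  gm <- group_level(contrasts, grid, voxel_alpha = 0.05)
  rate <- mean(gm$p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  expect_equal(gm$df, 9)
  # degenerate cells flagged
  contrasts0 <- lapply(1:5, function(i) matrix(1, 4, 2))
  gm0 <- group_level(contrasts0, grid, 0.05)
  expect_true(all(gm0$degenerate))
  expect_error(group_level(contrasts[1], grid), class = "too_few_subjects")
})

test_that("tone windows tile 0-1250 ms and the family alpha is 0.01/10", {
  tw <- tone_windows()
  expect_equal(tw$t_start, c(0, 0.25, 0.5, 0.75, 1.0))
  expect_equal(tw$t_end, c(0.25, 0.5, 0.75, 1.0, 1.25))
  expect_equal(tw$t_start[-1], tw$t_end[-5])   # contiguous, non-overlapping
  grid <- tiny_grid()
  withr::with_seed(3, {
    contrasts <- lapply(1:6, function(i) matrix(rnorm(nrow(grid) * 5), nrow(grid), 5))
  })
  tab <- tone_window_mcs(contrasts, grid, times = NULL, band_count = 2,
                         n_perm = 120, seed = 5)
  expect_equal(attr(tab, "alpha_adjusted"), 0.001)
  tab1 <- tone_window_mcs(contrasts, grid, times = NULL, band_count = 1,
                          n_perm = 120, seed = 5)
  expect_equal(attr(tab1, "alpha_adjusted"), 0.002)
})

test_that("window MCS recovers an injected ROI effect in the right windows", {
  grid <- tiny_grid(spacing = 0.02)
  roi <- which(grid$roi == "cingulate")
  withr::with_seed(29, {
    contrasts <- lapply(1:8, function(i) {
      m <- matrix(rnorm(nrow(grid) * 5, 0, 1), nrow(grid), 5)
      m[roi, 3:5] <- m[roi, 3:5] + 4
      m
    })
  })
  tab <- tone_window_mcs(contrasts, grid, times = NULL, band_count = 1,
                         n_perm = 300, seed = 9)
  sig <- tab[tab$significant & tab$direction == "A>B", ]
  expect_true(all(3:5 %in% sig$window))
  # clusters in the injected windows are cingulate-dominated
  for (w in 3:5) {
    rows <- sig[sig$window == w, ]
    expect_true(any(rows$roi_majority == "cingulate"))
  }
  # no-effect windows produce no significant A>B cingulate clusters
  early <- sig[sig$window %in% 1:2, ]
  expect_false(any(early$roi_majority == "cingulate" & early$k > 3))
  # identical conditions -> empty tables
  tab0 <- tone_window_mcs(lapply(contrasts, function(m) m * 0 + 1e-14 *
                                   matrix(rnorm(length(m)), nrow(m))),
                          grid, times = NULL, band_count = 1,
                          n_perm = 120, seed = 2)
  expect_equal(sum(tab0$significant), 0)
})

test_that("piece and band contrasts behave symmetrically and respect normalization", {
  grid <- tiny_grid(spacing = 0.02)
  n_dip <- nrow(grid)
  withr::with_seed(31, {
    tonal <- lapply(1:6, function(i)
      structure(list(data = matrix(rnorm(n_dip * 188), n_dip, 188),
                     times = seq(0, 1.25, length.out = 188)),
                class = "source_estimate"))
    atonal <- lapply(1:6, function(i)
      structure(list(data = matrix(rnorm(n_dip * 188), n_dip, 188),
                     times = seq(0, 1.25, length.out = 188)),
                class = "source_estimate"))
  })
  tab_ab <- memorized_piece_contrast(tonal, atonal, grid,
                                     times = tonal[[1]]$times,
                                     n_perm = 120, seed = 3)
  tab_ba <- memorized_piece_contrast(atonal, tonal, grid,
                                     times = tonal[[1]]$times,
                                     n_perm = 120, seed = 3)
  # swapping the pieces swaps the direction labels
  expect_equal(sum(tab_ab$direction == "A>B") + sum(tab_ab$direction == "B>A"),
               sum(tab_ba$direction == "A>B") + sum(tab_ba$direction == "B>A"))
  # identical pieces -> nothing significant
  tab_same <- memorized_piece_contrast(tonal, tonal, grid,
                                       times = tonal[[1]]$times,
                                       n_perm = 120, seed = 3)
  expect_equal(sum(tab_same$significant), 0)

  # band contrast: invariant to a global gain on either band
  wm_slow <- lapply(1:6, function(i) matrix(rnorm(n_dip * 5), n_dip, 5))
  wm_fast <- lapply(1:6, function(i) matrix(rnorm(n_dip * 5), n_dip, 5))
  t1 <- band_contrast(wm_slow, wm_fast, grid, n_perm = 120, seed = 4)
  t2 <- band_contrast(lapply(wm_slow, function(m) 100 * m), wm_fast, grid,
                      n_perm = 120, seed = 4)
  expect_equal(t1$k, t2$k)
  expect_equal(t1$p_value, t2$p_value)
})

test_that("familiarity correlations: perfect linearity, recovery and degeneracy", {
  grid <- tiny_grid(spacing = 0.02)
  n_dip <- nrow(grid)
  fam <- c(1, 2, 3, 4, 5, 6, 7, 4, 2, 5)
  roi <- which(grid$roi == "auditory_L")
  withr::with_seed(41, {
    wm <- lapply(seq_along(fam), function(i) {
      m <- matrix(rnorm(n_dip * 5), n_dip, 5)
      m[roi, ] <- m[roi, ] + 2 * fam[i]
      m
    })
  })
  res <- familiarity_correlation(fam, wm, grid, alpha = 0.05,
                                 n_perm = 200, seed = 6)
  # a dipole with activity = a * rating exactly gives r = 1
  wm_exact <- lapply(seq_along(fam), function(i) {
    m <- matrix(0, n_dip, 5); m[1, ] <- 3 * fam[i]; m
  })
  res_exact <- familiarity_correlation(fam, wm_exact, grid, n_perm = 100,
                                       seed = 2)
  expect_equal(unname(res_exact$r[1, 1]), 1, tolerance = 1e-9)
  # recovery: significant positive clusters dominated by the injected ROI
  sig <- res$clusters[res$clusters$significant & res$clusters$direction == "r>0", ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$roi_majority == "auditory_L"))
  # zero-variance ratings are a typed error
  expect_error(familiarity_correlation(rep(4, 10), wm, grid),
               class = "degenerate_ratings")
  expect_error(familiarity_correlation(c(1, 2), wm[1:2], grid),
               class = "too_few_subjects")
})

test_that("vector weights give orientation-free magnitudes and scalar stays linear", {
  setup <- bf_setup(16, 0.024)
  lf <- setup$lf; grid <- setup$grid
  withr::with_seed(51, {
    X <- matrix(rnorm(nrow(setup$sens) * 100, 0, 1e-12), nrow(setup$sens), 100)
  })
  C <- tcrossprod(X - rowMeans(X)) / 99
  C <- C + diag(0.05 * mean(diag(C)), nrow(C))
  attr(C, "pd") <- TRUE; attr(C, "lambda") <- 1
  wv <- lcmv_weights(lf, C, orientation = "vector")
  expect_equal(wv$type, "vector")
  ev <- structure(list(data = X[, 1:20], times = seq(0, 1.25, length.out = 20),
                       fs = 150, n_trials = 1, condition = "x", band = "slow"),
                  class = "evoked")
  src <- reconstruct(wv, ev, normalize = TRUE)
  expect_false(is.null(src$data2))
  wm <- window_magnitude(src)
  expect_true(all(wm >= 0))
  expect_equal(dim(wm), c(nrow(grid), 5))
  # window_contrast of an estimate against itself is exactly zero
  expect_true(all(window_contrast(src, src) == 0))
})
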