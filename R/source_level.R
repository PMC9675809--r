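#' Regularized data covariance of an epoch set
#'
#' Sample covariance over the concatenated epoch samples plus Tikhonov
#' loading `lambda * I`, with `lambda = lambda_fraction * mean(diag(C))`.
#'
#' @param ep an `epoch_set` with >= 2 epochs.
#' @param lambda_fraction regularization as a fraction of the mean sensor
#'   power (default 0.05).
#' @return covariance matrix (channels x channels) with attributes `lambda`
#'   and `pd` (TRUE if positive definite).
#' @export
data_covariance <- function(ep, lambda_fraction = 0.05) {
  .assert(dim(ep$data)[1] >= 2, "need at least 2 epochs", "too_few_epochs")
  n_ch <- dim(ep$data)[2]
  X <- matrix(aperm(ep$data, c(2, 1, 3)), n_ch)   # channels x (trials*samples)
  .assert(all(is.finite(X)), "non-finite values in epoch data",
          "nonfinite_data")
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  lambda <- lambda_fraction * mean(diag(C))
  C <- C + diag(lambda, n_ch)
  pd <- inherits(try(chol(C), silent = TRUE), "matrix")
  if (!pd) warning("covariance is not positive definite (increase lambda_fraction)")
  dimnames(C) <- list(dimnames(ep$data)[[2]], dimnames(ep$data)[[2]])
  structure(C, lambda = lambda, pd = pd)
}

#' LCMV beamformer spatial filters
#'
#' For every dipole, the scalar orientation is the tangential direction
#' maximizing output source power (the eigenvector of the smaller eigenvalue
#' of `L_d' C^-1 L_d`), and the weights are the unit-gain minimum-variance
#' solution `w = C^-1 l / (l' C^-1 l)` for the oriented lead-field column
#' `l`, so `w'l = 1` (unit gain at the target dipole). Dipoles with a
#' numerically zero lead field (sphere center) get an all-zero filter row
#' and are listed in the `skipped` attribute.
#'
#' @param lf a `lead_field`.
#' @param C regularized covariance from [data_covariance()].
#' @param orientation `"power"` (default): scalar filter along the
#'   power-maximizing tangential direction, appropriate when the source of
#'   interest contributes appreciably to the covariance (e.g. single-source
#'   localization); `"vector"`: one unit-gain filter per tangential
#'   component, whose component-norm magnitude is orientation-free and is
#'   the robust choice for mapping weak evoked effects whose share of the
#'   covariance is too small to steer the orientation estimate.
#' @return a `beamformer_weights` object: `W` (dipoles x channels; the
#'   scalar filter, or the first-component filter with the second in `W2`),
#'   `orientation` (dipoles x 2 tangential coefficients, sign-normalized;
#'   scalar type only), `lambda`, and the grid.
#' @export
lcmv_weights <- function(lf, C, orientation = c("power", "vector")) {
  orientation <- match.arg(orientation)
  if (orientation == "vector") return(.lcmv_vector(lf, C))
  pd <- attr(C, "pd")
  .assert(is.null(pd) || isTRUE(pd), "covariance must be positive definite",
          "covariance_not_pd")
  n_ch <- dim(lf)[1]
  n_dip <- dim(lf)[2]
  R <- chol(C)
  Ci <- chol2inv(R)
  W <- matrix(0, n_dip, n_ch)
  ori <- matrix(NA_real_, n_dip, 2)
  skipped <- integer(0)
  # Ci %*% L for both orientations in two big products
  CiL1 <- Ci %*% lf[, , 1]
  CiL2 <- Ci %*% lf[, , 2]
  m11 <- colSums(lf[, , 1] * CiL1)
  m12 <- colSums(lf[, , 1] * CiL2)
  m22 <- colSums(lf[, , 2] * CiL2)
  scale2 <- colSums(lf[, , 1]^2) + colSums(lf[, , 2]^2)
  for (d in seq_len(n_dip)) {
    if (scale2[d] < .Machine$double.eps) {
      skipped <- c(skipped, d)
      next
    }
    # eigenvector of the smaller eigenvalue of the 2x2 [m11 m12; m12 m22]
    tr <- m11[d] + m22[d]
    det2 <- m11[d] * m22[d] - m12[d]^2
    lam_min <- tr / 2 - sqrt(max(tr^2 / 4 - det2, 0))
    u <- c(m12[d], lam_min - m11[d])
    if (sqrt(sum(u^2)) < 1e-14 * abs(tr)) u <- c(1, 0)
    u <- u / sqrt(sum(u^2))
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    l <- lf[, d, 1] * u[1] + lf[, d, 2] * u[2]
    Cil <- CiL1[, d] * u[1] + CiL2[, d] * u[2]
    W[d, ] <- Cil / sum(l * Cil)
    ori[d, ] <- u
  }
  if (length(skipped))
    message(sprintf("%d dipole(s) with zero lead field skipped", length(skipped)))
  w_norm <- sqrt(rowSums(W^2))
  structure(list(type = "scalar", W = W, orientation = ori, w_norm = w_norm,
                 lambda = attr(C, "lambda"), grid = attr(lf, "grid"),
                 skipped = skipped),
            class = "beamformer_weights")
}

# vector LCMV: independent unit-gain minimum-variance filters for the two
# tangential lead-field columns of every dipole
.lcmv_vector <- function(lf, C) {
  pd <- attr(C, "pd")
  .assert(is.null(pd) || isTRUE(pd), "covariance must be positive definite",
          "covariance_not_pd")
  Ci <- chol2inv(chol(C))
  n_dip <- dim(lf)[2]
  Ws <- lapply(1:2, function(o) {
    CiL <- Ci %*% lf[, , o]
    den <- colSums(lf[, , o] * CiL)
    W <- t(CiL) / ifelse(abs(den) > 0, den, Inf)
    W[!is.finite(W)] <- 0
    W
  })
  skipped <- which(rowSums(abs(Ws[[1]])) == 0 & rowSums(abs(Ws[[2]])) == 0)
  structure(list(type = "vector", W = Ws[[1]], W2 = Ws[[2]],
                 w_norm = sqrt(rowSums(Ws[[1]]^2)),
                 w_norm2 = sqrt(rowSums(Ws[[2]]^2)),
                 lambda = attr(C, "lambda"), grid = attr(lf, "grid"),
                 skipped = skipped),
            class = "beamformer_weights")
}

#' @export
print.beamformer_weights <- function(x, ...) {
  cat(sprintf("<beamformer_weights: %d dipoles x %d channels, lambda = %.3g>\n",
              nrow(x$W), ncol(x$W), x$lambda))
  invisible(x)
}

#' Reconstruct source activity with beamformer weights
#'
#' Applies the spatial filters to an evoked response (dipoles x samples) or
#' to every epoch of an epoch set (trials x dipoles x samples). Linear.
#' With `normalize = TRUE` each dipole's filter is rescaled to unit noise
#' gain (`w / ||w||`): amplitudes are then in pseudo-z-like units rather
#' than A.m, which removes the depth-dependent noise amplification of the
#' unit-gain minimum-variance filter and is the appropriate scaling for
#' across-voxel mapping statistics; leave `FALSE` to recover physical
#' source amplitudes.
#'
#' @param w a `beamformer_weights`.
#' @param x an `evoked` or `epoch_set`.
#' @param normalize unit-noise-gain scaling (default FALSE).
#' @return a `source_estimate`: `data` (dipoles x samples or trials x
#'   dipoles x samples), `times`, grid, condition/band labels carried over.
#' @export
reconstruct <- function(w, x, normalize = FALSE) {
  vector_type <- identical(w$type, "vector")
  if (normalize) {
    sc <- ifelse(w$w_norm > 0, 1 / w$w_norm, 0)
    w$W <- w$W * sc
    if (vector_type) {
      sc2 <- ifelse(w$w_norm2 > 0, 1 / w$w_norm2, 0)
      w$W2 <- w$W2 * sc2
    }
  }
  if (vector_type) {
    .assert(inherits(x, "evoked"), "vector weights reconstruct evoked data",
            "channel_mismatch")
    .assert(ncol(w$W) == nrow(x$data), "channel count mismatch",
            "channel_mismatch")
    return(structure(list(data = w$W %*% x$data, data2 = w$W2 %*% x$data,
                          times = x$times, grid = w$grid,
                          condition = x$condition, band = x$band),
                     class = "source_estimate"))
  }
  if (inherits(x, "evoked")) {
    .assert(ncol(w$W) == nrow(x$data), "channel count mismatch",
            "channel_mismatch")
    est <- w$W %*% x$data
    structure(list(data = est, times = x$times, grid = w$grid,
                   condition = x$condition, band = x$band),
              class = "source_estimate")
  } else if (inherits(x, "epoch_set")) {
    .assert(ncol(w$W) == dim(x$data)[2], "channel count mismatch",
            "channel_mismatch")
    n_tr <- dim(x$data)[1]
    est <- array(0, c(n_tr, nrow(w$W), dim(x$data)[3]))
    for (k in seq_len(n_tr)) est[k, , ] <- w$W %*% x$data[k, , ]
    structure(list(data = est, times = x$times, grid = w$grid,
                   events = x$events, band = x$band),
              class = "source_estimate")
  } else .err("x must be an evoked or epoch_set", "channel_mismatch")
}

#' Output source power of the beamformer filters
#'
#' `p_d = w_d' C w_d` per dipole: the variance each spatial filter passes,
#' used to localize the dominant source.
#'
#' @param w a `beamformer_weights`.
#' @param C covariance matrix.
#' @return numeric vector, one power value per dipole.
#' @export
source_power <- function(w, C) {
  rowSums((w$W %*% C) * w$W)
}

#' First-level (within-subject) memorized-minus-novel contrast
#'
#' Difference of the two condition-mean source estimates. The beamformer
#' sign ambiguity is handled by the deterministic orientation sign
#' convention of [lcmv_weights()] (first tangential coefficient positive),
#' which is consistent across subjects sharing one sensor/grid geometry, so
#' no data-dependent alignment is applied by default. `align = "peak"`
#' additionally flips each dipole so the subject's mean time course over
#' both conditions has a positive peak; note this couples the alignment
#' statistic to the contrast and can bias it when the condition variances
#' differ, so it is not the default. When a dipole's orientation is flipped
#' (both conditions together), only the contrast's sign changes, never its
#' magnitude.
#'
#' @param src_mem,src_nov `source_estimate`s (dipoles x samples) for the
#'   memorized and novel condition means of one subject/band/piece.
#' @param align `"none"` (default) or `"peak"`.
#' @return matrix dipoles x samples of the contrast.
#' @export
first_level <- function(src_mem, src_nov, align = c("none", "peak")) {
  align <- match.arg(align)
  .assert(!is.null(src_mem) && !is.null(src_nov),
          "both condition estimates are required", "missing_condition")
  .assert(identical(dim(src_mem$data), dim(src_nov$data)),
          "condition estimates must share dimensions", "missing_condition")
  d <- src_mem$data - src_nov$data
  if (align == "peak") {
    m <- (src_mem$data + src_nov$data) / 2
    peak <- m[cbind(seq_len(nrow(m)), max.col(abs(m), ties.method = "first"))]
    d <- d * ifelse(peak < 0, -1, 1)
  }
  d
}

#' Group-level one-sample t-map over subject contrasts
#'
#' One-sample t-test across subjects at every dipole/timepoint, binarized at
#' `voxel_alpha` and split by sign into two direction maps on the 3D source
#' lattice.
#'
#' @param contrasts list (one per subject) of dipoles x samples (or dipoles
#'   x windows) contrast matrices.
#' @param grid the `source_grid`.
#' @param voxel_alpha per-dipole threshold (default 0.05).
#' @return a `group_stat_map`: `t`, `p` (dipoles x samples), `df`,
#'   `degenerate` mask, and the grid.
#' @export
group_level <- function(contrasts, grid, voxel_alpha = 0.05) {
  n <- length(contrasts)
  .assert(n >= 2, "need at least 2 subjects", "too_few_subjects")
  dims <- dim(contrasts[[1]])
  X <- t(vapply(contrasts, as.numeric, numeric(prod(dims))))
  mt <- .mass_t(X)
  structure(list(t = matrix(mt$t, dims[1], dims[2]),
                 p = matrix(mt$p, dims[1], dims[2]),
                 df = mt$df, alpha = voxel_alpha,
                 degenerate = matrix(mt$degenerate, dims[1], dims[2]),
                 grid = grid),
            class = "group_stat_map")
}

#' The five 250-ms tone windows of an excerpt
#'
#' Contiguous, non-overlapping windows covering 0-1250 ms, one per tone.
#'
#' @return data frame with `window`, `t_start`, `t_end` (seconds).
#' @export
tone_windows <- function() {
  data.frame(window = 1:5, t_start = (0:4) * 0.25, t_end = (1:5) * 0.25)
}

#' Magnitude window contrast between two condition source estimates
#'
#' Per-tone-window contrast `|window-mean of A| - |window-mean of B|` per
#' dipole. Comparing window-mean magnitudes resolves the beamformer sign
#' ambiguity (the reconstructed polarity at a dipole is arbitrary with
#' respect to the true source orientation), so the contrast is consistent
#' across subjects without any alignment step. Normalized (unit-noise-gain)
#' estimates should be used so the magnitude comparison is not
#' depth-biased.
#'
#' @param src_a,src_b `source_estimate`s (dipoles x samples).
#' @return matrix dipoles x 5 of window-mean magnitude differences.
#' @export
window_contrast <- function(src_a, src_b) {
  .assert(identical(dim(src_a$data), dim(src_b$data)),
          "condition estimates must share dimensions", "missing_condition")
  window_magnitude(src_a) - window_magnitude(src_b)
}

#' Window-mean magnitude of a source estimate
#'
#' For scalar estimates, the absolute window mean per dipole; for vector
#' estimates, the norm over the two tangential components of the window
#' means (orientation-free activity magnitude).
#'
#' @param src a `source_estimate`.
#' @return matrix dipoles x 5.
#' @export
window_magnitude <- function(src) {
  w1 <- window_means(src$data, src$times)
  if (is.null(src$data2)) return(abs(w1))
  sqrt(w1^2 + window_means(src$data2, src$times)^2)
}

#' Sub-average a dipoles-by-samples matrix within the five tone windows
#'
#' @param x matrix dipoles x samples.
#' @param times time axis (s) of the columns.
#' @return matrix dipoles x 5 of window means.
#' @export
window_means <- function(x, times) {
  tw <- tone_windows()
  vapply(seq_len(5), function(w) {
    sel <- times >= tw$t_start[w] & times < ifelse(w == 5, tw$t_end[w] + 1e-9,
                                                   tw$t_end[w])
    rowMeans(x[, sel, drop = FALSE])
  }, numeric(nrow(x)))
}

# place per-dipole binary values on the 3D source lattice
.grid_binary_map <- function(values, grid, direction = NULL) {
  dims <- attr(grid, "lattice_dim")
  arr <- array(0L, dims)
  valid <- array(FALSE, dims)
  idx <- cbind(grid$ix, grid$iy, grid$iz)
  valid[idx] <- TRUE
  arr[idx] <- as.integer(values != 0)
  binary_map(arr, valid, direction)
}

# majority ROI label of a spatial cluster on the grid, plus the full label
# tally as a "label:count;..." string for the cluster tables
.roi_vote <- function(cells, grid) {
  key <- paste(grid$ix, grid$iy, grid$iz)
  lab <- grid$roi[match(paste(cells[, 1], cells[, 2], cells[, 3]), key)]
  tab <- sort(table(lab), decreasing = TRUE)
  list(majority = names(tab)[1],
       fraction = as.numeric(tab[1]) / nrow(cells),
       counts = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                      collapse = ";"))
}

.empty_window_table <- function() {
  data.frame(window = integer(0), direction = character(0),
             cluster_number = integer(0), k = integer(0),
             roi_majority = character(0), roi_fraction = numeric(0),
             roi_counts = character(0), p_value = numeric(0),
             significant = logical(0))
}

# shared engine of the per-window spatial cluster MCS family: for each tone
# window, group one-sample t across subjects, binarize at voxel_alpha, split
# by direction, spatial cluster MCS at alpha_adj
.window_family_mcs <- function(wm, grid, voxel_alpha, alpha_adj, n_perm,
                               seed, connectivity,
                               dir_labels = c("A>B", "B>A")) {
  seeds <- spawn_seeds(seed, 10)
  out <- list()
  for (w in 1:5) {
    X <- t(vapply(wm, function(m) m[, w], numeric(nrow(grid))))
    mt <- .mass_t(X)
    sig <- !is.na(mt$p) & mt$p < voxel_alpha
    for (dir_i in 1:2) {
      ones <- sig & (if (dir_i == 1) mt$t > 0 else mt$t < 0)
      bm <- .grid_binary_map(ones, grid, dir_labels[dir_i])
      cl <- find_clusters(bm, connectivity)
      if (length(cl) == 0) next
      null <- max_cluster_null(bm, n_perm, connectivity,
                               seeds[(w - 1) * 2 + dir_i])
      cl <- mcs_significance(cl, null, alpha_adj)
      out[[length(out) + 1]] <- do.call(rbind, lapply(seq_along(cl),
        function(i) {
          rv <- .roi_vote(cl[[i]]$cells, grid)
          data.frame(window = w, direction = dir_labels[dir_i],
                     cluster_number = i, k = cl[[i]]$size,
                     roi_majority = rv$majority, roi_fraction = rv$fraction,
                     roi_counts = rv$counts, p_value = cl[[i]]$p,
                     significant = cl[[i]]$significant,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_window_table()
  attr(res, "alpha_adjusted") <- alpha_adj
  res
}

#' Per-tone-window spatial cluster MCS on a group contrast
#'
#' For each of the five tone windows, the subject contrasts are sub-averaged
#' within the window, a group one-sample t-test is run per dipole, the map
#' is binarized at `voxel_alpha` (split by direction), and a 3D spatial
#' cluster MCS is run at the Bonferroni-adjusted cluster alpha
#' `base_alpha / (5 * band_count)` (0.01 / 10 = 0.001 for five tones and two
#' frequency bands).
#'
#' @param contrasts list (per subject) of dipoles x samples contrasts, or of
#'   dipoles x 5 pre-computed window means (then pass `times = NULL`).
#' @param grid the `source_grid`.
#' @param times time axis of the contrast samples (s), covering 0-1250 ms;
#'   `NULL` when the contrasts are already window means.
#' @param band_count number of bands in the analysis family (default 2).
#' @param base_alpha family-wise cluster alpha before adjustment (0.01).
#' @param voxel_alpha per-dipole binarization threshold (0.05).
#' @param n_perm permutations per MCS.
#' @param seed RNG seed.
#' @param connectivity cluster connectivity.
#' @return data frame of clusters: window, direction, size k, majority ROI
#'   label and fraction, p-value, significance.
#' @export
tone_window_mcs <- function(contrasts, grid, times, band_count = 2L,
                            base_alpha = 0.01, voxel_alpha = 0.05,
                            n_perm = 1000L, seed = 1L,
                            connectivity = "orthogonal") {
  alpha_adj <- base_alpha / (5 * band_count)
  if (is.null(times)) {
    .assert(ncol(contrasts[[1]]) == 5,
            "window-mean contrasts must have 5 columns", "window_coverage")
    wm <- contrasts
  } else {
    .assert(max(times) >= 1.25 - 1 / 150 - 1e-9,
            "contrast must cover the 0-1250 ms excerpt", "window_coverage")
    wm <- lapply(contrasts, window_means, times = times)
  }
  .window_family_mcs(wm, grid, voxel_alpha, alpha_adj, n_perm, seed,
                     connectivity)
}

#' Tonal-vs-atonal contrast of memorized-sequence source activity
#'
#' Group-level paired comparison of the memorized-condition window means of
#' the two pieces (per-subject tonal-minus-atonal differences of
#' sign-aligned condition means), binarized at `voxel_alpha` and submitted
#' to the ten-window-family cluster MCS.
#'
#' @param src_tonal,src_atonal per-subject lists of `source_estimate`s for
#'   the memorized condition of each piece (same band).
#' @param grid,times,band_count,n_perm,seed,connectivity as in
#'   [tone_window_mcs()].
#' @param voxel_alpha per-dipole alpha (default 0.01 for this contrast).
#' @return cluster table as in [tone_window_mcs()]; direction `"A>B"` means
#'   tonal > atonal.
#' @export
memorized_piece_contrast <- function(src_tonal, src_atonal, grid, times,
                                     voxel_alpha = 0.01, band_count = 2L,
                                     n_perm = 1000L, seed = 1L,
                                     connectivity = "orthogonal") {
  .assert(length(src_tonal) == length(src_atonal),
          "need both pieces for every subject", "missing_condition")
  contrasts <- lapply(seq_along(src_tonal), function(i) {
    first_level(src_tonal[[i]], src_atonal[[i]])
  })
  tone_window_mcs(contrasts, grid, times, band_count = band_count,
                  voxel_alpha = voxel_alpha, n_perm = n_perm, seed = seed,
                  connectivity = connectivity)
}

#' Slow-vs-fast band contrast of source window means
#'
#' Window means are z-scored within each band per subject (removing the
#' trivial overall amplitude difference between frequency bands) before the
#' paired group comparison and window-family cluster MCS, so the result is
#' invariant to a global gain applied to either band.
#'
#' @param wm_slow,wm_fast per-subject lists of dipoles x 5 window-mean
#'   matrices for the two bands.
#' @param grid the `source_grid`.
#' @param voxel_alpha,band_count,n_perm,seed,connectivity as elsewhere.
#' @return cluster table; direction `"A>B"` means slow > fast.
#' @export
band_contrast <- function(wm_slow, wm_fast, grid, voxel_alpha = 0.05,
                          band_count = 2L, n_perm = 1000L, seed = 1L,
                          connectivity = "orthogonal") {
  .assert(length(wm_slow) == length(wm_fast),
          "need both bands for every subject", "missing_condition")
  zs <- function(m) {
    v <- as.numeric(m)
    if (sd(v) == 0) return(m * 0)
    (m - mean(v)) / sd(v)
  }
  contrasts <- lapply(seq_along(wm_slow), function(i) {
    zs(abs(wm_slow[[i]])) - zs(abs(wm_fast[[i]]))
  })
  .window_family_mcs(contrasts, grid, voxel_alpha,
                     alpha_adj = 0.01 / (5 * band_count), n_perm, seed,
                     connectivity)
}

#' Correlation between familiarity ratings and source window means
#'
#' Pearson correlation across subjects between the 1-7 familiarity rating
#' and each dipole's window-mean activity, per tone window; r-maps are
#' binarized at `alpha` by the sign of r and submitted to a spatial cluster
#' MCS with the 95% maximum-cluster rule (cluster alpha = `alpha`).
#'
#' @param familiarity integer vector of per-subject ratings (1-7), >= 3
#'   subjects.
#' @param wm per-subject list of dipoles x 5 window-mean matrices.
#' @param grid the `source_grid`.
#' @param alpha per-dipole and cluster-level alpha (default 0.05).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param connectivity cluster connectivity.
#' @return list with `r` (dipoles x 5), `p`, and a cluster table.
#' @export
familiarity_correlation <- function(familiarity, wm, grid, alpha = 0.05,
                                    n_perm = 1000L, seed = 1L,
                                    connectivity = "orthogonal") {
  n <- length(familiarity)
  .assert(n >= 3 && n == length(wm), "need >= 3 subjects with ratings",
          "too_few_subjects")
  .assert(all(familiarity >= 1 & familiarity <= 7),
          "ratings must be on the 1-7 scale", "invalid_ratings")
  if (sd(familiarity) == 0)
    .err("familiarity ratings have zero variance", "degenerate_ratings")
  n_dip <- nrow(grid)
  rmat <- matrix(NA_real_, n_dip, 5)
  for (w in 1:5) {
    X <- vapply(wm, function(m) m[, w], numeric(n_dip))  # dipoles x subjects
    Xc <- X - rowMeans(X)
    fc <- familiarity - mean(familiarity)
    denom <- sqrt(rowSums(Xc^2) * sum(fc^2))
    r <- as.numeric(Xc %*% fc) / ifelse(denom == 0, NA_real_, denom)
    rmat[, w] <- r
  }
  tstat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, 1e-12))
  pmat <- 2 * pt(-abs(tstat), df = n - 2)
  seeds <- spawn_seeds(seed, 10)
  out <- list()
  for (w in 1:5) {
    sig <- !is.na(pmat[, w]) & pmat[, w] < alpha
    for (dir_i in 1:2) {
      dir_lab <- c("r>0", "r<0")[dir_i]
      ones <- sig & (if (dir_i == 1) rmat[, w] > 0 else rmat[, w] < 0)
      bm <- .grid_binary_map(ones, grid, dir_lab)
      cl <- find_clusters(bm, connectivity)
      if (length(cl)) {
        null <- max_cluster_null(bm, n_perm, connectivity,
                                 seeds[(w - 1) * 2 + dir_i])
        cl <- mcs_significance(cl, null, alpha)
        rows <- do.call(rbind, lapply(seq_along(cl), function(i) {
          rv <- .roi_vote(cl[[i]]$cells, grid)
          data.frame(window = w, direction = dir_lab, cluster_number = i,
                     k = cl[[i]]$size, roi_majority = rv$majority,
                     roi_fraction = rv$fraction, roi_counts = rv$counts,
                     p_value = cl[[i]]$p,
                     significant = cl[[i]]$significant,
                     stringsAsFactors = FALSE)
        }))
        out[[length(out) + 1]] <- rows
      }
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else .empty_window_table()
  list(r = rmat, p = pmat, clusters = tab)
}
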