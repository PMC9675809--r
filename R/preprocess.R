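#' Zero-phase band-pass filter a recording
#'
#' Forward-backward (zero-phase) Butterworth filtering, realized as a cascade
#' of an order-4 high-pass at `low` and an order-4 low-pass at `high`, each
#' applied with `filtfilt`. The cascade is used because a direct
#' transfer-function band-pass is numerically unstable at the very low
#' normalized edge frequencies this analysis needs (0.1 Hz at 150 Hz
#' sampling). Edge effects are handled by odd-reflection padding of at least
#' three filter time constants. `low = 0` gives a pure low-pass.
#'
#' @param rec a `recording` (or any list with `data` channels x samples and
#'   `fs`).
#' @param low high-pass edge (Hz), `>= 0`.
#' @param high low-pass edge (Hz), `< fs/2`.
#' @param order Butterworth order per pass.
#' @return the recording with filtered data and a `band` attribute.
#' @export
bandpass <- function(rec, low, high, order = 4L) {
  fs <- rec$fs
  .assert(low >= 0 && low < high, "need 0 <= low < high", "invalid_band")
  if (high >= fs / 2) .err("high edge must be below the Nyquist frequency",
                           "invalid_band")
  x <- rec$data
  n <- ncol(x)
  # pad by 3 time constants of the slowest edge
  f_slow <- if (low > 0) low else high
  pad <- min(n - 1L, ceiling(3 * fs / (2 * pi * f_slow)))
  hp <- if (low > 0) signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  filt_row <- function(v) {
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
            2 * v[n] - rev(v[(n - pad):(n - 1)]))
    if (low > 0) vp <- signal::filtfilt(hp, vp)
    vp <- signal::filtfilt(lp, vp)
    vp[(pad + 1):(pad + n)]
  }
  out <- t(apply(x, 1, filt_row))
  dimnames(out) <- dimnames(x)
  rec$data <- out
  rec$band <- c(low, high)
  rec
}

#' Epoch a recording around its event onsets
#'
#' Cuts one epoch per event from `tmin` to `tmax` relative to onset
#' (sample-count convention `floor((tmax - tmin) * fs) + 1`, onset sample
#' included at t = 0) and baseline-corrects each trial by subtracting the
#' per-channel mean of the pre-onset window. Events too close to the
#' recording edge are dropped with a warning.
#'
#' @param rec a `recording`.
#' @param tmin epoch start relative to onset (s), default -0.1.
#' @param tmax epoch end relative to onset (s), default 1.25.
#' @param baseline logical; subtract the pre-onset mean per channel/trial.
#' @return an `epoch_set`: `data` (trials x channels x samples), `times`,
#'   `fs`, `events` (surviving rows).
#' @export
epoch <- function(rec, tmin = -0.1, tmax = 1.25, baseline = TRUE) {
  fs <- rec$fs
  .assert(tmin < tmax, "tmin must be below tmax", "invalid_epoch")
  n_min <- round(tmin * fs)
  n_samp <- floor((tmax - tmin) * fs) + 1L
  offs <- n_min + 0:(n_samp - 1L)
  times <- offs / fs
  n_total <- ncol(rec$data)
  first <- rec$events$sample + offs[1]
  last <- rec$events$sample + offs[n_samp]
  keep <- first >= 1 & last <= n_total
  if (any(!keep))
    warning(sprintf("%d event(s) too close to the recording edge were dropped",
                    sum(!keep)))
  ev <- rec$events[keep, , drop = FALSE]
  n_tr <- nrow(ev)
  .assert(n_tr > 0, "no events fit within the recording", "invalid_epoch")
  n_ch <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(n_tr, n_ch, n_samp),
               dimnames = list(NULL, rownames(rec$data), NULL))
  bl <- times < 0
  for (k in seq_len(n_tr)) {
    seg <- rec$data[, ev$sample[k] + offs, drop = FALSE]
    if (baseline && any(bl))
      seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    arr[k, , ] <- seg
  }
  structure(list(data = arr, fs = fs, times = times, events = ev,
                 band = rec$band %||% "broadband"),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d trials x %d channels x %d samples (%.0f to %.0f ms)>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times) * 1000, max(x$times) * 1000))
  invisible(x)
}

#' Keep correctly answered trials only
#'
#' @param ep an `epoch_set` whose events carry `is_correct`.
#' @return the subset `epoch_set`, original trial order preserved. Errors
#'   (naming the condition) if a condition present in the input retains no
#'   correct trial.
#' @export
select_correct <- function(ep) {
  keep <- ep$events$is_correct
  for (cc in unique(ep$events$condition)) {
    if (!any(keep & ep$events$condition == cc))
      .err(sprintf("no correct trials left in condition '%s'", cc),
           "no_correct_trials")
  }
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$events <- ep$events[keep, , drop = FALSE]
  ep
}

#' Average the trials of one condition
#'
#' @param ep an `epoch_set`.
#' @param condition condition label to average.
#' @return an `evoked`: `data` (channels x samples), `times`, `fs`,
#'   `n_trials`, `condition`.
#' @export
average_condition <- function(ep, condition) {
  sel <- ep$events$condition == condition
  if (!any(sel)) .err(sprintf("unknown or empty condition '%s'", condition),
                      "unknown_condition")
  m <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = m, times = ep$times, fs = ep$fs,
                 n_trials = sum(sel), condition = condition,
                 band = ep$band %||% "broadband"),
            class = "evoked")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked: '%s', %d channels x %d samples, %d trials averaged>\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Combine planar-gradiometer pairs by root-sum-square
#'
#' Each gradiometer pair (the two orthogonal planar gradiometers sharing one
#' site) is combined sample-wise as `sqrt(g1^2 + g2^2)`; magnetometers are
#' dropped. The output has one non-negative channel per site and carries the
#' site layout used by the sensor-space cluster statistics.
#'
#' @param ev an `evoked` whose channels match `sensors`.
#' @param sensors the `sensor_array` the evoked was recorded with.
#' @return an `evoked` with one combined channel per gradiometer pair and a
#'   `layout` attribute (data frame: site, layout_row, layout_col).
#' @export
combine_planar <- function(ev, sensors) {
  gr <- sensors[sensors$type == "planar_gradiometer", ]
  pairs <- split(gr$channel, gr$pair_id)
  bad <- names(pairs)[vapply(pairs, length, integer(1)) != 2]
  if (length(bad))
    .err(sprintf("unpaired gradiometer(s) at pair_id %s",
                 paste(bad, collapse = ", ")), "unpaired_gradiometer")
  missing <- setdiff(gr$channel, rownames(ev$data))
  if (length(missing))
    .err(sprintf("evoked lacks gradiometer channel(s): %s",
                 paste(utils::head(missing, 4), collapse = ", ")),
         "unpaired_gradiometer")
  ids <- as.integer(names(pairs))
  comb <- t(vapply(seq_along(pairs), function(i) {
    g <- ev$data[pairs[[i]], , drop = FALSE]
    sqrt(g[1, ]^2 + g[2, ]^2)
  }, numeric(ncol(ev$data))))
  rownames(comb) <- sprintf("S%03d_C", ids)
  lay <- unique(gr[, c("pair_id", "layout_row", "layout_col")])
  lay <- lay[match(ids, lay$pair_id), ]
  names(lay)[1] <- "site"
  out <- ev
  out$data <- comb
  attr(out, "layout") <- lay
  attr(out, "layout_dim") <- attr(sensors, "layout_dim")
  attr(out, "combined") <- TRUE
  out
}
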