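#' Synthetic MEG sensor array on a spherical shell
#'
#' Places `n_positions` sensor sites quasi-uniformly on the upper hemisphere
#' of a shell outside the head sphere (Fibonacci spiral). Each site carries a
#' magnetometer (sensing the radial field component) and a pair of planar
#' gradiometers (finite differences of the radial component along two
#' orthogonal tangential directions). A 2D layout coordinate is assigned per
#' site by azimuthal-equidistant projection snapped to the smallest regular
#' grid holding one site per cell; the layout is what the sensor-space
#' cluster statistics operate on.
#'
#' @param n_positions number of sensor sites (default 102, i.e. 306 channels).
#' @param head_radius radius of the conducting head sphere (m).
#' @param sensor_shell_radius radius of the sensor shell (m); must exceed
#'   `head_radius`.
#' @param grad_baseline planar-gradiometer finite-difference baseline (m).
#' @return a `sensor_array`: data frame of channels (name, site, type,
#'   position, orientation, layout cell) with geometry attributes.
#' @export
make_sensor_array <- function(n_positions = 102L, head_radius = 0.09,
                              sensor_shell_radius = 0.102,
                              grad_baseline = 0.017) {
  .assert(n_positions >= 4, "need at least 4 sensor positions",
          "invalid_geometry")
  .assert(sensor_shell_radius > head_radius && head_radius > 0,
          "sensor shell must lie strictly outside the head sphere",
          "invalid_geometry")
  n <- as.integer(n_positions)
  i <- seq_len(n) - 0.5
  z <- i / n                              # upper hemisphere: z in (0, 1)
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  rho <- sqrt(1 - z^2)
  P <- cbind(rho * cos(phi), rho * sin(phi), z) * sensor_shell_radius

  # orthonormal tangent frame at each site (radial = site direction)
  rad <- P / sensor_shell_radius
  t1 <- cbind(-rad[, 2], rad[, 1], 0)
  nt1 <- sqrt(rowSums(t1^2))
  pole <- nt1 < 1e-9
  if (any(pole)) t1[pole, ] <- matrix(c(1, 0, 0), sum(pole), 3, byrow = TRUE)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(rad[, 2] * t1[, 3] - rad[, 3] * t1[, 2],
              rad[, 3] * t1[, 1] - rad[, 1] * t1[, 3],
              rad[, 1] * t1[, 2] - rad[, 2] * t1[, 1])

  # azimuthal-equidistant projection, snapped to the smallest collision-free grid
  theta <- acos(pmin(1, z))
  az <- atan2(P[, 2], P[, 1])
  u <- theta * cos(az)
  v <- theta * sin(az)
  m <- ceiling(sqrt(n))
  repeat {
    eps <- 1e-9
    row <- findInterval(v, seq(min(v) - eps, max(v) + eps, length.out = m + 1),
                        rightmost.closed = TRUE)
    col <- findInterval(u, seq(min(u) - eps, max(u) + eps, length.out = m + 1),
                        rightmost.closed = TRUE)
    if (!anyDuplicated(cbind(row, col))) break
    m <- m + 1L
    .assert(m <= 20L * n, "could not find a collision-free layout grid",
            "invalid_geometry")
  }

  site <- seq_len(n)
  ch <- data.frame(
    channel = c(sprintf("S%03d_G1", site), sprintf("S%03d_G2", site),
                sprintf("S%03d_M", site)),
    site = rep(site, 3),
    type = rep(c("planar_gradiometer", "planar_gradiometer", "magnetometer"),
               each = n),
    x = rep(P[, 1], 3), y = rep(P[, 2], 3), z = rep(P[, 3], 3),
    ox = c(t1[, 1], t2[, 1], rad[, 1]),
    oy = c(t1[, 2], t2[, 2], rad[, 2]),
    oz = c(t1[, 3], t2[, 3], rad[, 3]),
    layout_row = rep(row, 3), layout_col = rep(col, 3),
    stringsAsFactors = FALSE
  )
  ch$pair_id <- ifelse(ch$type == "planar_gradiometer", ch$site, NA_integer_)
  ch <- ch[order(ch$site, ch$type != "planar_gradiometer", ch$channel), ]
  rownames(ch) <- NULL
  structure(ch,
            head_radius = head_radius,
            sensor_shell_radius = sensor_shell_radius,
            grad_baseline = grad_baseline,
            n_positions = n,
            layout_dim = c(m, m),
            class = c("sensor_array", "data.frame"))
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array: %d sites, %d channels (%d gradiometers + %d magnetometers)>\n",
              attr(x, "n_positions"), nrow(x),
              sum(x$type == "planar_gradiometer"),
              sum(x$type == "magnetometer")))
  invisible(x)
}

#' Regular dipole grid inside a spherical head
#'
#' Cubic lattice of candidate source dipoles with uniform spacing, restricted
#' to the interior of the head sphere, with an optional region-of-interest
#' labelling by named spherical patches (first-listed patch wins on overlap).
#'
#' @param spacing grid spacing (m), e.g. 0.008 for an 8-mm grid.
#' @param radius head sphere radius (m).
#' @param roi_spec named list of patches, each `list(center = c(x, y, z),
#'   radius = r)` in meters; see [default_roi_spec()].
#' @return a `source_grid`: data frame of dipoles (position, lattice indices,
#'   ROI label).
#' @export
make_source_grid <- function(spacing = 0.008, radius = 0.08,
                             roi_spec = NULL) {
  .assert(spacing > 0, "spacing must be positive", "invalid_geometry")
  .assert(radius > 0, "radius must be positive", "invalid_geometry")
  k <- floor(radius / spacing)
  ax <- (-k:k) * spacing
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- sqrt(g$x^2 + g$y^2 + g$z^2) < radius
  g <- g[inside, , drop = FALSE]
  g$ix <- as.integer(round(g$x / spacing)) + k + 1L
  g$iy <- as.integer(round(g$y / spacing)) + k + 1L
  g$iz <- as.integer(round(g$z / spacing)) + k + 1L
  g$roi <- "none"
  if (!is.null(roi_spec)) {
    .assert(!is.null(names(roi_spec)) && all(nzchar(names(roi_spec))),
            "roi_spec must be a named list", "invalid_geometry")
    assigned <- rep(FALSE, nrow(g))
    for (nm in names(roi_spec)) {
      patch <- roi_spec[[nm]]
      d <- sqrt((g$x - patch$center[1])^2 + (g$y - patch$center[2])^2 +
                  (g$z - patch$center[3])^2)
      hit <- d <= patch$radius
      if (any(hit & assigned))
        warning(sprintf("ROI patch '%s' overlaps an earlier patch; first-listed wins",
                        nm))
      take <- hit & !assigned
      g$roi[take] <- nm
      assigned <- assigned | hit
    }
  }
  rownames(g) <- NULL
  structure(g, spacing = spacing, radius = radius,
            lattice_dim = rep(2L * k + 1L, 3),
            class = c("source_grid", "data.frame"))
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid: %d dipoles, %.0f-mm spacing, radius %.0f mm>\n",
              nrow(x), attr(x, "spacing") * 1000, attr(x, "radius") * 1000))
  invisible(x)
}

#' Default region-of-interest patches
#'
#' Named spherical patches standing in for anatomical labels on the
#' synthetic spherical head: bilateral auditory regions, bilateral
#' hippocampus, and a midline cingulate patch. Centers/radii in meters.
#'
#' @return named list usable as `roi_spec` in [make_source_grid()].
#' @export
default_roi_spec <- function() {
  # patch sizes are generous: each stands for a multi-area territory (the
  # auditory patches for the lateral peri-sylvian auditory network, the
  # medial patches for the deep hippocampal-parahippocampal-cingulate
  # memory network), and the medial patches tile a contiguous central block
  list(
    auditory_L    = list(center = c(-0.044, -0.008, 0.002), radius = 0.024),
    auditory_R    = list(center = c(0.044, -0.008, 0.002), radius = 0.024),
    hippocampus_L = list(center = c(-0.016, -0.020, -0.010), radius = 0.018),
    hippocampus_R = list(center = c(0.016, -0.020, -0.010), radius = 0.018),
    cingulate     = list(center = c(0, 0.004, 0.026), radius = 0.028)
  )
}
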