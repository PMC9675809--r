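# Analytic magnetic field of a current dipole in a homogeneous conducting
# sphere centered at the origin (classic closed-form solution).  The external
# field depends only on sphere center, dipole position/moment, and field
# point; radial dipole components are externally silent.
#
# rq: dipole position (length-3, m); q: dipole moment (length-3, A*m);
# RS: n x 3 matrix of field points (m, strictly outside the sphere).
# Returns n x 3 matrix of B (Tesla).
.dipole_field <- function(rq, q, RS) {
  mu0_4pi <- 1e-7
  A <- sweep(RS, 2, rq)                       # a = r - r0
  a <- sqrt(rowSums(A^2))
  r <- sqrt(rowSums(RS^2))
  r0_dot_r <- drop(RS %*% rq)
  a_dot_r <- rowSums(A * RS)
  F <- a * (r * a + r^2 - r0_dot_r)
  c1 <- a^2 / r + a_dot_r / a + 2 * a + 2 * r
  c2 <- a + 2 * r + a_dot_r / a
  gradF <- RS * c1 - matrix(rq, nrow(RS), 3, byrow = TRUE) * c2
  qxr0 <- c(q[2] * rq[3] - q[3] * rq[2],
            q[3] * rq[1] - q[1] * rq[3],
            q[1] * rq[2] - q[2] * rq[1])
  qxr0_dot_r <- drop(RS %*% qxr0)
  B <- (matrix(qxr0, nrow(RS), 3, byrow = TRUE) * F - gradF * qxr0_dot_r) *
    (mu0_4pi / F^2)
  B
}

# tangential unit vectors at a dipole position (w.r.t. sphere center)
.tangent_frame <- function(p) {
  r <- sqrt(sum(p^2))
  if (r < 1e-12) return(NULL)               # center dipole: no tangent plane
  rad <- p / r
  t1 <- c(-rad[2], rad[1], 0)
  if (sqrt(sum(t1^2)) < 1e-9) t1 <- c(1, 0, 0)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
          rad[3] * t1[1] - rad[1] * t1[3],
          rad[1] * t1[2] - rad[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Lead field of a dipole grid for a sensor array
#'
#' Linear forward operator mapping the two tangential moment components of
#' every grid dipole (A.m) to sensor readings: the analytic external field of
#' a current dipole in a homogeneous conducting sphere, projected on the
#' magnetometer orientation (T), and planar finite differences of the radial
#' field component over the gradiometer baseline (T/m). Radial moments are
#' externally silent in a sphere, so only the two tangential orientations are
#' represented. A dipole at the sphere center has an all-zero column pair
#' (documented degeneracy, not an error).
#'
#' @param grid a `source_grid`.
#' @param sensors a `sensor_array`.
#' @return a `lead_field`: array of dim `(n_channels, n_dipoles, 2)` with the
#'   grid, sensors and per-dipole tangent frames attached.
#' @export
compute_lead_field <- function(grid, sensors) {
  stopifnot(inherits(grid, "source_grid"), inherits(sensors, "sensor_array"))
  head_r <- attr(sensors, "head_radius")
  rs <- sqrt(sensors$x^2 + sensors$y^2 + sensors$z^2)
  .assert(all(rs > head_r - 1e-12), "all sensors must lie outside the head sphere",
          "invalid_geometry")
  rq_all <- as.matrix(grid[, c("x", "y", "z")])
  .assert(all(sqrt(rowSums(rq_all^2)) < head_r + 1e-12),
          "all dipoles must lie inside the head sphere", "invalid_geometry")

  b <- attr(sensors, "grad_baseline")
  is_grad <- sensors$type == "planar_gradiometer"
  site <- sensors$site
  pos <- as.matrix(sensors[, c("x", "y", "z")])
  orient <- as.matrix(sensors[, c("ox", "oy", "oz")])
  # radial sensing direction at each channel's site
  rad_dir <- pos / sqrt(rowSums(pos^2))

  # evaluation points: channel position, plus +-b/2 offsets for gradiometers
  eval_pts <- pos
  plus <- pos + (b / 2) * orient
  minus <- pos - (b / 2) * orient
  n_ch <- nrow(sensors)
  n_dip <- nrow(grid)
  L <- array(0, dim = c(n_ch, n_dip, 2),
             dimnames = list(sensors$channel, NULL, c("t1", "t2")))
  frames <- vector("list", n_dip)
  gi <- which(is_grad)
  mi <- which(!is_grad)
  for (d in seq_len(n_dip)) {
    fr <- .tangent_frame(rq_all[d, ])
    frames[[d]] <- fr
    if (is.null(fr)) next                   # center dipole: zero columns
    for (o in 1:2) {
      q <- if (o == 1) fr$t1 else fr$t2
      if (length(mi)) {
        Bm <- .dipole_field(rq_all[d, ], q, eval_pts[mi, , drop = FALSE])
        L[mi, d, o] <- rowSums(Bm * orient[mi, , drop = FALSE])
      }
      if (length(gi)) {
        Bp <- .dipole_field(rq_all[d, ], q, plus[gi, , drop = FALSE])
        Bn <- .dipole_field(rq_all[d, ], q, minus[gi, , drop = FALSE])
        L[gi, d, o] <- rowSums((Bp - Bn) * rad_dir[gi, , drop = FALSE]) / b
      }
    }
  }
  structure(L, grid = grid, sensors = sensors, frames = frames,
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field: %d channels x %d dipoles x 2 tangential orientations>\n",
              dim(x)[1], dim(x)[2]))
  invisible(x)
}

#' Sensor projection of dipole activity
#'
#' Applies the lead field: `channels x samples` readings produced by a set of
#' dipoles with fixed tangential moment directions and common time courses.
#'
#' @param lf a `lead_field`.
#' @param dipoles integer indices into the grid.
#' @param moments matrix `length(dipoles) x 2` of tangential moment
#'   coefficients (A.m) per dipole.
#' @param timecourse numeric vector (unitless modulation) or matrix
#'   `length(dipoles) x n_samples`.
#' @return matrix `n_channels x n_samples`.
#' @export
project_sources <- function(lf, dipoles, moments, timecourse) {
  if (is.vector(timecourse))
    timecourse <- matrix(timecourse, length(dipoles), length(timecourse),
                         byrow = TRUE)
  .assert(nrow(moments) == length(dipoles) && nrow(timecourse) == length(dipoles),
          "moments/timecourse rows must match dipoles", "invalid_projection")
  out <- 0
  for (j in seq_along(dipoles)) {
    l <- lf[, dipoles[j], 1] * moments[j, 1] + lf[, dipoles[j], 2] * moments[j, 2]
    out <- out + outer(l, timecourse[j, ])
  }
  out
}
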