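#' Pointwise paired t-tests on combined-gradiometer evoked data
#'
#' Two-sided paired t-tests across subjects at every (channel, sample) cell,
#' contrasting two conditions (e.g. memorized vs novel), binarized at
#' `alpha` and split into two direction maps by the sign of t.
#'
#' @param evoked_a,evoked_b lists of combined-planar `evoked` objects, one
#'   per subject, aligned subject-wise, >= 2 subjects.
#' @param alpha per-cell significance threshold (default 0.01).
#' @return a `sensor_stat_map`: `t`, `p` (channels x samples), `df`,
#'   `map_pos`/`map_neg` (`binary_map`s tagged `"A>B"`/`"B>A"`), plus layout
#'   and times carried over from the evokeds.
#' @export
pointwise_paired_t <- function(evoked_a, evoked_b, alpha = 0.01) {
  .assert(length(evoked_a) == length(evoked_b),
          "condition lists must contain the same subjects", "subject_mismatch")
  n <- length(evoked_a)
  .assert(n >= 2, "need at least 2 subjects", "too_few_subjects")
  dims <- dim(evoked_a[[1]]$data)
  for (i in seq_len(n)) {
    .assert(identical(dim(evoked_a[[i]]$data), dims) &&
              identical(dim(evoked_b[[i]]$data), dims),
            "all evoked arrays must share dimensions", "subject_mismatch")
  }
  if (n == 2) message("two-subject paired t-test: df = 1, low power")
  D <- t(vapply(seq_len(n),
                function(i) as.numeric(evoked_a[[i]]$data - evoked_b[[i]]$data),
                numeric(prod(dims))))
  mt <- .mass_t(D)
  tmat <- matrix(mt$t, dims[1], dims[2], dimnames = dimnames(evoked_a[[1]]$data))
  pmat <- matrix(mt$p, dims[1], dims[2])
  sig <- !is.na(pmat) & pmat < alpha
  structure(list(t = tmat, p = pmat, df = mt$df, alpha = alpha,
                 map_pos = binary_map((sig & tmat > 0) * 1L, direction = "A>B"),
                 map_neg = binary_map((sig & tmat < 0) * 1L, direction = "B>A"),
                 layout = attr(evoked_a[[1]], "layout"),
                 layout_dim = attr(evoked_a[[1]], "layout_dim"),
                 times = evoked_a[[1]]$times),
            class = "sensor_stat_map")
}

#' Embed a channels-by-time binary map into the 2D sensor layout
#'
#' For each timepoint the channel values are placed on the 2D grid cell of
#' their sensor site, giving a 3D (rows x cols x samples) space-time map
#' whose validity mask marks occupied layout cells. The cell-to-site mapping
#' is a bijection (layout collisions are an error), so the embedding is
#' lossless.
#'
#' @param bmap a `binary_map` of dimension channels x samples (rows ordered
#'   as `layout`).
#' @param layout data frame with `site`, `layout_row`, `layout_col` (one row
#'   per combined channel), as attached by [combine_planar()].
#' @param layout_dim integer c(rows, cols) of the layout grid.
#' @return a 3D `binary_map` with a `layout` attribute.
#' @export
embed_layout <- function(bmap, layout, layout_dim) {
  n_ch <- nrow(layout)
  .assert(dim(bmap$arr)[1] == n_ch,
          "map rows must match the layout channels", "layout_mismatch")
  if (anyDuplicated(layout[, c("layout_row", "layout_col")]))
    .err("layout collision: two channels share a cell", "layout_collision")
  n_t <- dim(bmap$arr)[2]
  arr <- array(0L, c(layout_dim[1], layout_dim[2], n_t))
  valid <- array(FALSE, c(layout_dim[1], layout_dim[2], n_t))
  for (i in seq_len(n_ch)) {
    arr[layout$layout_row[i], layout$layout_col[i], ] <- bmap$arr[i, ]
    valid[layout$layout_row[i], layout$layout_col[i], ] <- TRUE
  }
  out <- binary_map(arr, valid, direction = bmap$direction)
  attr(out, "layout") <- layout
  out
}

#' Cluster-based Monte-Carlo significance on a sensor space-time map
#'
#' Runs the cluster permutation engine on an embedded space-time binary map
#' and reports per-cluster size, number of distinct channels, covered time
#' interval (s) and permutation p-value.
#'
#' @param stmap a 3D `binary_map` from [embed_layout()].
#' @param times time axis (s) of the map's last dimension.
#' @param n_perm permutations (default 1000).
#' @param alpha cluster-level threshold (default 0.001).
#' @param seed RNG seed.
#' @param connectivity as in [find_clusters()].
#' @return data frame (one row per cluster) with the observed clusters as a
#'   `"clusters"` attribute.
#' @export
run_sensor_mcs <- function(stmap, times, n_perm = 1000L, alpha = 0.001,
                           seed = 1L, connectivity = "orthogonal") {
  cl <- find_clusters(stmap, connectivity)
  if (length(cl) == 0)
    return(.cluster_table(cl, stmap$direction %||% NA_character_, times))
  null <- max_cluster_null(stmap, n_perm, connectivity, seed)
  cl <- mcs_significance(cl, null, alpha)
  tab <- .cluster_table(cl, stmap$direction %||% NA_character_, times,
                        spatial_axes = 1:2)
  attr(tab, "clusters") <- cl
  attr(tab, "null") <- null
  tab
}

#' Sensor-level memorized-vs-novel analysis for one piece
#'
#' Full sensor-space chain: paired t-maps over subjects on combined
#' gradiometers, embedding into the 2D layout, and cluster MCS per
#' direction.
#'
#' @param evoked_mem,evoked_nov per-subject combined `evoked` lists.
#' @param t_alpha per-cell alpha for the t-tests (default 0.01).
#' @param cluster_alpha cluster-level alpha (default 0.001).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param connectivity cluster connectivity.
#' @return list with the `sensor_stat_map` and a combined cluster table
#'   (both directions).
#' @export
sensor_analysis <- function(evoked_mem, evoked_nov, t_alpha = 0.01,
                            cluster_alpha = 0.001, n_perm = 1000L,
                            seed = 1L, connectivity = "orthogonal") {
  sm <- pointwise_paired_t(evoked_mem, evoked_nov, alpha = t_alpha)
  seeds <- spawn_seeds(seed, 2)
  tabs <- lapply(1:2, function(i) {
    bm <- if (i == 1) sm$map_pos else sm$map_neg
    st <- embed_layout(bm, sm$layout, sm$layout_dim)
    run_sensor_mcs(st, sm$times, n_perm, cluster_alpha, seeds[i],
                   connectivity)
  })
  list(stat_map = sm, clusters = rbind(tabs[[1]], tabs[[2]]))
}
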