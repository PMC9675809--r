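#' Binarized significance map
#'
#' An n-dimensional 0/1 array with a validity mask marking the cells that
#' exist (layout cells holding a channel, voxels inside the head). Ones are
#' only allowed on valid cells. This is the object the cluster-based
#' Monte-Carlo significance machinery operates on.
#'
#' @param arr numeric/logical array of 0s and 1s.
#' @param valid logical array of the same dimension (default: all valid).
#' @param direction optional tag, e.g. `"A>B"` or `"B>A"`.
#' @return an object of class `binary_map`.
#' @export
binary_map <- function(arr, valid = NULL, direction = NULL) {
  arr <- (arr != 0) * 1L
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  if (is.null(valid)) valid <- array(TRUE, dim(arr))
  .assert(identical(dim(valid), dim(arr)),
          "valid mask must have the same dimensions as the map",
          "invalid_map_dims")
  .assert(all(arr[!valid] == 0), "ones are only allowed on valid cells",
          "ones_outside_mask")
  structure(list(arr = arr, valid = valid, direction = direction),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map: %s, %d/%d valid cells set%s>\n",
              paste(dim(x$arr), collapse = "x"), sum(x$arr), sum(x$valid),
              if (is.null(x$direction)) "" else paste0(", ", x$direction)))
  invisible(x)
}

# connected-component labelling of a set of cells on an n-D lattice.
# lin: 1-based linear indices of the ones; dims: lattice dimensions.
# Returns integer cluster id per entry of lin.
.label_components <- function(lin, dims, connectivity = "orthogonal") {
  n1 <- length(lin)
  if (n1 == 0) return(integer(0))
  nd <- length(dims)
  coords <- arrayInd(lin, dims)
  slot <- integer(prod(dims))
  slot[lin] <- seq_len(n1)
  if (connectivity == "orthogonal") {
    offsets <- matrix(0L, 2L * nd, nd)
    for (a in seq_len(nd)) {
      offsets[2L * a - 1L, a] <- 1L
      offsets[2L * a, a] <- -1L
    }
  } else {
    offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
    offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  }
  strides <- cumprod(c(1L, dims[-nd]))
  lab <- integer(n1)
  cur <- 0L
  for (s in seq_len(n1)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- coords[i, ]
      for (o in seq_len(nrow(offsets))) {
        cn <- ci + offsets[o, ]
        if (any(cn < 1L) || any(cn > dims)) next
        ln <- 1L + sum((cn - 1L) * strides)
        j <- slot[ln]
        if (j != 0L && lab[j] == 0L) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

#' Find connected clusters of ones in a binary map
#'
#' Connected components under orthogonal-neighbor adjacency
#' (4-connectivity in 2D, 6 in 3D; time counts as one orthogonal axis on
#' space-time maps) or, optionally, full diagonal adjacency. Only valid
#' cells can carry ones. Clusters are ordered by decreasing size, ties by
#' the lexicographically smallest first cell.
#'
#' @param map a `binary_map`.
#' @param connectivity `"orthogonal"` (default) or `"diagonal"`.
#' @return list of clusters, each `list(cells, size)` where `cells` is a
#'   matrix of lattice coordinates (rows sorted lexicographically).
#' @export
find_clusters <- function(map, connectivity = c("orthogonal", "diagonal")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(map$arr)
  lin <- which(map$arr == 1L)
  if (length(lin) == 0) return(list())
  lab <- .label_components(lin, dims, connectivity)
  coords <- arrayInd(lin, dims)
  out <- lapply(split(seq_along(lin), lab), function(ix) {
    cells <- coords[ix, , drop = FALSE]
    ord <- do.call(order, as.data.frame(cells))
    list(cells = cells[ord, , drop = FALSE], size = length(ix))
  })
  sizes <- vapply(out, `[[`, numeric(1), "size")
  firsts <- t(vapply(out, function(cl) cl$cells[1, ], numeric(ncol(coords))))
  ord <- do.call(order, c(list(-sizes), as.data.frame(firsts)))
  unname(out[ord])
}

#' Permutation null distribution of the maximum cluster size
#'
#' Each permutation re-places the observed number of ones uniformly at
#' random among the valid cells and records the size of the largest
#' connected cluster (0 if the map has no ones). This is the reference
#' distribution the observed cluster sizes are compared against.
#'
#' @param map a `binary_map`.
#' @param n_perm number of permutations (>= 1).
#' @param connectivity as in [find_clusters()].
#' @param seed RNG seed.
#' @return integer vector of `n_perm` maximum cluster sizes.
#' @export
max_cluster_null <- function(map, n_perm = 1000L,
                             connectivity = c("orthogonal", "diagonal"),
                             seed = 1L) {
  connectivity <- match.arg(connectivity)
  .assert(n_perm >= 1, "n_perm must be >= 1", "invalid_nperm")
  dims <- dim(map$arr)
  valid_lin <- which(map$valid)
  n1 <- sum(map$arr)
  if (n1 > length(valid_lin))
    .err("more ones than valid cells", "too_many_ones")
  if (n1 == 0) return(integer(n_perm))
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      ones <- valid_lin[sample.int(length(valid_lin), n1)]
      max(tabulate(.label_components(ones, dims, connectivity)))
    }, integer(1))
  })
}

#' Annotate observed clusters with Monte-Carlo significance
#'
#' The permutation p-value of a cluster of size k is
#' `(1 + #{null >= k}) / (1 + n_perm)`; a cluster is flagged significant iff
#' its size strictly exceeds the empirical `(1 - alpha)` quantile of the
#' null maximum-cluster-size distribution (the "larger than 100*(1-alpha)%
#' of the permuted maxima" rule).
#'
#' @param observed list of clusters from [find_clusters()].
#' @param null integer vector of permuted maximum cluster sizes.
#' @param alpha cluster-level significance threshold.
#' @return the cluster list with `p` and `significant` added to each element.
#' @export
mcs_significance <- function(observed, null, alpha = 0.001) {
  .assert(length(null) > 0, "null distribution must be non-empty",
          "empty_null")
  if (length(observed) == 0) return(observed)
  thr <- as.numeric(quantile(null, 1 - alpha, type = 1))
  lapply(observed, function(cl) {
    cl$p <- (1 + sum(null >= cl$size)) / (1 + length(null))
    cl$significant <- cl$size > thr
    cl
  })
}

# summarize clusters of a space-time or spatial map into a table.
# For space-time maps the last axis is time; `times` converts it to seconds.
.cluster_table <- function(clusters, direction, times = NULL,
                           spatial_axes = NULL) {
  if (length(clusters) == 0)
    return(data.frame(cluster_number = integer(0), size = integer(0),
                      n_channels_or_voxels = integer(0),
                      time_start_s = numeric(0), time_end_s = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      direction = character(0)))
  nd <- ncol(clusters[[1]]$cells)
  if (is.null(spatial_axes)) spatial_axes <- seq_len(nd - !is.null(times))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    spat <- cl$cells[, spatial_axes, drop = FALSE]
    n_sp <- nrow(unique(spat))
    if (!is.null(times)) {
      taxis <- cl$cells[, nd]
      t0 <- min(times[taxis]); t1 <- max(times[taxis])
    } else t0 <- t1 <- NA_real_
    data.frame(cluster_number = i, size = cl$size,
               n_channels_or_voxels = n_sp,
               time_start_s = t0, time_end_s = t1,
               p_value = cl$p %||% NA_real_,
               significant = isTRUE(cl$significant),
               direction = direction, stringsAsFactors = FALSE)
  }))
}
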