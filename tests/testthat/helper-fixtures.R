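# small shared geometry built once per test run
tiny_sensors <- function(n = 16) make_sensor_array(n, 0.09, 0.102)

tiny_grid <- function(spacing = 0.024, radius = 0.076, roi = TRUE) {
  suppressWarnings(make_source_grid(spacing, radius,
                                    if (roi) default_roi_spec() else NULL))
}

# a recording with known content: given channel x sample matrix and events
manual_recording <- function(data, fs = 150, events = NULL) {
  if (is.null(events))
    events <- data.frame(sample = integer(0), condition = character(0),
                         is_correct = logical(0))
  structure(list(data = data, fs = fs, events = events, subject = 1L,
                 seed = 1L), class = "recording")
}

# exhaustive max-cluster-size distribution for k ones on small maps:
# enumerates every placement of the ones over the valid cells
exact_max_cluster_dist <- function(valid, k, dims,
                                   connectivity = "orthogonal") {
  valid_lin <- which(valid)
  placements <- utils::combn(valid_lin, k)
  sizes <- apply(placements, 2, function(ones) {
    max(tabulate(megseqmem:::.label_components(ones, dims, connectivity)))
  })
  table(factor(sizes, levels = seq_len(k))) / ncol(placements)
}

# parse a "label:count;..." tally into a named integer vector
parse_roi_counts <- function(counts) {
  kv <- do.call(rbind, strsplit(strsplit(counts, ";")[[1]], ":"))
  stats::setNames(as.integer(kv[, 2]), kv[, 1])
}
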