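#' Write a recording as a flat binary array with a JSON sidecar
#'
#' The channel-by-sample matrix is stored as little-endian doubles
#' (`<stem>.bin`) and all metadata — dimensions, sampling rate, channel
#' names, events, subject id, seed — in a JSON sidecar (`<stem>.json`).
#'
#' @param rec a `recording`.
#' @param stem path without extension.
#' @return the stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 8, endian = "little")
  meta <- list(n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               fs = rec$fs, channels = rownames(rec$data),
               events = rec$events, subject = rec$subject, seed = rec$seed)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#' @param stem path without extension.
#' @return a `recording`.
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  data <- matrix(x, meta$n_channels, meta$n_samples)
  rownames(data) <- meta$channels
  structure(list(data = data, fs = meta$fs,
                 events = as.data.frame(meta$events),
                 subject = meta$subject, seed = meta$seed),
            class = "recording")
}

#' Write tone sequences as a JSON list
#' @param seqs list of `tone_sequence` objects.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
  jsonlite::write_json(lapply(seqs, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read tone sequences from a JSON list written by [write_sequences()]
#' @param path input path.
#' @return list of `tone_sequence` objects.
#' @export
read_sequences <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    tone_sequence(raw$pitches[[i]], raw$tone_duration_ms[i], raw$role[i],
                  raw$piece_class[i])
  })
}

#' Write a cluster table as TSV
#' @param tab data frame of clusters.
#' @param path output path.
#' @export
write_cluster_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a per-dipole map as NIfTI on the synthetic source lattice
#'
#' Places per-dipole values on the regular 3D lattice and writes a NIfTI
#' volume whose affine encodes the grid spacing, for inspection in external
#' viewers. Requires the RNifti package.
#'
#' @param values numeric vector, one value per grid dipole.
#' @param grid the `source_grid`.
#' @param path output `.nii` path.
#' @export
export_source_nifti <- function(values, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    .err("RNifti is required for NIfTI export", "missing_dependency")
  dims <- attr(grid, "lattice_dim")
  arr <- array(0, dims)
  arr[cbind(grid$ix, grid$iy, grid$iz)] <- values
  sp <- attr(grid, "spacing") * 1000   # mm
  img <- RNifti::asNifti(arr, pixdim = c(sp, sp, sp))
  RNifti::writeNifti(img, path)
  invisible(path)
}
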