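#' Configuration of a full simulated-experiment run
#'
#' Collects every parameter of the pipeline: geometry, cohort size, analysis
#' bands, statistical thresholds, permutation count, connectivity and master
#' seed. Defaults are desk-scale (64 sensor sites, 12-mm grid, 12 subjects)
#' so a complete run finishes quickly on one CPU; `paper_scale = TRUE`
#' switches to the full-scale geometry (102 sites, 8-mm grid, 71 subjects).
#'
#' @param n_subjects cohort size.
#' @param n_positions sensor sites (channels = 3x sites).
#' @param grid_spacing source-grid spacing (m).
#' @param grid_radius source-sphere radius (m).
#' @param head_radius,shell_radius head and sensor-shell radii (m).
#' @param bands named list of band edges (Hz); the first is treated as the
#'   slow band and the second as the fast band.
#' @param sensor_t_alpha per-cell alpha of the sensor paired t-tests.
#' @param sensor_cluster_alpha cluster alpha of the sensor MCS.
#' @param voxel_alpha per-dipole alpha of the group-level source tests.
#' @param familiarity_alpha alpha of the familiarity correlation analysis.
#' @param n_perm Monte-Carlo permutations (>= 100).
#' @param connectivity `"orthogonal"` or `"diagonal"` cluster adjacency.
#' @param lambda_fraction beamformer regularization fraction.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param paper_scale use the full-scale geometry and cohort.
#' @param cohort optional `cohort_config` overriding the one derived from
#'   this configuration.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_subjects = 12L, n_positions = 64L,
                       grid_spacing = 0.012, grid_radius = 0.08,
                       head_radius = 0.09, shell_radius = 0.102,
                       bands = list(slow = c(0.1, 1), fast = c(2, 8)),
                       sensor_t_alpha = 0.01, sensor_cluster_alpha = 0.001,
                       voxel_alpha = 0.05, familiarity_alpha = 0.05,
                       n_perm = 1000L, connectivity = "orthogonal",
                       lambda_fraction = 0.05, seed = 1L, out_dir = NULL,
                       paper_scale = FALSE, cohort = NULL) {
  if (paper_scale) {
    n_subjects <- 71L; n_positions <- 102L; grid_spacing <- 0.008
  }
  alphas <- c(sensor_t_alpha, sensor_cluster_alpha, voxel_alpha,
              familiarity_alpha)
  if (!all(alphas > 0 & alphas < 1))
    .err("all alpha levels must lie in (0, 1)", "config_invalid")
  if (n_perm < 100) .err("n_perm must be >= 100", "config_invalid")
  .assert(length(bands) >= 1 && !is.null(names(bands)),
          "bands must be a named list of c(low, high) edges", "config_invalid")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_positions = as.integer(n_positions),
                 grid_spacing = grid_spacing, grid_radius = grid_radius,
                 head_radius = head_radius, shell_radius = shell_radius,
                 bands = bands, sensor_t_alpha = sensor_t_alpha,
                 sensor_cluster_alpha = sensor_cluster_alpha,
                 voxel_alpha = voxel_alpha,
                 familiarity_alpha = familiarity_alpha,
                 n_perm = as.integer(n_perm), connectivity = connectivity,
                 lambda_fraction = lambda_fraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bands))
    raw$bands <- lapply(raw$bands, as.numeric)
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .err(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         "stage_failure")
  })
}

#' Run the complete simulated experiment and analysis
#'
#' Orchestrates all stages deterministically under the master seed:
#' geometry and forward model; cohort simulation; per-subject broadband
#' sensor preprocessing (epoching on correct trials, condition averaging,
#' planar combination) and per-band beamformer source reconstruction with
#' first-level memorized-minus-novel contrasts; sensor-level paired-t +
#' cluster MCS per piece; source-level tone-window MCS per piece and band;
#' memorized tonal-vs-atonal and slow-vs-fast band contrasts; familiarity
#' correlation; behavioral ANOVAs with Bonferroni post-hocs; and stimulus
#' information-content/entropy statistics. Tables are written as TSV to
#' `out_dir` together with a JSON manifest of files (MD5), seeds and
#' parameters.
#'
#' @param cfg a `run_config`.
#' @param gt ground truth (default [default_ground_truth()]).
#' @return a report list (tables and test results) with the manifest path.
#' @export
run_all <- function(cfg, gt = default_ground_truth()) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir %||% tempfile("megseqmem_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(cfg$seed, 6)
  pieces <- c("tonal", "atonal")
  band_names <- names(cfg$bands)

  geom <- .stage("geometry", {
    sensors <- make_sensor_array(cfg$n_positions, cfg$head_radius,
                                 cfg$shell_radius)
    grid <- make_source_grid(cfg$grid_spacing, cfg$grid_radius,
                             default_roi_spec())
    list(sensors = sensors, grid = grid,
         lf = compute_lead_field(grid, sensors))
  })

  ccfg <- cohort_config(n_subjects = cfg$n_subjects, seed = seeds[1])

  # per-subject simulation + preprocessing (streaming: one recording at a time)
  subj <- .stage("simulate_preprocess", {
    subj_seeds <- spawn_seeds(ccfg$seed, ccfg$n_subjects)
    res <- list(behavior = list(), familiarity = integer(0),
                comb = list(), contrasts = list(), wm_mem = list())
    for (i in seq_len(ccfg$n_subjects)) {
      s <- simulate_subject(gt, ccfg, geom$lf, subj_seeds[i], subject_id = i)
      res$behavior[[i]] <- s$behavior
      res$familiarity[i] <- s$familiarity
      # broadband sensor level
      ep <- select_correct(epoch(s$recording))
      for (pc in pieces) {
        for (cond in c("memorized", "novel")) {
          lab <- paste(cond, pc, sep = "_")
          ev <- combine_planar(average_condition(ep, lab), geom$sensors)
          res$comb[[pc]][[cond]][[i]] <- ev
        }
      }
      # per-band source level
      for (b in band_names) {
        edges <- cfg$bands[[b]]
        recb <- bandpass(s$recording, edges[1], edges[2])
        epb <- select_correct(epoch(recb))
        C <- data_covariance(epb, cfg$lambda_fraction)
        w <- lcmv_weights(geom$lf, C, orientation = "vector")
        for (pc in pieces) {
          src <- lapply(c("memorized", "novel"), function(cond) {
            reconstruct(w, average_condition(epb, paste(cond, pc, sep = "_")),
                        normalize = TRUE)
          })
          # magnitude window contrasts on unit-noise-gain vector estimates:
          # orientation/sign ambiguity resolved by the component norm,
          # depth bias removed by normalization
          res$contrasts[[b]][[pc]][[i]] <- window_contrast(src[[1]], src[[2]])
          res$wm_mem[[b]][[pc]][[i]] <- window_magnitude(src[[1]])
        }
      }
      rm(s, ep); gc(FALSE)
    }
    res$times <- NULL
    res
  })
  sensor <- .stage("sensor_level", {
    sseeds <- spawn_seeds(seeds[2], length(pieces))
    out <- list()
    for (k in seq_along(pieces)) {
      pc <- pieces[k]
      out[[pc]] <- sensor_analysis(subj$comb[[pc]]$memorized,
                                   subj$comb[[pc]]$novel,
                                   t_alpha = cfg$sensor_t_alpha,
                                   cluster_alpha = cfg$sensor_cluster_alpha,
                                   n_perm = cfg$n_perm, seed = sseeds[k],
                                   connectivity = cfg$connectivity)$clusters
    }
    out
  })

  source_tabs <- .stage("source_level", {
    sseeds <- spawn_seeds(seeds[3], length(pieces) * length(band_names) +
                            length(band_names) + 1L)
    out <- list()
    si <- 0L
    for (b in band_names) {
      for (pc in pieces) {
        si <- si + 1L
        out[[paste(pc, b, sep = "_")]] <-
          tone_window_mcs(subj$contrasts[[b]][[pc]], geom$grid,
                          times = NULL, band_count = length(band_names),
                          voxel_alpha = cfg$voxel_alpha,
                          n_perm = cfg$n_perm, seed = sseeds[si],
                          connectivity = cfg$connectivity)
      }
    }
    for (b in band_names) {
      si <- si + 1L
      out[[paste0("piece_contrast_", b)]] <-
        tone_window_mcs(lapply(seq_len(cfg$n_subjects), function(i) {
          subj$wm_mem[[b]]$tonal[[i]] - subj$wm_mem[[b]]$atonal[[i]]
        }), geom$grid, times = NULL,
        band_count = length(band_names), voxel_alpha = 0.01,
        n_perm = cfg$n_perm, seed = sseeds[si],
        connectivity = cfg$connectivity)
    }
    if (length(band_names) >= 2) {
      si <- si + 1L
      out$band_contrast <-
        band_contrast(subj$wm_mem[[band_names[1]]]$tonal,
                      subj$wm_mem[[band_names[2]]]$tonal, geom$grid,
                      voxel_alpha = cfg$voxel_alpha,
                      band_count = length(band_names),
                      n_perm = cfg$n_perm, seed = sseeds[si],
                      connectivity = cfg$connectivity)
    }
    out
  })

  familiarity <- .stage("familiarity", {
    familiarity_correlation(subj$familiarity,
                            subj$wm_mem[[band_names[1]]]$tonal, geom$grid,
                            alpha = cfg$familiarity_alpha,
                            n_perm = cfg$n_perm, seed = seeds[4],
                            connectivity = cfg$connectivity)
  })

  behavior <- .stage("behavior", {
    tab <- do.call(rbind, subj$behavior)
    list(table = tab,
         anova_accuracy = one_way_anova(tab, "accuracy"),
         anova_rt = one_way_anova(tab, "rt"),
         posthoc_accuracy = suppressWarnings(
           posthoc_bonferroni(tab, "accuracy")),
         posthoc_rt = suppressWarnings(posthoc_bonferroni(tab, "rt")))
  })

  stimuli <- .stage("stimuli", {
    corpus <- toy_corpus(seed = seeds[5])
    piece <- toy_corpus(1, 205, seed = seeds[5] + 1L)[[1]]
    excerpts_tonal <- lapply(0:39, function(k) {
      tone_sequence(piece$pitches[k * 5 + 1:5], role = "memorized_excerpt")
    })
    map <- random_pitch_map(unique(piece$pitches %% 12), seed = seeds[5])
    excerpts_atonal <- lapply(excerpts_tonal, make_atonal, map = map)
    alphabet <- sort(unique(c(unlist(lapply(corpus, `[[`, "pitches")),
                              piece$pitches,
                              unlist(lapply(excerpts_atonal, `[[`, "pitches")))))
    model <- train_ngram(corpus, order = 2, gamma = 1, alphabet = alphabet)
    prof_t <- lapply(excerpts_tonal, predictability_profile, model = model)
    prof_a <- lapply(excerpts_atonal, predictability_profile, model = model)
    ic_t <- unlist(lapply(prof_t, `[[`, "ic"))
    ic_a <- unlist(lapply(prof_a, `[[`, "ic"))
    h_t <- unlist(lapply(prof_t, `[[`, "h"))
    h_a <- unlist(lapply(prof_a, `[[`, "h"))
    list(profile = data.frame(
           tone = seq_along(ic_t), ic_tonal = ic_t, ic_atonal = ic_a,
           h_tonal = h_t, h_atonal = h_a),
         ic_test = compare_predictability(ic_t, ic_a),
         h_test = compare_predictability(h_t, h_a),
         mean_ic = c(tonal = mean(ic_t), atonal = mean(ic_a)),
         mean_h = c(tonal = mean(h_t), atonal = mean(h_a)))
  })

  # write outputs + manifest
  files <- character(0)
  wr <- function(tab, name) {
    p <- file.path(out_dir, name)
    write_cluster_table(tab, p)
    files[[name]] <<- unname(tools::md5sum(p))
    p
  }
  for (pc in pieces) wr(sensor[[pc]], sprintf("sensor_clusters_%s.tsv", pc))
  for (nm in names(source_tabs))
    wr(source_tabs[[nm]], sprintf("source_clusters_%s.tsv", nm))
  wr(familiarity$clusters, "familiarity_clusters.tsv")
  wr(behavior$table, "behavior.tsv")
  wr(behavior$posthoc_accuracy, "posthoc_accuracy.tsv")
  wr(behavior$posthoc_rt, "posthoc_rt.tsv")
  wr(stimuli$profile, "stimuli_profile.tsv")
  manifest <- list(package = "megseqmem",
                   parameters = cfg[setdiff(names(cfg), "out_dir")],
                   master_seed = cfg$seed, stage_seeds = seeds,
                   files = as.list(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  list(sensor = sensor, source = source_tabs, familiarity = familiarity,
       behavior = behavior, stimuli = stimuli, out_dir = out_dir,
       manifest = manifest_path)
}
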