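#' Ground-truth source effects for the simulated paradigm
#'
#' Each effect is a dipole-level activation: the conditions it applies to,
#' the frequency band its time course lives in (`"slow"`: a smooth envelope
#' over the whole five-tone sequence; `"fast"`: a transient response to every
#' 250-ms tone), the ROI whose dipoles carry it, a per-tone-window amplitude
#' envelope (nA.m, five values, one per 250-ms tone window), and an
#' orientation seed fixing the tangential moment direction of each dipole so
#' the effect is consistent across subjects.
#'
#' @param effects list of effects, each a list with fields `conditions`
#'   (character vector of condition labels), `band` (`"slow"`/`"fast"`),
#'   `roi` (character vector of ROI labels), `window_amp` (numeric length 5,
#'   nA.m per dipole, >= 0), `orientation_seed` (integer), and optionally
#'   `n_focus` (dipoles activated per ROI patch, nearest the patch
#'   centroid; default 3, `Inf` activates the whole patch).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(effects) {
  for (e in effects) {
    .assert(all(c("conditions", "band", "roi", "window_amp",
                  "orientation_seed") %in% names(e)),
            "each effect needs conditions, band, roi, window_amp, orientation_seed",
            "invalid_ground_truth")
    .assert(length(e$window_amp) == 5 && all(e$window_amp >= 0),
            "window_amp must be five non-negative amplitudes (nA.m)",
            "invalid_ground_truth")
    .assert(e$band %in% c("slow", "fast"), "band must be 'slow' or 'fast'",
            "invalid_ground_truth")
  }
  structure(list(effects = effects), class = "ground_truth")
}

#' Default ground truth: the tonal/atonal recognition dissociation
#'
#' Encodes the effect geometry the package's analysis chain is designed to
#' recover: every condition evokes a fast-band auditory response to each
#' tone; on top of that, recognition of memorized tonal sequences adds a
#' slow-band effect in the medial memory territory (cingulate patch of the
#' hippocampal-cingulate network) over tone windows 3-5, and recognition of
#' memorized atonal sequences adds a slow-band effect in the right auditory
#' ROI across all five windows.
#'
#' @param tone_amp baseline per-tone auditory response amplitude (nA.m).
#' @param memory_amp amplitude of the memorized-tonal memory-region effect.
#' @param atonal_amp amplitude of the memorized-atonal auditory-region effect.
#' @return a `ground_truth`.
#' @export
default_ground_truth <- function(tone_amp = 30, memory_amp = 60,
                                 atonal_amp = 35) {
  ground_truth(list(
    list(conditions = .conditions, band = "fast",
         roi = c("auditory_L", "auditory_R"),
         window_amp = rep(tone_amp, 5), orientation_seed = 101L,
         n_focus = 3L),
    list(conditions = "memorized_tonal", band = "slow",
         roi = "cingulate",
         window_amp = c(0, 0, memory_amp, memory_amp * 1.2, memory_amp * 1.2),
         orientation_seed = 103L, n_focus = 4L),
    list(conditions = "memorized_atonal", band = "slow",
         roi = "auditory_R",
         window_amp = rep(atonal_amp, 5), orientation_seed = 104L,
         n_focus = 3L)
  ))
}

#' Cohort simulation parameters
#'
#' Defaults reproduce the simulated study conditions: 71 subjects, two pieces
#' with 40 memorized + 40 novel five-tone excerpts each (160 trials), 250-ms
#' tones with a 100-ms baseline, 150 Hz sampling, condition-specific
#' behavioral accuracy and reaction-time means (memorized-atonal hardest and
#' slowest), and 1-7 familiarity ratings.
#'
#' @param n_subjects number of subjects.
#' @param fs sampling rate (Hz).
#' @param n_trials_per_condition trials per condition (4 conditions).
#' @param noise_sd_mag magnetometer sensor-noise sd (T, per sample).
#' @param noise_sd_grad gradiometer sensor-noise sd (T/m, per sample).
#' @param inter_subject_amp_sd sd of the per-subject log amplitude factor.
#' @param trial_amp_sd sd of the per-trial log amplitude factor.
#' @param dipole_amp_sd sd of the per-dipole, per-trial log amplitude jitter
#'   (decorrelates the dipoles of an effect, as in real cortex).
#' @param dipole_latency_sd_ms sd of the per-dipole response latency offset
#'   (ms), drawn once per subject.
#' @param n_background_dipoles number of ongoing background brain-noise
#'   dipoles per subject (randomly placed).
#' @param background_amp RMS amplitude of each background dipole (nA.m);
#'   background time courses are AR(1) (low-pass) processes.
#' @param accuracy_mean named mean number of correct responses (of 40) per
#'   condition.
#' @param accuracy_logit_sd subject-level ability sd on the logit scale
#'   (creates the between-subject accuracy spread).
#' @param rt_mean_ms named mean reaction time per condition (ms).
#' @param rt_subject_sd_log subject-level log-RT offset sd.
#' @param rt_trial_sd_log trial-level log-RT sd.
#' @param familiarity_probs probabilities of familiarity ratings 1-7.
#' @param iti_range inter-trial gap range (s) appended after each 1.35-s trial.
#' @param seed master seed for the cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 71L, fs = 150, n_trials_per_condition = 40L,
                          noise_sd_mag = 2e-13, noise_sd_grad = 8e-12,
                          inter_subject_amp_sd = 0.1, trial_amp_sd = 0.1,
                          dipole_amp_sd = 0.4, dipole_latency_sd_ms = 40,
                          n_background_dipoles = 100L, background_amp = 45,
                          accuracy_mean = c(memorized_tonal = 34.34,
                                            novel_tonal = 34.41,
                                            memorized_atonal = 30.98,
                                            novel_atonal = 34.51),
                          accuracy_logit_sd = 1.0,
                          rt_mean_ms = c(memorized_tonal = 1735.17,
                                         novel_tonal = 1799.52,
                                         memorized_atonal = 1879.44,
                                         novel_atonal = 1873.78),
                          rt_subject_sd_log = 0.14, rt_trial_sd_log = 0.25,
                          familiarity_probs = c(0.15, 0.30, 0.25, 0.15,
                                                0.08, 0.05, 0.02),
                          iti_range = c(0.3, 0.7), seed = 1L) {
  .assert(n_subjects >= 1, "n_subjects must be >= 1", "invalid_config")
  .assert(all(noise_sd_mag >= 0, noise_sd_grad >= 0, inter_subject_amp_sd >= 0,
              trial_amp_sd >= 0, accuracy_logit_sd >= 0),
          "all standard deviations must be >= 0", "invalid_config")
  .assert(all(sort(names(accuracy_mean)) == sort(.conditions)) &&
            all(accuracy_mean >= 0 & accuracy_mean <= n_trials_per_condition),
          "accuracy_mean must name all four conditions with values in [0, n_trials]",
          "invalid_config")
  .assert(all(rt_mean_ms > 0), "RT means must be positive", "invalid_config")
  .assert(length(familiarity_probs) == 7 && all(familiarity_probs >= 0),
          "familiarity_probs must be 7 non-negative weights", "invalid_config")
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 noise_sd_mag = noise_sd_mag, noise_sd_grad = noise_sd_grad,
                 inter_subject_amp_sd = inter_subject_amp_sd,
                 trial_amp_sd = trial_amp_sd,
                 dipole_amp_sd = dipole_amp_sd,
                 dipole_latency_sd_ms = dipole_latency_sd_ms,
                 n_background_dipoles = as.integer(n_background_dipoles),
                 background_amp = background_amp,
                 accuracy_mean = accuracy_mean,
                 accuracy_logit_sd = accuracy_logit_sd,
                 rt_mean_ms = rt_mean_ms,
                 rt_subject_sd_log = rt_subject_sd_log,
                 rt_trial_sd_log = rt_trial_sd_log,
                 familiarity_probs = familiarity_probs / sum(familiarity_probs),
                 iti_range = iti_range, seed = as.integer(seed)),
            class = "cohort_config")
}

# per-band canonical single-trial source time courses on the 0..1.25 s trial
# window, sampled at fs; window_amp is scaled per 250-ms tone window.
# slow: per-window box amplitudes smoothed with a 150-ms Hann kernel;
# fast: a damped 5.5-Hz transient launched at each tone onset.
.trial_timecourse <- function(window_amp, band, fs) {
  n <- floor(1.25 * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  win <- pmin(floor(t / 0.25) + 1L, 5L)
  if (band == "slow") {
    # box envelope over the tone windows, Hann-smoothed, with a smooth
    # cosine offset tail so the abrupt stimulus offset does not ring
    # through the high-pass filter
    tail_n <- round(0.2 * fs)
    x <- c(window_amp[win],
           window_amp[5] * 0.5 * (1 + cos(pi * seq_len(tail_n) / tail_n)))
    klen <- max(3L, round(0.15 * fs))
    k <- 0.5 * (1 - cos(2 * pi * seq_len(klen) / (klen + 1)))
    k <- k / sum(k)
    pad <- c(rep(x[1], klen), x, rep(0, klen))
    y <- stats::filter(pad, k, sides = 2)
    as.numeric(y[(klen + 1):(klen + n + tail_n)])
  } else {
    y <- numeric(n)
    for (w in 1:5) {
      tau <- t - (w - 1) * 0.25
      resp <- ifelse(tau >= 0 & tau < 0.25,
                     sin(2 * pi * 5.5 * tau) * exp(-tau / 0.06), 0)
      y <- y + window_amp[w] * resp
    }
    y
  }
}

# active dipoles of an effect: the n_focus dipoles nearest each ROI patch
# centroid (compact focal generators at the core of the labelled territory),
# plus per-patch locally coherent tangential orientations. Deterministic in
# the orientation seed.
.effect_dipoles <- function(grid, rois, n_focus, orientation_seed) {
  dip <- integer(0)
  patch_id <- integer(0)
  for (pi in seq_along(rois)) {
    idx <- which(grid$roi == rois[pi])
    if (length(idx) == 0) next
    ctr <- c(mean(grid$x[idx]), mean(grid$y[idx]), mean(grid$z[idx]))
    d <- sqrt((grid$x[idx] - ctr[1])^2 + (grid$y[idx] - ctr[2])^2 +
                (grid$z[idx] - ctr[3])^2)
    take <- idx[order(d)][seq_len(min(n_focus, length(idx)))]
    dip <- c(dip, take)
    patch_id <- c(patch_id, rep(pi, length(take)))
  }
  if (length(dip) == 0) return(NULL)
  M <- withr::with_seed(as.integer(orientation_seed), {
    base <- runif(length(rois), 0, 2 * pi)
    ang <- base[patch_id] + rnorm(length(dip), 0, 0.3)
    cbind(cos(ang), sin(ang))
  })
  list(dip = dip, M = M)
}

#' Simulate one subject's MEG recording, behavior and familiarity rating
#'
#' Generates a continuous multichannel recording containing 160 trials (40
#' per condition; tonal block then atonal block, trial order randomized
#' within block): for each trial, dipole-level band-specific time courses
#' scaled by the matching ground-truth effects are projected through the lead
#' field, and iid Gaussian sensor noise (per channel type) is added.
#' Response correctness is Bernoulli from the subject's condition accuracy,
#' reaction times are lognormal, and a familiarity rating (1-7) is drawn.
#' Fully reproducible for a fixed `subject_seed`.
#'
#' @param gt a `ground_truth`.
#' @param cfg a `cohort_config`.
#' @param lf a `lead_field` (carries the grid and sensors).
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @return a list with elements `recording` (class `recording`: `data`
#'   channels x samples, `fs`, `events` data frame, `subject`, `seed`),
#'   `behavior` (data frame, one row per condition), and `familiarity`
#'   (integer 1-7).
#' @export
simulate_subject <- function(gt, cfg, lf, subject_seed, subject_id = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(cfg, "cohort_config"),
            inherits(lf, "lead_field"))
  grid <- attr(lf, "grid")
  sensors <- attr(lf, "sensors")
  fs <- cfg$fs
  npc <- cfg$n_trials_per_condition
  trial_len <- floor(1.35 * fs) + 2L      # baseline + excerpt + margin
  n_trials <- 4L * npc

  withr::with_seed(as.integer(subject_seed), {
    # trial schedule: tonal block then atonal block, shuffled within block
    cond <- c(sample(rep(c("memorized_tonal", "novel_tonal"), npc)),
              sample(rep(c("memorized_atonal", "novel_atonal"), npc)))
    iti <- round(runif(n_trials, cfg$iti_range[1], cfg$iti_range[2]) * fs)
    onset <- cumsum(c(round(1.0 * fs), trial_len + iti))[seq_len(n_trials)]
    n_samp <- onset[n_trials] + trial_len + round(1.0 * fs)

    # behavior
    subj_ability <- rnorm(1, 0, cfg$accuracy_logit_sd)
    p_cond <- plogis(qlogis(pmin(pmax(cfg$accuracy_mean / npc, 1e-3),
                                 1 - 1e-3)) + subj_ability)
    correct <- rbinom(n_trials, 1, p_cond[cond]) == 1
    subj_rt_off <- rnorm(1, 0, cfg$rt_subject_sd_log)
    rt <- rlnorm(n_trials,
                 log(cfg$rt_mean_ms[cond]) + subj_rt_off -
                   cfg$rt_trial_sd_log^2 / 2,
                 cfg$rt_trial_sd_log)
    familiarity <- sample(1:7, 1, prob = cfg$familiarity_probs)

    # neural signal
    subj_amp <- exp(rnorm(1, 0, cfg$inter_subject_amp_sd))
    n_ch <- nrow(sensors)
    data <- matrix(0, n_ch, n_samp)
    # per-effect dipole sets, oriented lead columns and per-dipole shapes;
    # each dipole gets a fixed latency offset and per-trial amplitude jitter
    # so the sources of an effect are strongly but not perfectly correlated
    # (perfectly coherent sources are unphysical and would be cancelled by a
    # minimum-variance inverse model)
    eff_cols <- lapply(gt$effects, function(e) {
      ed <- .effect_dipoles(grid, e$roi, e$n_focus %||% 3L,
                            e$orientation_seed)
      if (is.null(ed)) return(NULL)
      dip <- ed$dip
      M <- ed$M
      lcol <- matrix(0, n_ch, length(dip))
      for (j in seq_along(dip))
        lcol[, j] <- lf[, dip[j], 1] * M[j, 1] + lf[, dip[j], 2] * M[j, 2]
      shape <- .trial_timecourse(e$window_amp * 1e-9, e$band, fs)
      lat <- round(rnorm(length(dip), 0, cfg$dipole_latency_sd_ms / 1000 * fs))
      shapes <- t(vapply(lat, function(l) {
        if (l == 0) shape
        else if (l > 0) c(rep(0, l), shape[seq_len(length(shape) - l)])
        else c(shape[(-l + 1):length(shape)], rep(0, -l))
      }, numeric(length(shape))))
      list(dip = dip, L = lcol, shapes = shapes)
    })
    for (k in seq_len(n_trials)) {
      trial_amp <- subj_amp * exp(rnorm(1, 0, cfg$trial_amp_sd))
      idx0 <- onset[k]                    # sample index of excerpt onset
      for (i_e in seq_along(gt$effects)) {
        e <- gt$effects[[i_e]]
        ec <- eff_cols[[i_e]]
        if (is.null(ec) || !(cond[k] %in% e$conditions)) next
        nd <- length(ec$dip)
        amps <- trial_amp * exp(rnorm(nd, 0, cfg$dipole_amp_sd) -
                                  cfg$dipole_amp_sd^2 / 2)
        seg <- idx0 + seq_len(ncol(ec$shapes)) - 1L
        data[, seg] <- data[, seg] + ec$L %*% (ec$shapes * amps)
      }
    }
    # ongoing background brain noise: AR(1) dipole time courses
    if (cfg$n_background_dipoles > 0 && cfg$background_amp > 0) {
      nb <- min(cfg$n_background_dipoles, nrow(grid))
      bdip <- sample.int(nrow(grid), nb)
      Mb <- cbind(cos(ang_b <- runif(nb, 0, 2 * pi)), sin(ang_b))
      Lb <- matrix(0, n_ch, nb)
      for (j in seq_len(nb))
        Lb[, j] <- lf[, bdip[j], 1] * Mb[j, 1] + lf[, bdip[j], 2] * Mb[j, 2]
      phi <- 0.97
      innov_sd <- sqrt(1 - phi^2)          # unit-variance AR(1)
      S <- vapply(seq_len(nb), function(j) {
        as.numeric(stats::filter(rnorm(n_samp, 0, innov_sd), phi,
                                 method = "recursive"))
      }, numeric(n_samp))
      data <- data + Lb %*% (t(S) * (cfg$background_amp * 1e-9 * subj_amp))
    }
    # sensor noise by channel type
    is_grad <- sensors$type == "planar_gradiometer"
    if (cfg$noise_sd_grad > 0 && any(is_grad))
      data[is_grad, ] <- data[is_grad, ] +
        matrix(rnorm(sum(is_grad) * n_samp, 0, cfg$noise_sd_grad),
               sum(is_grad), n_samp)
    if (cfg$noise_sd_mag > 0 && any(!is_grad))
      data[!is_grad, ] <- data[!is_grad, ] +
        matrix(rnorm(sum(!is_grad) * n_samp, 0, cfg$noise_sd_mag),
               sum(!is_grad), n_samp)
    rownames(data) <- sensors$channel

    events <- data.frame(sample = onset, condition = cond,
                         is_correct = correct, rt_ms = rt,
                         piece = ifelse(grepl("tonal$", cond) &
                                          !grepl("atonal$", cond),
                                        "tonal", "atonal"),
                         stringsAsFactors = FALSE)
    rec <- structure(list(data = data, fs = fs, events = events,
                          subject = subject_id, seed = as.integer(subject_seed)),
                     class = "recording")
    beh <- do.call(rbind, lapply(.conditions, function(cc) {
      sel <- events$condition == cc
      data.frame(subject = subject_id, condition = cc,
                 n_correct = sum(events$is_correct[sel]),
                 mean_rt = mean(events$rt_ms[sel]),
                 familiarity = familiarity, stringsAsFactors = FALSE)
    }))
    list(recording = rec, behavior = beh, familiarity = familiarity)
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: subject %s, %d channels x %d samples at %g Hz, %d events>\n",
              x$subject, nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Spawns one seed per subject deterministically from the master seed in
#' `cfg$seed` and simulates each subject independently.
#'
#' @param cfg a `cohort_config`.
#' @param gt a `ground_truth` (default [default_ground_truth()]).
#' @param lf a `lead_field`.
#' @param callback optional `function(subject_result, i)`; when given, each
#'   subject result is passed to it and only behavior/familiarity are
#'   retained (streaming mode keeps memory flat for large cohorts).
#' @return list with `subjects` (list of per-subject results, or `NULL`s in
#'   streaming mode), `behavior` (cohort behavioral table), `familiarity`
#'   (integer vector), `seeds`.
#' @export
simulate_cohort <- function(cfg, gt = default_ground_truth(), lf,
                            callback = NULL) {
  seeds <- spawn_seeds(cfg$seed, cfg$n_subjects)
  beh <- vector("list", cfg$n_subjects)
  fam <- integer(cfg$n_subjects)
  subjects <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    res <- simulate_subject(gt, cfg, lf, seeds[i], subject_id = i)
    beh[[i]] <- res$behavior
    fam[i] <- res$familiarity
    if (is.null(callback)) subjects[[i]] <- res else callback(res, i)
  }
  list(subjects = subjects, behavior = do.call(rbind, beh),
       familiarity = fam, seeds = seeds)
}
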