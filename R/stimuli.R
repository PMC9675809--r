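#' Construct a tone sequence
#'
#' A melodic stimulus: an ordered list of MIDI pitches with constant tone
#' duration. Excerpt sequences (the recognition-task stimuli) are exactly
#' five tones of 250 ms each, mirroring the five-note sequences used in
#' old/new auditory recognition paradigms.
#'
#' @param pitches integer vector of MIDI pitches (0--127).
#' @param tone_duration_ms positive integer, duration of every tone in ms.
#' @param role one of `"piece"`, `"memorized_excerpt"`, `"novel_excerpt"`.
#' @param piece_class one of `"tonal"`, `"atonal"`.
#' @return an object of class `tone_sequence`.
#' @export
tone_sequence <- function(pitches, tone_duration_ms = 250L,
                          role = c("piece", "memorized_excerpt",
                                   "novel_excerpt"),
                          piece_class = c("tonal", "atonal")) {
  role <- match.arg(role)
  piece_class <- match.arg(piece_class)
  pitches <- as.integer(pitches)
  .assert(length(pitches) > 0 && !anyNA(pitches),
          "pitches must be a non-empty integer vector", "invalid_sequence")
  .assert(all(pitches >= 0L & pitches <= 127L),
          "all pitches must be MIDI values in 0-127", "invalid_sequence")
  .assert(tone_duration_ms > 0, "tone_duration_ms must be positive",
          "invalid_sequence")
  if (role != "piece") {
    .assert(length(pitches) == 5L,
            "excerpt sequences must have exactly 5 pitches",
            "invalid_sequence")
  }
  structure(list(pitches = pitches,
                 tone_duration_ms = as.integer(tone_duration_ms),
                 role = role, piece_class = piece_class),
            class = "tone_sequence")
}

#' @export
print.tone_sequence <- function(x, ...) {
  cat(sprintf("<tone_sequence: %d tones, %d ms/tone, %s, %s>\n",
              length(x$pitches), x$tone_duration_ms, x$role, x$piece_class))
  invisible(x)
}

#' Pitch-class remapping for atonal transformation
#'
#' A `pitch_map` displaces each pitch class by one or two semitones up or
#' down, applied uniformly across octaves. Remapping every tone of a tonal
#' piece this way destroys the tonal center while preserving rhythm, contour
#' and the positional recurrence structure of the tones.
#'
#' @param displacements named integer vector; names are pitch classes
#'   (`"0"`..`"11"`), values in `{-2, -1, 1, 2}` (semitones).
#' @return an object of class `pitch_map`.
#' @export
pitch_map <- function(displacements) {
  .assert(length(displacements) > 0 && !is.null(names(displacements)),
          "displacements must be a named vector (names = pitch classes)",
          "invalid_map")
  pcs <- suppressWarnings(as.integer(names(displacements)))
  .assert(!anyNA(pcs) && all(pcs >= 0L & pcs <= 11L) && !anyDuplicated(pcs),
          "names must be distinct pitch classes 0-11", "invalid_map")
  d <- as.integer(displacements)
  if (!all(abs(d) %in% c(1L, 2L)))
    .err("every displacement must be 1 or 2 semitones up or down",
         "invalid_map")
  tgt <- (pcs + d) %% 12L
  .assert(!anyDuplicated(tgt),
          "mapping must be injective on the pitch classes present",
          "invalid_map")
  structure(stats::setNames(d, pcs), class = "pitch_map")
}

#' The three explicit example assignments of the atonal transformation
#'
#' C up to C-sharp, E up to F-sharp, G down to F.
#' @return a `pitch_map` covering pitch classes C, E and G.
#' @export
preset_pitch_map <- function() {
  pitch_map(c("0" = 1L, "4" = 2L, "7" = -2L))
}

#' Random valid pitch map over a set of pitch classes
#'
#' Draws displacements in `{-2,-1,1,2}` per pitch class, rejecting draws
#' until the induced pitch-class mapping is injective.
#'
#' @param pitch_classes integer vector of pitch classes (0-11) to cover.
#' @param seed integer RNG seed.
#' @return a `pitch_map`.
#' @export
random_pitch_map <- function(pitch_classes, seed = 1L) {
  pitch_classes <- sort(unique(as.integer(pitch_classes)))
  withr::with_seed(as.integer(seed), {
    repeat {
      d <- sample(c(-2L, -1L, 1L, 2L), length(pitch_classes), replace = TRUE)
      if (!anyDuplicated((pitch_classes + d) %% 12L)) break
    }
    pitch_map(stats::setNames(d, pitch_classes))
  })
}

#' Invert a pitch map
#' @param map a `pitch_map`.
#' @return the inverse `pitch_map` (target pitch classes back to sources).
#' @export
invert_pitch_map <- function(map) {
  pcs <- as.integer(names(map))
  tgt <- (pcs + as.integer(map)) %% 12L
  pitch_map(stats::setNames(-as.integer(map), tgt))
}

#' Apply the atonal transformation to a tone sequence
#'
#' Every pitch is displaced by the map entry of its pitch class; the same
#' conversion is applied to every occurrence, so equal-pitch positions in the
#' source remain equal in the target and rhythm is untouched.
#'
#' @param seq a `tone_sequence`.
#' @param map a `pitch_map` covering every pitch class present in `seq`.
#' @return a `tone_sequence` with `piece_class` flipped.
#' @export
make_atonal <- function(seq, map) {
  stopifnot(inherits(seq, "tone_sequence"), inherits(map, "pitch_map"))
  pcs <- seq$pitches %% 12L
  missing_pc <- setdiff(unique(pcs), as.integer(names(map)))
  if (length(missing_pc) > 0)
    .err(sprintf("pitch class(es) %s not covered by the map",
                 paste(missing_pc, collapse = ", ")),
         "mapping_incomplete")
  d <- as.integer(map)[match(pcs, as.integer(names(map)))]
  out <- seq$pitches + d
  .assert(all(out >= 0L & out <= 127L),
          "mapped pitches fall outside MIDI range 0-127", "invalid_sequence")
  tone_sequence(out, seq$tone_duration_ms, seq$role,
                if (seq$piece_class == "tonal") "atonal" else "tonal")
}

# ---- n-gram model of melodic expectation -----------------------------------

.ctx_key <- function(ctx) paste0("c:", paste(ctx, collapse = ","))

#' Train a bounded-order additively smoothed n-gram model
#'
#' Counts event occurrences after every context of length `0..order` seen in
#' the corpus. Next-event probabilities use additive smoothing:
#' `p(e|ctx) = (count(ctx,e) + gamma) / (count(ctx) + gamma * |A|)`,
#' so every probability is strictly positive. Contexts shorter than the model
#' order (e.g. at a sequence start) are scored with the matching shorter-order
#' counts (back-off to the longest available context).
#'
#' @param corpus non-empty list of `tone_sequence` objects (or integer
#'   vectors of pitches).
#' @param order context length n >= 0.
#' @param gamma additive pseudo-count, > 0.
#' @param alphabet optional integer event set; defaults to the union of all
#'   corpus pitches.
#' @return an object of class `ngram_model`.
#' @export
train_ngram <- function(corpus, order = 2L, gamma = 1, alphabet = NULL) {
  .assert(length(corpus) > 0, "corpus must be non-empty", "empty_corpus")
  .assert(order >= 0, "order must be >= 0", "invalid_model")
  .assert(gamma > 0, "gamma must be > 0", "invalid_model")
  seqs <- lapply(corpus, function(s) {
    if (inherits(s, "tone_sequence")) s$pitches else as.integer(s)
  })
  if (is.null(alphabet)) alphabet <- sort(unique(unlist(seqs)))
  alphabet <- sort(unique(as.integer(alphabet)))
  .assert(length(alphabet) >= 1, "alphabet must be non-empty", "invalid_model")

  counts <- vector("list", order + 1L)     # counts[[len+1]]: env key -> named counts
  for (len in 0:order) counts[[len + 1L]] <- new.env(parent = emptyenv())
  for (s in seqs) {
    ns <- length(s)
    for (i in seq_len(ns)) {
      for (len in 0:min(order, i - 1L)) {
        ctx <- if (len == 0) integer(0) else s[(i - len):(i - 1L)]
        key <- .ctx_key(ctx)
        env <- counts[[len + 1L]]
        ev <- as.character(s[i])
        cur <- if (exists(key, env, inherits = FALSE)) get(key, env) else
          integer(0)
        cur[ev] <- (if (ev %in% names(cur)) cur[[ev]] else 0L) + 1L
        assign(key, cur, envir = env)
      }
    }
  }
  structure(list(order = as.integer(order), alphabet = alphabet,
                 gamma = gamma, counts = counts),
            class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model: order %d, |A| = %d, gamma = %g>\n",
              x$order, length(x$alphabet), x$gamma))
  invisible(x)
}

#' Next-event probability distribution given a context
#'
#' @param object an `ngram_model`.
#' @param context integer vector of preceding events; truncated to the last
#'   `order` events. An unseen context yields the smoothed-uniform
#'   distribution.
#' @param ... unused.
#' @return named numeric vector of probabilities over the alphabet (sums to 1).
#' @export
predict.ngram_model <- function(object, context = integer(0), ...) {
  n <- object$order
  context <- as.integer(context)
  if (length(context) > n) context <- utils::tail(context, n)
  len <- length(context)
  env <- object$counts[[len + 1L]]
  key <- .ctx_key(context)
  cnt <- stats::setNames(numeric(length(object$alphabet)),
                         as.character(object$alphabet))
  if (exists(key, env, inherits = FALSE)) {
    seen <- get(key, env)
    seen <- seen[names(seen) %in% names(cnt)]
    cnt[names(seen)] <- seen
  }
  g <- object$gamma
  p <- (cnt + g) / (sum(cnt) + g * length(cnt))
  p
}

#' Per-tone information content of a sequence under an n-gram model
#'
#' IC of tone i is `log2(1 / p(e_i | context_i))` in bits: the minimum number
#' of bits required to encode the tone given its melodic context. Contexts
#' are truncated at the sequence start.
#'
#' @param model an `ngram_model`.
#' @param seq a `tone_sequence` or integer vector of pitches.
#' @return numeric vector of per-tone IC values (bits, >= 0).
#' @export
information_content <- function(model, seq) {
  pitches <- if (inherits(seq, "tone_sequence")) seq$pitches else
    as.integer(seq)
  .assert(length(pitches) > 0, "sequence must be non-empty",
          "invalid_sequence")
  .assert(all(pitches %in% model$alphabet),
          "sequence contains events outside the model alphabet",
          "invalid_sequence")
  vapply(seq_along(pitches), function(i) {
    ctx <- pitches[seq_len(i - 1L)]
    p <- predict(model, ctx)[[as.character(pitches[i])]]
    log2(1 / p)
  }, numeric(1))
}

#' Entropy of the next-event distribution given a context
#'
#' The expected information content over the alphabet:
#' `H(ctx) = sum_e p(e|ctx) * log2(1 / p(e|ctx))` in bits. H is 0 when one
#' continuation has probability one (maximum certainty) and `log2(|A|)` under
#' a uniform distribution (maximum uncertainty).
#'
#' @param model an `ngram_model`.
#' @param context integer vector of preceding events (longer contexts are
#'   truncated to the last `order` events).
#' @return entropy in bits.
#' @export
entropy <- function(model, context = integer(0)) {
  p <- predict(model, context)
  sum(p * log2(1 / p))
}

#' Predictability profile of a sequence
#'
#' Per-tone information content and per-context entropy under a model.
#'
#' @param model an `ngram_model`.
#' @param seq a `tone_sequence` or integer pitch vector.
#' @return list with components `ic` and `h` (numeric vectors, bits), class
#'   `predictability_profile`.
#' @export
predictability_profile <- function(model, seq) {
  pitches <- if (inherits(seq, "tone_sequence")) seq$pitches else
    as.integer(seq)
  ic <- information_content(model, pitches)
  h <- vapply(seq_along(pitches), function(i) {
    entropy(model, pitches[seq_len(i - 1L)])
  }, numeric(1))
  structure(list(ic = ic, h = h), class = "predictability_profile")
}

#' Paired comparison of two predictability profiles
#'
#' Standard paired-samples t-test on element-wise differences of aligned
#' per-tone values (IC or H).
#'
#' @param a,b numeric vectors (or `predictability_profile` objects, compared
#'   on `ic`) aligned element-wise.
#' @param measure which component to compare when profiles are given.
#' @return list with `t`, `df`, `p`, `mean_diff` and `degenerate` (TRUE when
#'   the differences have zero variance).
#' @export
compare_predictability <- function(a, b, measure = c("ic", "h")) {
  measure <- match.arg(measure)
  if (inherits(a, "predictability_profile")) a <- a[[measure]]
  if (inherits(b, "predictability_profile")) b <- b[[measure]]
  .assert(length(a) == length(b),
          "profiles must be aligned element-wise", "misaligned_profiles")
  .assert(length(a) >= 2, "need at least 2 paired values",
          "too_few_observations")
  d <- a - b
  if (sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1L, p = 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Toy training corpus of diatonic random walks
#'
#' Generates simple melodies as random walks on the C-major scale, a small
#' stand-in corpus so information content and entropy are computable offline.
#'
#' @param n_pieces number of melodies.
#' @param length_tones tones per melody.
#' @param seed RNG seed.
#' @return list of `tone_sequence` objects.
#' @export
toy_corpus <- function(n_pieces = 20L, length_tones = 60L, seed = 1L) {
  scale_pcs <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  scale <- sort(as.vector(outer(scale_pcs, 12L * (4:6), `+`)))  # C3..B5
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_pieces), function(i) {
      pos <- match(60L, scale)
      steps <- sample(c(-3:-1, 0:3), length_tones - 1L, replace = TRUE,
                      prob = c(0.08, 0.15, 0.22, 0.10, 0.22, 0.15, 0.08))
      idx <- pos + cumsum(c(0L, steps))
      idx <- pmin(pmax(idx, 1L), length(scale))
      tone_sequence(scale[idx])
    })
  })
}
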