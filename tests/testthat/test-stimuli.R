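# MIDI: C4 = 60, E4 = 64, G4 = 67, C#4 = 61, F#4 = 66, F4 = 65

test_that("atonal transform applies the example pitch-class map and round-trips", {
  seq <- tone_sequence(c(60L, 64L, 67L), role = "piece")
  out <- make_atonal(seq, preset_pitch_map())
  expect_identical(out$pitches, c(61L, 66L, 65L))
  expect_identical(out$piece_class, "atonal")
  expect_identical(out$tone_duration_ms, seq$tone_duration_ms)
  back <- make_atonal(out, invert_pitch_map(preset_pitch_map()))
  expect_identical(back$pitches, seq$pitches)
  expect_identical(back$piece_class, "tonal")
})

test_that("atonal transform preserves positional recurrence structure", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      pcs <- sample(0:11, sample(3:7, 1))
      pitches <- 60L + sample(pcs, 24, replace = TRUE)
      map <- random_pitch_map(pcs, seed = rep)
      out <- make_atonal(tone_sequence(pitches), map)
      expect_length(out$pitches, 24)
      # equal-pitch positions stay equal, unequal stay unequal
      expect_identical(outer(pitches, pitches, `==`),
                       outer(out$pitches, out$pitches, `==`))
    }
  })
})

test_that("invalid and incomplete maps are rejected with typed errors", {
  expect_error(pitch_map(c("0" = 4L)), class = "invalid_map")
  expect_error(pitch_map(c("0" = 0L)), class = "invalid_map")
  # non-injective: both classes displaced onto the same target
  expect_error(pitch_map(c("0" = 2L, "1" = 1L)), class = "invalid_map")
  seq <- tone_sequence(c(60L, 62L))
  expect_error(make_atonal(seq, preset_pitch_map()),
               class = "mapping_incomplete")
})

test_that("n-gram probabilities match hand counts with additive smoothing", {
  # corpus "C C C C": count(C|C) = 3, gamma -> 0 gives p(C|C) -> 1
  m <- train_ngram(list(c(60L, 60L, 60L, 60L)), order = 1, gamma = 1e-9)
  expect_equal(unname(predict(m, 60L)["60"]), 1, tolerance = 1e-6)

  # corpus "C D C D", order 1, gamma = 1, |A| = 2:
  # p(D|C) = (2 + 1) / (2 + 2) = 0.75
  m2 <- train_ngram(list(c(60L, 62L, 60L, 62L)), order = 1, gamma = 1)
  expect_equal(unname(predict(m2, 60L)["62"]), 0.75)
  expect_equal(unname(predict(m2, 60L)["60"]), 0.25)
  # IC of D after C = log2(1/0.75)
  expect_equal(information_content(m2, c(60L, 62L))[2], log2(1 / 0.75))

  # unseen context: smoothed-uniform over the alphabet
  m3 <- train_ngram(list(60:71), order = 2, gamma = 0.5)
  p <- predict(m3, c(71L, 60L))   # context never observed
  expect_equal(unname(p), rep(1 / 12, 12))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("training validates inputs", {
  expect_error(train_ngram(list(), order = 1), class = "empty_corpus")
  expect_error(train_ngram(list(c(60L)), order = 1, gamma = 0),
               class = "invalid_model")
})

test_that("information content follows the closed form and is non-negative", {
  m <- train_ngram(list(c(60L, 62L, 60L, 62L)), order = 1, gamma = 1)
  # p = 1 -> 0 bits; p = 0.5 -> 1 bit; p = 0.25 -> 2 bits
  expect_equal(log2(1 / 1), 0)
  expect_equal(log2(1 / 0.5), 1)
  expect_equal(log2(1 / 0.25), 2)
  withr::with_seed(11, {
    for (i in 1:20) {
      seq <- sample(c(60L, 62L), 8, replace = TRUE)
      expect_true(all(information_content(m, seq) >= 0))
    }
  })
})

test_that("entropy matches its definition, bounds and degenerate cases", {
  # uniform over |A| = 4 -> 2 bits
  m <- train_ngram(list(c(60L, 62L, 64L, 65L)), order = 1, gamma = 1e6)
  expect_equal(entropy(m, 60L), 2, tolerance = 1e-9)
  # single continuation with probability ~1 -> ~0 bits
  m0 <- train_ngram(list(rep(60L, 30)), order = 1, gamma = 1e-12,
                    alphabet = c(60L, 62L, 64L))
  expect_lt(entropy(m0, 60L), 1e-8)
  # brute-force identity H = sum p * log2(1/p) on random models
  withr::with_seed(7, {
    for (i in 1:50) {
      alpha <- sort(sample(40:80, sample(2:8, 1)))
      corpus <- lapply(1:3, function(j)
        sample(alpha, sample(5:20, 1), replace = TRUE))
      m <- train_ngram(corpus, order = sample(0:2, 1), gamma = runif(1, 0.01, 2))
      ctx <- sample(alpha, sample(0:2, 1))
      p <- predict(m, ctx)
      href <- 0
      for (e in names(p)) href <- href + p[[e]] * log2(1 / p[[e]])
      expect_equal(entropy(m, ctx), href, tolerance = 1e-12)
      expect_gte(entropy(m, ctx), 0)
      expect_lte(entropy(m, ctx), log2(length(alpha)) + 1e-12)
    }
  })
})

test_that("IC decreases strictly as probability increases", {
  p <- seq(0.05, 1, by = 0.05)
  ic <- log2(1 / p)
  expect_true(all(diff(ic) < 0))
})

test_that("paired comparison of profiles matches the closed-form t", {
  # differences (1, 2, 3): t = mean / (sd / sqrt(3)) = 2 / (1 / sqrt(3))
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  res <- compare_predictability(a, b)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_false(res$degenerate)

  ident <- compare_predictability(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  const <- compare_predictability(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_true(is.finite(const$p))

  expect_error(compare_predictability(1, 2), class = "too_few_observations")
  expect_error(compare_predictability(1:3, 1:4), class = "misaligned_profiles")
})

test_that("profiles, toy corpus and JSON round trip work end to end", {
  corpus <- toy_corpus(n_pieces = 5, length_tones = 30, seed = 2)
  expect_length(corpus, 5)
  m <- train_ngram(corpus, order = 2, gamma = 1)
  prof <- predictability_profile(m, corpus[[1]])
  expect_length(prof$ic, 30)
  expect_length(prof$h, 30)
  expect_true(all(prof$ic >= 0) && all(prof$h >= 0))
  path <- tempfile(fileext = ".json")
  write_sequences(corpus[1:2], path)
  back <- read_sequences(path)
  expect_identical(back[[1]]$pitches, corpus[[1]]$pitches)
  expect_identical(back[[2]]$role, corpus[[2]]$role)
})

test_that("excerpt sequences must have exactly five tones", {
  expect_error(tone_sequence(60:65, role = "memorized_excerpt"),
               class = "invalid_sequence")
  expect_silent(tone_sequence(60:64, role = "novel_excerpt"))
})
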