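test_that("sensor array geometry: counts, shell radius, injective layout", {
  sa <- make_sensor_array(102)
  expect_equal(nrow(sa), 306)
  expect_equal(sum(sa$type == "planar_gradiometer"), 204)
  expect_equal(sum(sa$type == "magnetometer"), 102)
  r <- sqrt(sa$x^2 + sa$y^2 + sa$z^2)
  expect_equal(r, rep(attr(sa, "sensor_shell_radius"), nrow(sa)),
               tolerance = 1e-12)
  # one layout cell per site
  sites <- unique(sa[, c("site", "layout_row", "layout_col")])
  expect_false(anyDuplicated(sites[, c("layout_row", "layout_col")]) > 0)
  # gradiometer pairs share position, orthogonal tangential orientations
  g <- sa[sa$type == "planar_gradiometer", ]
  for (id in unique(g$pair_id)[1:10]) {
    pr <- g[g$pair_id == id, ]
    expect_equal(pr$x[1], pr$x[2])
    expect_lt(abs(sum(pr[1, c("ox", "oy", "oz")] * pr[2, c("ox", "oy", "oz")])),
              1e-9)
  }
  expect_error(make_sensor_array(3), class = "invalid_geometry")
  expect_error(make_sensor_array(16, head_radius = 0.1,
                                 sensor_shell_radius = 0.09),
               class = "invalid_geometry")
})

test_that("source grid matches brute-force lattice enumeration", {
  spacing <- 0.008; radius <- 0.08
  g <- make_source_grid(spacing, radius)
  # independent triple loop
  cnt <- 0L
  k <- floor(radius / spacing)
  for (ix in -k:k) for (iy in -k:k) for (iz in -k:k) {
    if (sqrt(ix^2 + iy^2 + iz^2) * spacing < radius) cnt <- cnt + 1L
  }
  expect_equal(nrow(g), cnt)
  expect_true(all(sqrt(g$x^2 + g$y^2 + g$z^2) < radius))
  # degenerate spacing: at least the origin
  expect_gte(nrow(make_source_grid(0.2, 0.05)), 1)
  # single all-covering patch labels everything
  g1 <- make_source_grid(0.02, 0.05,
                         list(all = list(center = c(0, 0, 0), radius = 1)))
  expect_true(all(g1$roi == "all"))
})

test_that("lead field obeys superposition, radial silence and depth ordering", {
  sens <- tiny_sensors()
  grid <- tiny_grid(roi = FALSE)
  lf <- compute_lead_field(grid, sens)
  d <- which.min(abs(sqrt(grid$x^2 + grid$y^2 + grid$z^2) - 0.06))
  # linearity: doubling the moment doubles every reading
  m1 <- project_sources(lf, d, matrix(c(1e-8, 0), 1), rep(1, 3))
  m2 <- project_sources(lf, d, matrix(c(2e-8, 0), 1), rep(1, 3))
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # radial dipole: external field vanishes
  rq <- as.numeric(grid[d, c("x", "y", "z")])
  radm <- rq / sqrt(sum(rq^2))
  pts <- as.matrix(sens[sens$type == "magnetometer", c("x", "y", "z")])
  Brad <- megseqmem:::.dipole_field(rq, radm * 1e-8, pts)
  fr <- megseqmem:::.tangent_frame(rq)
  Btan <- megseqmem:::.dipole_field(rq, fr$t1 * 1e-8, pts)
  expect_lt(max(abs(Brad)), 1e-6 * max(abs(Btan)))
  # deep dipole weaker than shallow at equal moment
  dd <- which.min(abs(sqrt(grid$x^2 + grid$y^2 + grid$z^2) - 0.02))
  ds <- which.min(abs(sqrt(grid$x^2 + grid$y^2 + grid$z^2) - 0.06))
  expect_lt(max(abs(lf[, dd, ])), max(abs(lf[, ds, ])))
})

test_that("subject simulation is reproducible and noiseless data is pure projection", {
  sens <- tiny_sensors()
  grid <- tiny_grid()
  lf <- compute_lead_field(grid, sens)
  gt <- default_ground_truth()
  cfg <- cohort_config(n_subjects = 1, seed = 5)
  s1 <- simulate_subject(gt, cfg, lf, 99L, 1)
  s2 <- simulate_subject(gt, cfg, lf, 99L, 1)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$behavior, s2$behavior)
  expect_equal(nrow(s1$recording$events), 160)
  expect_equal(sort(unique(s1$recording$events$condition)),
               sort(c("memorized_tonal", "novel_tonal",
                      "memorized_atonal", "novel_atonal")))

  cfg0 <- cohort_config(n_subjects = 1, seed = 5, noise_sd_mag = 0,
                        noise_sd_grad = 0, background_amp = 0,
                        n_background_dipoles = 0)
  s0 <- simulate_subject(gt, cfg0, lf, 99L, 1)
  # between trials (before the first onset) the sensors are exactly zero
  pre <- s0$recording$data[, 1:50]
  expect_true(all(pre == 0))
  # during trials the projected signal is nonzero
  on <- s0$recording$events$sample[1]
  expect_gt(max(abs(s0$recording$data[, on + 10:100])), 0)
})

test_that("cohort simulation: distinct seeds and calibrated accuracy means", {
  sens <- tiny_sensors(8)
  grid <- tiny_grid(spacing = 0.04)
  lf <- compute_lead_field(grid, sens)
  cfg <- cohort_config(n_subjects = 71, seed = 11, background_amp = 0,
                       n_background_dipoles = 0, noise_sd_mag = 0,
                       noise_sd_grad = 0)
  gt <- ground_truth(list())  # behavioral-only cohort
  co <- simulate_cohort(cfg, gt, lf)
  expect_false(anyDuplicated(co$seeds) > 0)
  expect_equal(nrow(co$behavior), 71 * 4)
  # condition means within 3 SE of configured targets (overdispersed binomial)
  for (cc in names(cfg$accuracy_mean)) {
    x <- co$behavior$n_correct[co$behavior$condition == cc]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$accuracy_mean[[cc]]), 3 * se + 1e-9)
  }
  expect_true(all(co$familiarity >= 1 & co$familiarity <= 7))
})

test_that("simulated accuracy ordering puts memorized-atonal lowest in most cohorts", {
  sens <- tiny_sensors(8)
  grid <- tiny_grid(spacing = 0.04)
  lf <- compute_lead_field(grid, sens)
  gt <- ground_truth(list())
  hits <- 0
  for (s in 1:20) {
    cfg <- cohort_config(n_subjects = 25, seed = s, background_amp = 0,
                         n_background_dipoles = 0, noise_sd_mag = 0,
                         noise_sd_grad = 0)
    co <- simulate_cohort(cfg, gt, lf)
    m <- tapply(co$behavior$n_correct, co$behavior$condition, mean)
    if (names(which.min(m)) == "memorized_atonal") hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("recording round-trips through the binary+sidecar format", {
  sens <- tiny_sensors(8)
  grid <- tiny_grid(spacing = 0.04)
  lf <- compute_lead_field(grid, sens)
  cfg <- cohort_config(n_subjects = 1, seed = 3)
  s <- simulate_subject(default_ground_truth(), cfg, lf, 17L, 4)
  stem <- tempfile()
  write_recording(s$recording, stem)
  back <- read_recording(stem)
  expect_equal(back$data, s$recording$data, tolerance = 0)
  expect_equal(back$fs, s$recording$fs)
  expect_equal(nrow(back$events), nrow(s$recording$events))
  expect_equal(back$events$condition, s$recording$events$condition)
})
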