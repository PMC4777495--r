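test_that("generators are deterministic given a seed", {
  cfg <- motion_config(n_segments = 8, jitter_sd = 1, seed = 42)
  expect_identical(generate_trace(cfg), generate_trace(cfg))
  expect_identical(
    generate_stickfigure_series(cfg),
    generate_stickfigure_series(cfg)
  )
  feats <- tibble::tibble(stimulus_id = letters[1:10], value = 1:10)
  rc <- rater_config(n_raters = 5, seed = 9)
  expect_identical(generate_ratings(feats, rc), generate_ratings(feats, rc))
  cc <- choice_config(n_trials = 40, sensitivity = 2, seed = 3)
  low <- tibble::tibble(stimulus_id = c("a", "b"), value = c(1, 2))
  high <- tibble::tibble(stimulus_id = c("y", "z"), value = c(9, 10))
  expect_identical(
    simulate_forced_choice(low, high, cc),
    simulate_forced_choice(low, high, cc)
  )
  # a generator call leaves the caller's RNG stream untouched
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(generate_trace(cfg))
  expect_identical(rnorm(1), before)
})

test_that("forced reversals are recovered exactly as planted maxima", {
  cfg <- motion_config(
    n_segments = 3, heading_mean = 180, heading_kappa = Inf,
    jitter_sd = 0, seed = 12
  )
  tr <- generate_trace(cfg)
  seg <- segment_maxima(tr)
  expect_equal(count_maxima(seg), 3)
  expect_equal(average_turn_angle(turning_angles(seg, tr)), 180, tolerance = 1e-6)
})

test_that("planted per-segment velocities are recovered to numerical precision", {
  for (seed in 1:5) {
    cfg <- motion_config(n_segments = 30, jitter_sd = 0, seed = seed)
    tr <- generate_trace(cfg)
    pl <- attr(tr, "planted")
    seg <- segment_maxima(tr)
    expect_equal(count_maxima(seg), pl$n_segments)
    expect_equal(seg$max_frame, pl$corner_frames)
    expect_equal(segment_velocity(seg), pl$velocity, tolerance = 1e-9)
    expect_equal(average_velocity(seg), mean(pl$velocity), tolerance = 1e-9)
  }
})

test_that("planted heading-change distribution is recovered by the pipeline", {
  errs <- vapply(1:5, function(seed) {
    cfg <- motion_config(
      n_segments = 200, heading_mean = 60, heading_kappa = 50,
      duration_sd = 0, jitter_sd = 0, seed = seed
    )
    tr <- generate_trace(cfg)
    seg <- segment_maxima(tr)
    average_turn_angle(turning_angles(seg, tr)) - 60
  }, numeric(1))
  expect_true(all(abs(errs) < 5))
})

test_that("stick figures plant static angularity exactly", {
  # constant 90-degree elbows, straight shoulders: 180 degrees total
  s <- generate_stickfigure_series(NULL,
    n_frames = 12,
    flexion_mean = 90, flexion_amplitude = 0,
    shoulder_mean = 0, shoulder_amplitude = 0
  )
  expect_equal(average_bodypart_angle(s), 180)

  # zero flexion everywhere: fully extended, zero angularity
  s0 <- generate_stickfigure_series(NULL,
    n_frames = 12,
    flexion_mean = 0, flexion_amplitude = 0,
    shoulder_mean = 0, shoulder_amplitude = 0
  )
  expect_equal(average_bodypart_angle(s0), 0)

  # oscillating joints: measured per-frame sums equal the planted schedule
  s_osc <- generate_stickfigure_series(NULL, n_frames = 30)
  pf <- bodypart_angles(s_osc)
  expect_equal(pf$total, attr(s_osc, "planted_bodypart"), tolerance = 1e-8)
})

test_that("rating panels carry the planted feature correlation", {
  feats <- tibble::tibble(stimulus_id = sprintf("s%02d", 1:30), value = rnorm(30))
  # deterministic map at loading 1, noise 0
  r1 <- generate_ratings(feats, rater_config(
    n_raters = 4, loading = 1,
    noise_sd = 0, rating_sd = 20, seed = 2
  ))
  m1 <- mean_ratings(r1)
  joined <- dplyr::inner_join(m1, feats, by = "stimulus_id")
  expect_equal(cor(joined$mean_rating, joined$value), 1)
  expect_true(all(abs(r1$value) <= 100))

  # loading 0 panels decorrelate on average
  set.seed(88)
  feats60 <- tibble::tibble(stimulus_id = sprintf("s%02d", 1:60), value = rnorm(60))
  rs <- vapply(1:100, function(seed) {
    r <- generate_ratings(feats60, rater_config(
      n_raters = 10, loading = 0,
      noise_sd = 10, seed = seed
    ))
    j <- dplyr::inner_join(mean_ratings(r), feats60, by = "stimulus_id")
    cor(j$mean_rating, j$value)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  expect_error(
    generate_ratings(feats[1:2, ], rater_config()),
    class = "angulate_data_error"
  )
  expect_error(
    generate_ratings(dplyr::mutate(feats, value = 1), rater_config()),
    class = "angulate_data_error"
  )
})

test_that("forced-choice simulation spans guessing to determinism", {
  low <- tibble::tibble(stimulus_id = sprintf("lo%d", 1:10), value = rnorm(10, 2))
  high <- tibble::tibble(stimulus_id = sprintf("hi%d", 1:10), value = rnorm(10, 20))

  guess <- simulate_forced_choice(low, high, choice_config(460, sensitivity = 0, seed = 4))
  ch <- dplyr::filter(analyze_choices(guess), condition == "overall")
  chance_band <- binomial_exact(230, 460) # Clopper-Pearson band around 0.5
  expect_gte(ch$p_hat, chance_band$ci_low)
  expect_lte(ch$p_hat, chance_band$ci_high)

  sharp <- simulate_forced_choice(low, high, choice_config(200, sensitivity = 1e6, seed = 5))
  expect_true(all(sharp$correct))
  expect_true(all(sharp$word %in% c("takete", "maluma")))
  # chosen stimulus is consistent with word and correctness
  with_takete <- dplyr::filter(sharp, word == "takete")
  expect_true(all(with_takete$chosen == with_takete$high_stimulus))
})
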