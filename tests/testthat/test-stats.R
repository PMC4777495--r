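test_that("mean ratings average across raters per stimulus and scale", {
  r <- tibble::tibble(
    rater_id = rep(c("r1", "r2", "r3"), each = 2),
    stimulus_id = rep(c("s1", "s2"), 3),
    scale = "takete_maluma",
    value = c(10, -20, 30, -40, 50, -60)
  )
  m <- mean_ratings(r)
  expect_equal(m$mean_rating[m$stimulus_id == "s1"], 30)
  expect_equal(m$mean_rating[m$stimulus_id == "s2"], -40)

  # single rater: means equal that rater's scores
  one <- dplyr::filter(r, rater_id == "r1")
  expect_equal(mean_ratings(one)$mean_rating, one$value)

  # symmetric pair cancels
  pair <- tibble::tibble(
    rater_id = c("a", "b"), stimulus_id = "s",
    value = c(100, -100)
  )
  expect_equal(mean_ratings(pair)$mean_rating, 0)
  expect_error(mean_ratings(pair[0, ]), class = "angulate_data_error")
})

test_that("pearson_ci matches cor.test and handles perfect correlation", {
  expect_equal(pearson_ci(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_ci(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson_ci(c(1, 2, 3), c(2, 4, 6))$p, 0)

  set.seed(33)
  x <- rnorm(20)
  y <- 0.6 * x + rnorm(20)
  fit <- pearson_ci(x, y)
  ref <- cor.test(x, y)
  expect_equal(fit$r, unname(ref$estimate))
  expect_equal(fit$p, ref$p.value)
  expect_equal(c(fit$ci_low, fit$ci_high), as.numeric(ref$conf.int))
  expect_equal(fit$df, unname(ref$parameter))
  # textbook covariance-formula cross-check
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit$r, r_direct)
  td <- tidy(fit)
  expect_equal(td$r, fit$r)
  expect_equal(glance(fit)$n, 20)

  expect_error(pearson_ci(rep(1, 5), rnorm(5)), class = "angulate_data_error")
  expect_error(pearson_ci(1:4, 1:5), class = "angulate_parameter_error")
})

test_that("pearson_ci is symmetric and equivariant under affine maps", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    a <- pearson_ci(x, y)
    expect_equal(pearson_ci(y, x)$r, a$r)
    expect_equal(pearson_ci(2 * x + 3, y)$r, a$r)
    flipped <- pearson_ci(-2 * x + 1, y)
    expect_equal(flipped$r, -a$r)
    expect_equal(flipped$p, a$p)
  }
})

test_that("average-measure ICC reproduces the worked two-way ANOVA fixture", {
  m <- matrix(
    c(
      9, 2, 5, 8,
      6, 1, 3, 2,
      8, 4, 6, 8,
      7, 1, 2, 6,
      10, 5, 6, 9,
      6, 2, 4, 7
    ),
    nrow = 6, byrow = TRUE
  )
  # mean squares agree with aov() on the long layout
  long <- data.frame(
    y = as.vector(m),
    target = factor(rep(1:6, 4)),
    rater = factor(rep(1:4, each = 6))
  )
  ms <- anova(stats::aov(y ~ target + rater, data = long))["Mean Sq"]
  fit2 <- icc_average(m, "ICC2k")
  fit3 <- icc_average(m, "ICC3k")
  expect_equal(glance(fit2)$ms_targets, ms["target", 1])
  expect_equal(glance(fit2)$ms_raters, ms["rater", 1])
  expect_equal(glance(fit2)$ms_residual, ms["Residuals", 1])

  # frozen reference values for this fixture (independent implementation)
  expect_equal(fit2$icc, 0.6200505, tolerance = 1e-6)
  expect_lt(abs(fit2$ci_low - 0.07), 0.005)
  expect_lt(abs(fit2$ci_high - 0.93), 0.005)
  expect_equal(fit3$icc, 0.9093155, tolerance = 1e-6)
  expect_lt(abs(fit3$ci_low - 0.68), 0.005)
  expect_lt(abs(fit3$ci_high - 0.99), 0.005)

  # consistency form ignores rater offsets, agreement form does not
  expect_gt(fit3$icc, fit2$icc)
})

test_that("ICC hits its boundaries: 1 under perfect agreement, ~0 for noise", {
  targets <- c(1, 4, 9, 2, 7, 5)
  perfect <- matrix(rep(targets, 4), ncol = 4)
  expect_equal(icc_average(perfect, "ICC2k")$icc, 1)
  expect_equal(icc_average(perfect, "ICC3k")$icc, 1)
  expect_true(icc_average(perfect, "ICC2k")$ci_high <= 1)

  # rater offsets leave consistency at 1 but drag agreement below it
  offset <- perfect + matrix(rep(c(0, 5, -3, 2), each = 6), ncol = 4)
  expect_equal(icc_average(offset, "ICC3k")$icc, 1)
  expect_lt(icc_average(offset, "ICC2k")$icc, 1)

  set.seed(55)
  iccs <- replicate(1000, {
    icc_average(matrix(rnorm(50 * 10), 50, 10), "ICC2k")$icc
  })
  expect_lt(abs(mean(iccs)), 0.05)

  expect_error(
    icc_average(matrix(c(1, NA, 2, 3), 2, 2)),
    class = "angulate_data_error"
  )
})

test_that("exact binomial test matches direct mass summation and binom.test", {
  fit <- binomial_exact(5, 10)
  expect_equal(fit$p_value, sum(choose(10, 5:10) * 0.5^10))
  expect_equal(fit$p_value, 0.623046875)
  expect_equal(binomial_exact(10, 10)$p_value, 2^-10)

  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:400, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.1, 0.9)
    fit <- binomial_exact(k, n, p0)
    ref <- binom.test(k, n, p0, alternative = "greater")
    ref2 <- binom.test(k, n, p0)
    expect_equal(fit$p_value, ref$p.value)
    expect_equal(c(fit$ci_low, fit$ci_high), as.numeric(ref2$conf.int))
  }

  # p-value is monotone decreasing in k at fixed n
  ps <- vapply(0:20, function(k) binomial_exact(k, 20)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(binomial_exact(11, 10), class = "angulate_parameter_error")
  expect_error(binomial_exact(5, 10, p0 = 1), class = "angulate_parameter_error")
})

test_that("extreme-group selection ranks deterministically with tie-breaks", {
  f <- tibble::tibble(
    stimulus_id = sprintf("s%02d", 1:60),
    avg_velocity = as.numeric(1:60)
  )
  sel <- select_extremes(f, k = 10)
  expect_equal(
    dplyr::filter(sel, group == "low")$stimulus_id,
    sprintf("s%02d", 1:10)
  )
  expect_equal(
    sort(dplyr::filter(sel, group == "high")$stimulus_id),
    sprintf("s%02d", 51:60)
  )

  # k = n/2 partitions all stimuli
  sel_half <- select_extremes(f, k = 30)
  expect_setequal(sel_half$stimulus_id, f$stimulus_id)

  # all-tied fixture: lexicographically smallest ids win the low tail,
  # the high tail is filled from the remainder, smallest id first
  tie <- tibble::tibble(stimulus_id = c("e", "c", "a", "d", "b"), avg_velocity = 7)
  sel_tie <- select_extremes(tie, k = 2)
  expect_equal(dplyr::filter(sel_tie, group == "low")$stimulus_id, c("a", "b"))
  expect_equal(dplyr::filter(sel_tie, group == "high")$stimulus_id, c("c", "d"))

  expect_error(select_extremes(f, k = 31), class = "angulate_parameter_error")
  f$avg_velocity[1:50] <- NA
  expect_error(select_extremes(f, k = 10), class = "angulate_parameter_error")
})

test_that("forced-choice analysis stratifies by word and adds up", {
  trials <- tibble::tibble(
    word = rep(c("takete", "maluma"), c(246, 214)),
    correct = c(
      rep(c(TRUE, FALSE), c(178, 246 - 178)),
      rep(c(TRUE, FALSE), c(148, 214 - 148))
    )
  )
  ch <- analyze_choices(trials)
  overall <- dplyr::filter(ch, condition == "overall")
  expect_equal(overall$k, 326)
  expect_equal(overall$n, 460)
  expect_equal(overall$k, sum(dplyr::filter(ch, condition != "overall")$k))
  expect_equal(overall$n, sum(dplyr::filter(ch, condition != "overall")$n))

  all_right <- tibble::tibble(word = rep(c("takete", "maluma"), 5), correct = TRUE)
  expect_true(all(analyze_choices(all_right)$p_hat == 1))
  expect_error(analyze_choices(all_right[0, ]), class = "angulate_data_error")
})

test_that("analyze_choices recovers a 0.7-accurate observer across replicates", {
  set.seed(77)
  p_hats <- replicate(500, {
    trials <- tibble::tibble(
      word = sample(c("takete", "maluma"), 460, replace = TRUE),
      correct = runif(460) < 0.7
    )
    dplyr::filter(analyze_choices(trials), condition == "overall")$p_hat
  })
  expect_lt(abs(mean(p_hats) - 0.7), 0.01)
})
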