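test_that("population activity conserves mass and localizes single events", {
  z <- matrix(0L, 200, 4)
  expect_true(all(population_activity(z, 7)$values == 0))

  m <- matrix(0L, 200, 4)
  m[50, ] <- 1L
  act <- population_activity(m, 7)
  expect_equal(sum(act$values), 1, tolerance = 0.01) # 1 spike/cell
  expect_equal(which.max(act$values), 50)

  set.seed(2)
  r <- matrix(rpois(200 * 5, 0.3), 200, 5)
  act2 <- population_activity(r, 7)
  expect_lt(abs(sum(act2$values) - sum(r) / 5) / (sum(r) / 5), 0.01)

  expect_error(population_activity(m[, 1, drop = FALSE], 7), ">= 2 cells")
})

test_that("smoothed activity tracks a square-wave rate profile", {
  set.seed(10)
  fs <- 7
  n <- 4200
  profile <- rep(rep(c(0.01, 0.1), each = 70), 30) # 10 s period square wave
  counts <- vapply(1:30, function(j) rpois(n, profile), numeric(n))
  act <- population_activity(counts, fs, sigma = 0.5)
  expect_gt(cor(act$values, profile), 0.9)
})

test_that("bimodal threshold lands in the valley of a two-mode density", {
  set.seed(42)
  x <- c(stats::rnorm(2000, 2, 1), stats::rnorm(2000, 20, 1))
  res <- compute_state_threshold(x)
  expect_true(res$bimodal)
  expect_gt(res$threshold, 5)
  expect_lt(res$threshold, 15)

  # brute-force valley of the analytic mixture density is near 11;
  # the KDE threshold agrees to within a couple of units
  grid <- seq(2, 20, by = 0.01)
  dens <- 0.5 * stats::dnorm(grid, 2, 1) + 0.5 * stats::dnorm(grid, 20, 1)
  valley <- grid[which.min(dens)]
  expect_lt(abs(res$threshold - valley), 3)
})

test_that("constant or unimodal activity is not bimodal", {
  expect_false(compute_state_threshold(rep(2, 500))$bimodal)
  set.seed(1)
  expect_false(compute_state_threshold(stats::rnorm(2000))$bimodal)
})

test_that("segmentation recovers noiseless alternating states", {
  fs <- 7
  cycle <- c(rep(2, round(10 * fs)), rep(20, round(3 * fs)))
  act <- structure(
    list(values = rep(cycle, 12), frame_rate = fs, sigma = 0),
    class = "population_activity"
  )
  seg <- segment_states(act, 11)
  inner <- seg$states[-c(1, nrow(seg$states)), ]
  expect_lte(max(abs(inner$duration_s[inner$label == "low"] - 10)), 0.5)
  expect_lte(max(abs(inner$duration_s[inner$label == "high"] - 3)), 0.5)
  # states tile the recording exactly
  expect_equal(sum(seg$states$duration_s), length(act$values) / fs)
  # every high-state rate above every low-state rate
  expect_gt(
    min(seg$states$mean_rate_spm[seg$states$label == "high"]),
    max(seg$states$mean_rate_spm[seg$states$label == "low"])
  )
})

test_that("segmentation is invariant to joint rescaling and handles edge cases", {
  fs <- 7
  set.seed(9)
  vals <- abs(stats::rnorm(700, 1, 0.6))
  act <- structure(
    list(values = vals, frame_rate = fs, sigma = 0),
    class = "population_activity"
  )
  seg1 <- segment_states(act, 1)
  act2 <- act
  act2$values <- act$values * 5
  seg2 <- segment_states(act2, 5)
  expect_identical(seg1$frame_labels, seg2$frame_labels)

  # activity entirely below threshold: single low state
  act3 <- structure(
    list(values = rep(0.3, 700) + (1:700) * 1e-6, frame_rate = fs, sigma = 0),
    class = "population_activity"
  )
  seg3 <- segment_states(act3, 0.301)
  expect_equal(nrow(seg3$states), 1)
  expect_equal(seg3$states$label, "low")
  expect_equal(seg3$states$duration_s, 100)

  expect_error(segment_states(act, NA), "finite")
})

test_that("accordance detects state-following cells and rejects rate-matched ones", {
  fs <- 7
  set.seed(31)
  n <- 6000
  state <- rep(rep(c("low", "high"), times = 60),
    times = rep(c(round(12 * fs), round(4 * fs)), 60)
  )[1:n]
  act <- structure(
    list(
      values = ifelse(state == "high", 0.05, 0.005), frame_rate = fs,
      sigma = 0
    ),
    class = "population_activity"
  )
  seg <- segment_states(act, 0.02)
  lam_acc <- ifelse(state == "high", 21 / 420, 1.7 / 420)
  lam_flat <- mean(lam_acc)
  hits_acc <- 0
  hits_flat <- 0
  for (s in 1:20) {
    acc <- cell_accordance(stats::rpois(n, lam_acc), seg)
    flat <- cell_accordance(stats::rpois(n, lam_flat), seg)
    hits_acc <- hits_acc + acc$accordant
    hits_flat <- hits_flat + flat$accordant
  }
  expect_gte(hits_acc, 18) # power ~ >= 0.9
  expect_lte(hits_flat, 2) # type-I controlled at alpha = 0.05

  silent <- cell_accordance(integer(n), seg)
  expect_false(silent$accordant)
})

test_that("population summary aggregates bimodality percentages", {
  seg <- list(
    mean_high_s = 2, mean_low_s = 10, high_rate_spm = 20, low_rate_spm = 2
  )
  pop_bi <- list(bimodal = TRUE, segmentation = seg, accordant = c(TRUE, FALSE))
  pop_no <- list(bimodal = FALSE)
  expect_equal(population_summary(list(pop_bi, pop_bi))$pct_bimodal, 100)
  expect_equal(population_summary(list(pop_no, pop_no))$pct_bimodal, 0)
  s <- population_summary(list(pop_bi, pop_bi, pop_no))
  expect_equal(s$pct_bimodal, 200 / 3, tolerance = 1e-10)
  expect_equal(s$pct_accordant_mean, 50)
  expect_equal(s$high_duration_s_mean, 2)
})
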