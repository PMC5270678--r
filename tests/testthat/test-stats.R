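test_that("identical groups give H = 0, p = 1", {
  res <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
})

test_that("exact permutation p-value matches a brute-force oracle", {
  groups <- list(a = c(1, 2, 3), b = c(101, 102, 103), c = c(201, 202, 203))
  res <- kruskal_wallis(groups) # auto -> exact on 9 observations
  expect_equal(res$method, "exact permutation")

  # oracle: enumerate all assignments of the 9 values to the 3 groups and
  # compute H for each with stats::kruskal.test
  values <- unlist(groups)
  H_obs <- unname(stats::kruskal.test(values, rep(1:3, each = 3))$statistic)
  count <- 0L
  total <- 0L
  for (i in utils::combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(1:9, i)
    for (j in utils::combn(6, 3, simplify = FALSE)) {
      g <- integer(9)
      g[i] <- 1L
      g[rest[j]] <- 2L
      g[g == 0L] <- 3L
      H <- unname(stats::kruskal.test(values, g)$statistic)
      total <- total + 1L
      if (H >= H_obs - 1e-9) count <- count + 1L
    }
  }
  expect_equal(total, 1680L)
  expect_equal(res$p.value, count / total, tolerance = 1e-12)
  # complete separation: only the 3! orderings of the rank blocks reach H_obs
  expect_equal(res$p.value, 6 / 1680, tolerance = 1e-12)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(17)
  groups <- list(
    a = stats::rnorm(8, 0), b = stats::rnorm(8, 1), c = stats::rnorm(8, 0.5)
  )
  r1 <- kruskal_wallis(groups, p_method = "asymptotic")
  r2 <- kruskal_wallis(lapply(groups, function(v) exp(3 * v)), p_method = "asymptotic")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-12)
  expect_equal(r1$posthoc$z, r2$posthoc$z, tolerance = 1e-12)
})

test_that("Dunn-Holm post hoc separates the discrepant pair", {
  set.seed(30)
  groups <- list(
    a = stats::rnorm(15, 0), b = stats::rnorm(15, 0), c = stats::rnorm(15, 3)
  )
  ph <- kruskal_wallis(groups, p_method = "asymptotic")$posthoc
  pick <- function(g1, g2) ph$p_adj[ph$group1 == g1 & ph$group2 == g2]
  expect_lt(pick("a", "c"), 0.01)
  expect_lt(pick("b", "c"), 0.01)
  expect_gt(pick("a", "b"), 0.1)
  # Holm adjustment is monotone and >= raw p
  expect_true(all(ph$p_adj >= ph$p - 1e-15))
})

test_that("Welch ANOVA reduces to classic one-way for equal variances", {
  res <- welch_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1, tolerance = 1e-12)

  g <- list(a = c(1, 2, 3, 4), b = c(11, 12, 13, 14)) # identical variances
  w <- welch_anova(g)
  classic <- stats::oneway.test(
    c(g$a, g$b) ~ rep(c("a", "b"), each = 4),
    var.equal = TRUE
  )
  expect_lt(abs(w$p.value - classic$p.value), 1e-6)

  expect_error(welch_anova(list(a = c(1, 1, 1), b = c(1, 2, 3))), "variance")
  expect_error(welch_anova(list(a = 1, b = c(1, 2))), ">= 2 values")
})

test_that("Welch ANOVA rejects under unequal-variance shifts", {
  set.seed(40)
  hits <- 0
  for (i in 1:50) {
    g <- list(
      a = stats::rnorm(20, 0, 1), b = stats::rnorm(20, 1.5, 3)
    )
    hits <- hits + (welch_anova(g)$p.value < 0.05)
  }
  expect_gte(hits / 50, 0.5)
})

test_that("both tests hold their level under the null", {
  set.seed(50)
  n_sim <- 400
  rej_kw <- rej_w <- 0
  for (i in seq_len(n_sim)) {
    g <- list(
      a = stats::rnorm(12), b = stats::rnorm(12), c = stats::rnorm(12)
    )
    rej_kw <- rej_kw + (kruskal_wallis(g, p_method = "asymptotic")$p.value < 0.05)
    rej_w <- rej_w + (welch_anova(g)$p.value < 0.05)
  }
  expect_gt(rej_kw / n_sim, 0.02)
  expect_lt(rej_kw / n_sim, 0.08)
  expect_gt(rej_w / n_sim, 0.02)
  expect_lt(rej_w / n_sim, 0.08)
})

test_that("summary statistics follow the SEM convention", {
  s <- summarize_values(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$median, 4)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3)
  expect_warning(s1 <- summarize_values(5), "single value")
  expect_equal(s1$sem, 0)
  expect_error(summarize_values(numeric(0)), "empty")

  set.seed(60)
  x <- stats::rnorm(5000, 3, 2)
  s2 <- summarize_values(x)
  expect_lt(abs(s2$mean - 3), 3 * s2$sem)
})

test_that("optical density is decadic", {
  expect_equal(optical_density(10, 10), 0)
  expect_equal(optical_density(10, 100), 1)
  expect_equal(optical_density(50, 100), 0.3010, tolerance = 1e-4)
  expect_error(optical_density(-1, 5), "positive")
  expect_error(optical_density(10, 5), ">= mean")
})
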