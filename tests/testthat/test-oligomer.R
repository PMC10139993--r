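test_that("distributions are normalized tallies of valid nonzero step counts", {
  d <- build_distribution(c(1, 1, 1))
  expect_equal(unname(d$frequencies), 1)
  expect_equal(d$n_traces, 3L)

  d <- build_distribution(c(rep(1, 700), rep(2, 300)))
  expect_equal(unname(d$frequencies), c(0.70, 0.30))

  d <- build_distribution(c(1, 2, 2, 3))
  expect_equal(unname(d$frequencies), c(0.25, 0.5, 0.25))

  # zero-step and invalid traces are excluded via the detection table
  tab <- data.frame(spot_id = letters[1:4], step_count = c(0L, 1L, 2L, 5L),
                    valid = c(TRUE, TRUE, TRUE, FALSE),
                    rejection_reason = c("none", "none", "none", "upward_step"))
  d <- build_distribution(list(table = tab))
  expect_equal(d$n_traces, 2L)
  expect_error(build_distribution(c(0, 0)), "valid traces")
})

test_that("bin-shift correction reproduces the GFP-control arithmetic", {
  gfp <- build_distribution(c(rep(1, 70), rep(2, 30)))
  corr <- correct_gfp_background(gfp, correction_model(0.30))
  expect_equal(unname(corr$frequencies), c(1, 0))

  # clipping: only the available dimer mass is moved
  d <- build_distribution(rep(1:3, c(50, 20, 30)))
  corr <- correct_gfp_background(d, correction_model(0.30))
  expect_equal(unname(corr$frequencies), c(0.70, 0, 0.30))

  # zero fraction and mode "none" are identities
  expect_equal(correct_gfp_background(d, correction_model(0))$frequencies,
               d$frequencies)
  expect_equal(correct_gfp_background(d, correction_model(0.3, "none"))$frequencies,
               d$frequencies)
})

test_that("deconvolution inverts the self-dimer mixing exactly on expected frequencies", {
  D <- c(0.4, 0.3, 0.2, 0.1)
  p <- 0.30
  g <- (1 - p) * c(D, 0) + p * c(0, D)  # g(k) = (1-p) D(k) + p D(k-1)
  obs <- build_distribution(rep(1:5, round(g * 1e4)))
  corr <- correct_gfp_background(obs, correction_model(p, "deconvolve"))
  expect_equal(unname(corr$frequencies), c(D, 0), tolerance = 1e-12)
})

test_that("average step follows the arithmetic chain of the GFP control", {
  expect_equal(average_step(build_distribution(c(1, 1)), n_boot = 0)$average_step, 1.0)
  expect_equal(average_step(build_distribution(c(1, 2)), n_boot = 0)$average_step, 1.5)

  d <- build_distribution(c(rep(1, 70), rep(2, 30)))
  expect_equal(average_step(d, n_boot = 0)$average_step, 1.3)
  corr <- correct_gfp_background(d, correction_model(0.30))
  expect_equal(average_step(corr, n_boot = 0)$average_step, 1.0)
})

test_that("average step increases under rightward mass shifts", {
  lo <- build_distribution(rep(1:3, c(50, 30, 20)))
  hi <- build_distribution(rep(1:3, c(50, 20, 30)))  # mass moved 2 -> 3
  expect_gt(average_step(hi, n_boot = 0)$average_step,
            average_step(lo, n_boot = 0)$average_step)
})

test_that("bootstrap SEM shrinks as 1/sqrt(n)", {
  probs <- c(0.5, 0.3, 0.2)
  sems <- vapply(c(250, 1000, 4000), function(n) {
    steps <- rep(1:3, round(probs * n))
    average_step(build_distribution(steps), n_boot = 400, seed = 17)$sem
  }, 0)
  expect_true(all(diff(sems) < 0))
  ratios <- sems[-3] / sems[-1]
  expect_true(all(ratios > 1.4 & ratios < 2.9))  # ideal: 2
})

test_that("dissolution differences are per-bin and conserve mass", {
  b <- build_distribution(rep(1:2, c(40, 60)))
  a <- build_distribution(rep(1:2, c(90, 10)))
  d <- dissolution_difference(b, a)
  expect_equal(d$diff, c(0.5, -0.5))
  expect_equal(sum(d$diff), 0, tolerance = 1e-9)

  same <- dissolution_difference(b, b)
  expect_true(all(same$diff == 0))

  # unequal bin ranges are zero-filled
  a3 <- build_distribution(rep(1:3, c(30, 30, 40)))
  d <- dissolution_difference(b, a3)
  expect_equal(nrow(d), 3)
  expect_equal(sum(d$diff), 0, tolerance = 1e-9)

  # bootstrap CIs bracket the point estimate
  dci <- dissolution_difference(b, a, n_boot = 200, seed = 4)
  expect_true(all(dci$ci_lo <= dci$diff & dci$diff <= dci$ci_hi))

  broken <- b
  broken$frequencies <- broken$frequencies * 0.9
  expect_error(dissolution_difference(broken, a), "normalized")
})

test_that("condition comparisons use the standard tests", {
  # identical groups: t statistic 0, p = 1
  g <- c(1, 2, 2, 3, 1, 2)
  res <- compare_conditions(c(g, g), rep(c("a", "b"), each = 6))
  expect_equal(res$method, "two-sample t-test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # well-separated groups at n = 500: overwhelming evidence
  set.seed(12)
  y <- c(rnorm(500, 1.5, 0.8), rnorm(500, 3.0, 0.8))
  res <- compare_conditions(y, rep(c("a", "b"), each = 500))
  expect_lt(res$p_value, 0.001)

  # three groups: one-way ANOVA with adjusted pairwise p-values
  set.seed(13)
  y <- rnorm(90)
  res <- compare_conditions(y, rep(letters[1:3], each = 30))
  expect_equal(res$method, "one-way ANOVA")
  expect_equal(res$p_adjust, "holm")
  expect_false(is.null(res$pairwise))

  # two factors: two-way ANOVA
  res <- compare_conditions(y, rep(letters[1:3], each = 30),
                            stress = rep(c("minus", "plus"), 45))
  expect_equal(res$method, "two-way ANOVA")

  expect_error(compare_conditions(1:5, rep("a", 5)), "two groups")
})

test_that("tail pooling collapses rare high step counts for display", {
  d <- build_distribution(rep(1:8, c(40, 20, 10, 10, 8, 6, 4, 2)))
  pooled <- pool_steps(d, k_max = 6)
  expect_equal(pooled$step, c("1", "2", "3", "4", "5", "6+"))
  expect_equal(sum(pooled$frequency), 1, tolerance = 1e-12)
  expect_equal(pooled$frequency[6], 0.12)
  # no pooling needed when the range is short
  d2 <- build_distribution(c(1, 2, 2))
  expect_equal(pool_steps(d2)$step, c("1", "2"))
})

test_that("probability mass is conserved through every operation", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    steps <- sample(1:k, 300, replace = TRUE, prob = runif(k) + 0.1)
    d <- build_distribution(steps)
    expect_equal(sum(d$frequencies), 1, tolerance = 1e-9)
    for (mode in c("bin_shift", "deconvolve", "none")) {
      cc <- correct_gfp_background(d, correction_model(runif(1, 0, 0.5), mode))
      expect_equal(sum(cc$frequencies), 1, tolerance = 1e-9)
    }
    d2 <- build_distribution(sample(1:k, 200, replace = TRUE))
    expect_equal(sum(dissolution_difference(d, d2)$diff), 0, tolerance = 1e-9)
  }
})
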