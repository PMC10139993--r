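test_that("noiseless traces are non-increasing staircases matching the truth record", {
  phys <- gfp_photophysics(noise_sd = 0, bleach_rate = 0.03)
  for (k in 0:6) {
    tr <- simulate_trace(k, phys, n_frames = 500, seed = 100 + k)
    expect_true(all(diff(tr$intensities) <= 0))
    expect_equal(tr$truth$n_active, k)
    # drops occur exactly at the recorded bleach frames
    drops <- which(diff(tr$intensities) < 0) + 1L
    in_window <- unique(tr$truth$bleach_frames[tr$truth$bleach_frames <= 500])
    expect_equal(drops, in_window)
    # first and last levels bracket the staircase
    expect_equal(tr$intensities[1],
                 phys$background_level + k * phys$unit_intensity)
  }
})

test_that("empty spots give a flat trace at background with zero steps", {
  phys <- gfp_photophysics(noise_sd = 0)
  tr <- simulate_trace(0, phys, n_frames = 50, seed = 1)
  expect_true(all(tr$intensities == phys$background_level))
  expect_equal(detect_steps(tr)$step_count, 0L)
})

test_that("a noiseless 2-fluorophore trace bleaches in unit steps to background", {
  phys <- gfp_photophysics(noise_sd = 0, dark_fraction = 0, bleach_rate = 0.05)
  tr <- simulate_trace(2, phys, n_frames = 400, seed = 11)
  lv <- unique(tr$intensities)
  expect_equal(sort(diff(sort(lv))), rep(phys$unit_intensity, length(lv) - 1))
  expect_equal(min(tr$intensities), phys$background_level)
  expect_equal(detect_steps(tr)$step_count, 2L)
})

test_that("noisy segment means match configured levels around the true bleach frame", {
  phys <- gfp_photophysics(noise_sd = 5, unit_intensity = 100,
                           background_level = 50, bleach_rate = 0.01)
  tr <- simulate_trace(1, phys, n_frames = 600, seed = 21)
  b <- tr$truth$bleach_frames[1]
  expect_true(b > 1 && b <= 600)
  pre <- mean(tr$intensities[1:(b - 1)])
  post <- mean(tr$intensities[b:600])
  expect_lt(abs(pre - 150), 3 * phys$noise_sd)
  expect_lt(abs(post - 50), 3 * phys$noise_sd)
})

test_that("self-dimerization inflates the apparent count by one at the configured rate", {
  phys <- gfp_photophysics(self_dimer_fraction = 0.30)
  pop <- simulate_population(oligomer_spec(c(`1` = 1), n_spots = 4000, seed = 3),
                             phys, n_frames = 10)
  frac2 <- mean(pop$truth$n_fluorophores == 2)
  expect_true(all(pop$truth$n_fluorophores %in% 1:2))
  expect_lt(abs(frac2 - 0.30), 4 * sqrt(0.3 * 0.7 / 4000))

  # with the dimerization switched off, every spot carries one tag
  pop0 <- simulate_population(oligomer_spec(c(`1` = 1), n_spots = 200, seed = 4),
                              gfp_photophysics(self_dimer_fraction = 0),
                              n_frames = 10)
  expect_true(all(pop0$truth$n_fluorophores == 1))
})

test_that("mixed specs have the expected mean fluorophore count", {
  pop <- simulate_population(
    oligomer_spec(c(`1` = 0.5, `3` = 0.5), n_spots = 4000, seed = 5),
    gfp_photophysics(self_dimer_fraction = 0, dark_fraction = 0),
    n_frames = 10)
  expect_lt(abs(mean(pop$truth$n_fluorophores) - 2.0),
            4 * sqrt(1 / 4000))  # per-spot sd = 1 for the 50/50 1-vs-3 mix
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- oligomer_spec(c(`1` = 0.7, `2` = 0.3), n_spots = 30, seed = 9)
  p1 <- simulate_population(spec, n_frames = 50)
  p2 <- simulate_population(spec, n_frames = 50)
  expect_identical(p1, p2)
  p3 <- simulate_population(oligomer_spec(c(`1` = 0.7, `2` = 0.3),
                                          n_spots = 30, seed = 10),
                            n_frames = 50)
  expect_false(identical(p1$traces[[1]]$intensities,
                         p3$traces[[1]]$intensities))
})

test_that("blinking produces upward recoveries that the detector rejects", {
  phys <- gfp_photophysics(noise_sd = 0, bleach_rate = 0.002)
  n_rejected <- 0L
  for (seed in 1:10) {
    tr <- simulate_trace(2, phys, n_frames = 400, seed = seed,
                         blink_rate = 0.02, blink_mean_off = 5)
    if (any(diff(tr$intensities) > 0)) {
      fit <- detect_steps(tr)
      expect_false(fit$valid)
      expect_equal(fit$rejection_reason, "upward_step")
      n_rejected <- n_rejected + 1L
    }
  }
  expect_gt(n_rejected, 0L)  # blinking actually occurred in the batch
})

test_that("invalid parameters are rejected", {
  expect_error(gfp_photophysics(self_dimer_fraction = 1.2), "probability")
  expect_error(gfp_photophysics(unit_intensity = -5), "unit_intensity")
  expect_error(gfp_photophysics(noise_sd = -1), "noise_sd")
  expect_error(simulate_trace(-1, gfp_photophysics()), "n_fluorophores")
  expect_error(simulate_trace(1, gfp_photophysics(), n_frames = 5), "n_frames")
  expect_error(oligomer_spec(c(`0` = 1)), "sizes")
  expect_error(oligomer_spec(c(`1` = 0.5, `2` = 0.6)), "sum to 1")
})
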