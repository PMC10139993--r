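# one off-center cell per small field, geometry jittered by the caller
one_cell_spec <- function(f, noise = 0, granules = NULL, seed = 1,
                          total = 1e5, size = 96, axes = c(34, 26)) {
  synthetic_image_spec(size, size, pixel_size = 0.25, cells = list(
    cell_spec(c(size / 2, size / 2), axes, nucleus_axes = axes / 2.5,
              total_intensity = total, nuclear_signal_fraction = f,
              granules = granules)),
    noise_sd = noise, seed = seed)
}

test_that("three separated cells segment into three nucleus-cell pairs", {
  cells <- lapply(list(c(40, 40), c(130, 45), c(85, 130)), function(ctr)
    cell_spec(ctr, c(28, 22), nucleus_axes = c(11, 9),
              nuclear_signal_fraction = 0.5))
  img <- simulate_cell_image(synthetic_image_spec(176, 176, cells = cells))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  expect_equal(seg$n_cells, 3L)
  for (i in 1:3)
    expect_true(all(seg$cells[seg$nuclei == i] == i))  # nucleus inside its cell
})

test_that("a blank image yields zero cells with a warning", {
  z <- matrix(0, 64, 64)
  expect_warning(seg <- segment_cells_and_nuclei(z, z), "no cells")
  expect_equal(seg$n_cells, 0L)
})

test_that("segmentation recovers ground-truth masks at 2% noise (Jaccard >= 0.9)", {
  for (seed in 1:5) {
    sp <- one_cell_spec(0.5, noise = 0.02 * 1e5 / (pi * 34 * 26), seed = seed)
    img <- simulate_cell_image(sp)
    seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
    expect_equal(seg$n_cells, 1L)
    jac <- function(a, b) sum(a & b) / sum(a | b)
    expect_gte(jac(seg$cells == 1, img$cell_labels == 1), 0.9)
    expect_gte(jac(seg$nuclei == 1, img$nucleus_labels == 1), 0.9)
  }
})

test_that("localization fractions recover the generator's nuclear split", {
  # all signal nuclear
  img <- simulate_cell_image(one_cell_spec(1.0))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  loc <- localization_ratio(seg$cells, seg$nuclei, img$gfp)
  expect_equal(loc$nuclear_fraction, 1.0, tolerance = 1e-6)
  expect_equal(loc$cytosolic_fraction, 0.0, tolerance = 1e-6)

  # 50/50 split, noiseless: within rasterization tolerance
  img <- simulate_cell_image(one_cell_spec(0.5))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  loc <- localization_ratio(seg$cells, seg$nuclei, img$gfp)
  expect_lt(abs(loc$nuclear_fraction - 0.5), 0.02)
  expect_equal(loc$nuclear_fraction + loc$cytosolic_fraction, 1,
               tolerance = 1e-6)
})

test_that("granule detection counts disks and measures their area", {
  img <- simulate_cell_image(one_cell_spec(0.5))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  # uniform cell: nothing to detect
  gr <- quantify_granules(seg$cells, img$gfp, pixel_size = 0.25,
                          nuclei = seg$nuclei)
  expect_equal(nrow(gr$granules), 0L)
  expect_false(gr$cells$has_granules[1])

  # one disk of radius 5 px at 10x local intensity
  g1 <- data.frame(x = 70, y = 48, radius = 5, amplification = 10)
  img <- simulate_cell_image(one_cell_spec(0.5, granules = g1))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  gr <- quantify_granules(seg$cells, img$gfp, pixel_size = 0.25,
                          nuclei = seg$nuclei)
  expect_equal(nrow(gr$granules), 1L)
  expect_lt(abs(gr$granules$area_um2 - pi * 1.25^2), 0.15 * pi * 1.25^2)

  # two disjoint granules
  g2 <- data.frame(x = c(70, 30), y = c(48, 48), radius = c(5, 4),
                   amplification = c(10, 10))
  img <- simulate_cell_image(one_cell_spec(0.5, granules = g2))
  seg <- segment_cells_and_nuclei(img$nuclear, img$gfp)
  gr <- quantify_granules(seg$cells, img$gfp, pixel_size = 0.25,
                          nuclei = seg$nuclei)
  expect_equal(nrow(gr$granules), 2L)

  # relative contrast: invariant to rescaling the GFP channel
  gr7 <- quantify_granules(seg$cells, img$gfp * 7.3, pixel_size = 0.25,
                           nuclei = seg$nuclei)
  expect_equal(gr7$granules$area_um2, gr$granules$area_um2)
})

test_that("per-condition summaries report granule rates and SEMs", {
  m <- data.frame(cell_id = 1:10,
                  nuclear_fraction = rep(0.6, 10),
                  cytosolic_fraction = rep(0.4, 10),
                  undefined = FALSE,
                  n_granules = c(rep(1L, 4), rep(0L, 6)),
                  has_granules = c(rep(TRUE, 4), rep(FALSE, 6)),
                  total_granule_area_um2 = c(rep(2, 4), rep(0, 6)))
  s <- summarize_cells(m)
  expect_equal(s$pct_granule_positive, 40)
  expect_equal(s$sem_nuclear_fraction, 0)  # identical cells
  expect_equal(s$n_cells, 10L)
  expect_warning(summarize_cells(m[0, ]), "no cells")
})

test_that("a seeded cohort recovers its granule-positive rate within binomial error", {
  set.seed(77)
  n <- 120
  has <- runif(n) < 0.3
  meas <- lapply(seq_len(n), function(i) {
    gran <- if (has[i])
      data.frame(x = 70, y = 48, radius = 5, amplification = 10) else NULL
    img <- simulate_cell_image(one_cell_spec(0.5, granules = gran, seed = i))
    measure_cells(img$nuclear, img$gfp, pixel_size = 0.25)
  })
  meas <- do.call(rbind, meas)
  expect_equal(nrow(meas), n)
  s <- summarize_cells(meas)
  expect_lt(abs(s$pct_granule_positive / 100 - mean(has)),
            3 * sqrt(0.3 * 0.7 / n))
})

test_that("two-channel TIFF round trip preserves the image", {
  img <- simulate_cell_image(one_cell_spec(0.5))
  path <- tempfile(fileext = ".tif")
  scale <- write_cell_image(img, path)
  back <- read_cell_image(path, scale = scale)
  expect_equal(dim(back$gfp), dim(img$gfp))
  # 16-bit quantization: relative error bounded by 1/65535 of full scale
  expect_lt(max(abs(back$gfp - img$gfp)), scale / 65535)
  unlink(path)
})

test_that("invalid image specs are rejected", {
  expect_error(cell_spec(c(50, 50), c(20, 20),
                         granules = data.frame(x = 90, y = 50, radius = 3,
                                               amplification = 5)),
               "outside the cell")
  expect_error(simulate_cell_image(synthetic_image_spec(64, 64, cells = list(
    cell_spec(c(32, 32), c(10, 10), nucleus_axes = c(20, 20))))),
    "nucleus not contained")
  expect_error(segment_cells_and_nuclei(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical shape")
})
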