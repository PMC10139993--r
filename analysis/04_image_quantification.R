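#!/usr/bin/env Rscript

# Stage 4: subcellular localization and granule quantification on
# synthetic two-channel cell images.
#
# Cohorts of single-cell images emulate the fixed-cell arm of the
# study: a freely shuttling GFP control (~50% nuclear), a nuclear
# wildtype-like protein (~90% nuclear, occasional granules), an
# NLS-mutant-like condition (mislocalized, ~45% nuclear, frequent
# granules), and wildtype under osmotic stress (partially
# mislocalized, more granules). Each cell is segmented from its
# nuclear stain and GFP channel, nuclear/cytosolic signal fractions
# are measured, and granules are detected by local contrast.
#
# Output: results/image_summary.tsv

suppressMessages(library(simpullr))

cohorts <- list(
  GFP_only   = list(f = 0.50, granule_rate = 0.00, seed = 410),
  WT         = list(f = 0.90, granule_rate = 0.10, seed = 420),
  NLS_mutant = list(f = 0.45, granule_rate = 0.55, seed = 430),
  WT_stress  = list(f = 0.70, granule_rate = 0.40, seed = 440)
)
n_cells <- 30       # cells per condition
size <- 96          # px per single-cell field (24 um at 0.25 um/px)
noise <- 0.02 * 1e5 / (pi * 34 * 26)

measure_cohort <- function(f, granule_rate, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_cells), function(i) {
    gran <- NULL
    if (runif(1) < granule_rate) {
      ng <- sample(1:2, 1)
      gran <- data.frame(x = runif(ng, 40, 75), y = runif(ng, 40, 58),
                         radius = runif(ng, 3, 6), amplification = 10)
    }
    sp <- synthetic_image_spec(size, size, pixel_size = 0.25, cells = list(
      cell_spec(c(size / 2, size / 2), c(34, 26), nucleus_axes = c(13, 10),
                total_intensity = 1e5, nuclear_signal_fraction = f,
                granules = gran)),
      noise_sd = noise, seed = seed * 1000 + i)
    img <- simulate_cell_image(sp)
    measure_cells(img$nuclear, img$gfp, pixel_size = 0.25)
  })
  do.call(rbind, rows)
}

meas <- data.frame()
for (nm in names(cohorts)) {
  co <- cohorts[[nm]]
  m <- measure_cohort(co$f, co$granule_rate, co$seed)
  m$condition <- nm
  meas <- rbind(meas, m)
}

summary_tab <- summarize_cells(meas, group = "condition")
write.table(summary_tab, "results/image_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab, row.names = FALSE)

cat("\nRecovered nuclear fractions track the cohort settings and the\n")
cat("granule-positive percentages separate the NLS-mutant-like and\n")
cat("stressed cohorts from the controls; table in results/image_summary.tsv.\n")
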