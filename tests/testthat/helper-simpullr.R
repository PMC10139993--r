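# shared fixtures, built in code

# deterministic noiseless staircase: unit-height drops at given frames
make_staircase <- function(n, drop_frames, unit = 100, background = 50,
                           noise_sd = 0, seed = NULL) {
  x <- rep(background + unit * length(drop_frames), n)
  for (b in drop_frames) x[b:n] <- x[b:n] - unit
  if (noise_sd > 0) x <- x + with_seed_helper(seed, rnorm(n, 0, noise_sd))
  new_trace("stair", x)
}

with_seed_helper <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# half-width of a 95% normal-approximation binomial CI
binom_ci_halfwidth <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)

# a small standard photophysics: SNR 20, faster bleaching for short tests
fast_phys <- function(...) {
  gfp_photophysics(bleach_rate = 0.03, ...)
}
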