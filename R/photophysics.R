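#' GFP photophysics parameters for trace simulation
#'
#' Bundles the photophysical constants used by [simulate_trace()] and
#' [simulate_population()]. Defaults describe a typical EMCCD TIRF
#' recording of surface-immobilized GFP at signal-to-noise ratio 20
#' (`unit_intensity / noise_sd`).
#'
#' @param self_dimer_fraction Probability that a spot recruits one extra
#'   GFP-tagged partner through GFP-GFP self-association. The default
#'   0.30 reproduces the canonical GFP-only pull-down control in which
#'   roughly 70% of spots bleach in one step and 30% in two.
#' @param dark_fraction Probability that a given GFP is non-fluorescent
#'   (immature chromophore). Default 0: the standard single-bin dimer
#'   correction assumes every tag is counted; nonzero values are for
#'   robustness studies only.
#' @param bleach_rate Per-frame bleaching hazard of one fluorophore
#'   (geometric waiting time). Default 0.005 per frame, i.e. a mean
#'   bleach time of 20 s at a 0.1 s frame interval -- slow enough that
#'   two fluorophores in a spot essentially never bleach in the same
#'   frame.
#' @param unit_intensity Mean fluorescence (camera counts) contributed
#'   by one active fluorophore.
#' @param background_level Mean counts of an empty surface spot.
#' @param noise_sd Standard deviation of additive per-frame Gaussian
#'   camera noise, in counts.
#' @return An object of class `gfp_photophysics`.
#' @examples
#' phys <- gfp_photophysics()
#' phys$unit_intensity / phys$noise_sd  # SNR 20
#' @export
gfp_photophysics <- function(self_dimer_fraction = 0.30,
                             dark_fraction = 0,
                             bleach_rate = 0.005,
                             unit_intensity = 100,
                             background_level = 50,
                             noise_sd = 5) {
  check_prob(self_dimer_fraction, "self_dimer_fraction")
  check_prob(dark_fraction, "dark_fraction")
  if (!is.numeric(bleach_rate) || bleach_rate <= 0 || bleach_rate > 1)
    stop_input("bleach_rate must be a per-frame hazard in (0, 1]")
  if (!is.numeric(unit_intensity) || unit_intensity <= 0)
    stop_input("unit_intensity must be > 0")
  if (!is.numeric(background_level) || background_level < 0)
    stop_input("background_level must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_input("noise_sd must be >= 0")
  structure(list(self_dimer_fraction = self_dimer_fraction,
                 dark_fraction = dark_fraction,
                 bleach_rate = bleach_rate,
                 unit_intensity = unit_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd),
            class = "gfp_photophysics")
}

#' @export
print.gfp_photophysics <- function(x, ...) {
  cat("GFP photophysics:\n")
  cat(sprintf("  self-dimer fraction : %.3f\n", x$self_dimer_fraction))
  cat(sprintf("  dark fraction       : %.3f\n", x$dark_fraction))
  cat(sprintf("  bleach rate / frame : %.4f\n", x$bleach_rate))
  cat(sprintf("  unit intensity      : %.1f counts\n", x$unit_intensity))
  cat(sprintf("  background level    : %.1f counts\n", x$background_level))
  cat(sprintf("  noise sd            : %.1f counts (SNR %.0f)\n",
              x$noise_sd,
              if (x$noise_sd > 0) x$unit_intensity / x$noise_sd else Inf))
  invisible(x)
}
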