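#' Construct a single-molecule trace
#'
#' @param spot_id Spot identifier (character).
#' @param intensities Numeric vector of per-frame intensities (length >= 10).
#' @param frame_interval Seconds per frame.
#' @param truth Optional list of ground-truth fields (see [simulate_trace()]).
#' @return An object of class `simpull_trace`.
#' @export
new_trace <- function(spot_id, intensities, frame_interval = 0.1, truth = NULL) {
  if (!is.numeric(intensities) || length(intensities) < 10L)
    stop_input("a trace needs at least 10 frames")
  if (any(!is.finite(intensities)))
    stop_input("trace '", spot_id, "' contains non-finite intensities")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop_input("frame_interval must be > 0")
  structure(list(spot_id = as.character(spot_id),
                 intensities = as.numeric(intensities),
                 frame_interval = frame_interval,
                 truth = truth),
            class = "simpull_trace")
}

#' @export
print.simpull_trace <- function(x, ...) {
  cat(sprintf("<simpull_trace '%s': %d frames, %.3g s/frame%s>\n",
              x$spot_id, length(x$intensities), x$frame_interval,
              if (!is.null(x$truth))
                sprintf(", truth: %d active fluorophore(s)", x$truth$n_active)
              else ""))
  invisible(x)
}

#' Simulate one photobleaching trace
#'
#' Generates the intensity time series of a single immobilized spot
#' carrying `n_fluorophores` GFP tags. Each active fluorophore
#' contributes `unit_intensity` counts until its bleach frame, drawn
#' from a geometric distribution with per-frame hazard `bleach_rate`;
#' the first frame always shows the full initial level (acquisition
#' starts with all fluorophores on). Tags may be silently lost to the
#' dark fraction before the movie starts. Gaussian noise of sd
#' `noise_sd` is added per frame.
#'
#' The returned truth record stores the requested fluorophore count,
#' the active count after dark-fraction thinning, and the bleach frame
#' of every active fluorophore (1-based; the drop occurs *at* that
#' frame), so tests can compare fitted change points against the
#' generative staircase.
#'
#' @param n_fluorophores Number of GFP tags on the spot (integer >= 0).
#' @param phys A [gfp_photophysics()] object.
#' @param n_frames Number of frames (>= 10).
#' @param seed Optional integer seed (local to this call).
#' @param spot_id Identifier for the trace.
#' @param blink_rate Optional per-frame hazard of a transient dark
#'   (blinking) excursion per active fluorophore. Default 0: GFP
#'   blinking is off, and bleaching is the only intensity change.
#'   Nonzero values produce temporary drops followed by upward
#'   recoveries and exist to stress-test trace rejection.
#' @param blink_mean_off Mean length (frames) of a blinking dark
#'   excursion when `blink_rate > 0`.
#' @return A `simpull_trace` with `truth = list(n_fluorophores,
#'   n_active, bleach_frames)`.
#' @examples
#' tr <- simulate_trace(2, gfp_photophysics(noise_sd = 0, bleach_rate = 0.05),
#'                      n_frames = 100, seed = 1)
#' length(unique(round(tr$intensities)))  # 3 levels: 2 steps down
#' @export
simulate_trace <- function(n_fluorophores, phys = gfp_photophysics(),
                           n_frames = 1600, seed = NULL,
                           spot_id = "spot_1", blink_rate = 0,
                           blink_mean_off = 3) {
  if (!is_count(n_fluorophores)) stop_input("n_fluorophores must be an integer >= 0")
  if (!is_count(n_frames) || n_frames < 10) stop_input("n_frames must be an integer >= 10")
  stopifnot(inherits(phys, "gfp_photophysics"))
  with_seed(seed, {
    m <- if (phys$dark_fraction > 0)
      stats::rbinom(1L, n_fluorophores, 1 - phys$dark_fraction)
    else as.integer(n_fluorophores)
    # bleach frame on {2, 3, ...}: at least one frame at the full level
    bleach <- if (m > 0) 2L + stats::rgeom(m, phys$bleach_rate) else integer(0)
    # active fluorophores at frame t (1-based): those with bleach frame > t
    n_bleached_by <- cumsum(tabulate(pmin(bleach, n_frames + 1L), nbins = n_frames))
    active <- m - n_bleached_by
    if (blink_rate > 0 && m > 0) {
      for (i in seq_len(m)) {
        last_on <- min(bleach[i] - 1L, n_frames)
        t <- 1L
        while (t <= last_on) {
          t <- t + 1L + stats::rgeom(1L, blink_rate)  # end of on-period
          if (t > last_on) break
          off_end <- min(t + stats::rgeom(1L, 1 / blink_mean_off), last_on)
          active[t:off_end] <- active[t:off_end] - 1L
          t <- off_end + 1L
        }
      }
    }
    skeleton <- phys$background_level + active * phys$unit_intensity
    noise <- if (phys$noise_sd > 0) stats::rnorm(n_frames, 0, phys$noise_sd) else 0
    new_trace(spot_id, skeleton + noise,
              truth = list(n_fluorophores = as.integer(n_fluorophores),
                           n_active = m,
                           bleach_frames = sort(bleach)))
  })
}

#' Ground-truth oligomer-size distribution for a simulated condition
#'
#' @param probs Named numeric vector mapping oligomer size (>= 1) to
#'   probability; must sum to 1 within 1e-9.
#' @param n_spots Number of spots to simulate (> 0). The default, 300,
#'   matches the upper end of a typical pull-down surface density
#'   (100-300 molecules per 2,500 square-micron field).
#' @param seed Integer seed.
#' @return An object of class `oligomer_spec`.
#' @examples
#' oligomer_spec(c(`1` = 0.7, `2` = 0.3), n_spots = 1000, seed = 1)
#' @export
oligomer_spec <- function(probs, n_spots = 300, seed = 1) {
  if (is.null(names(probs)) || any(names(probs) == ""))
    stop_input("probs must be a named vector: names are oligomer sizes")
  sizes <- suppressWarnings(as.integer(names(probs)))
  if (any(is.na(sizes)) || any(sizes < 1))
    stop_input("oligomer sizes must be integers >= 1")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop_input("probabilities must be non-negative and sum to 1 (tol 1e-9)")
  if (!is_count(n_spots) || n_spots < 1) stop_input("n_spots must be an integer > 0")
  structure(list(sizes = sizes, probs = as.numeric(probs),
                 n_spots = as.integer(n_spots), seed = as.integer(seed)),
            class = "oligomer_spec")
}

#' Simulate a population of photobleaching traces
#'
#' Draws each spot's true oligomer size from `spec`, adds one extra
#' tagged partner with probability `self_dimer_fraction` (GFP-mediated
#' association; the increment is capped at +1), thins the resulting
#' fluorophore count by the dark fraction, and simulates one trace per
#' spot. A single RNG stream seeded from `spec$seed` makes the whole
#' population reproducible.
#'
#' @param spec An [oligomer_spec()].
#' @param phys A [gfp_photophysics()].
#' @param n_frames Frames per trace.
#' @return A list with `traces` (list of `simpull_trace`) and `truth`
#'   (data.frame: spot_id, true_size, n_fluorophores, n_active).
#' @examples
#' pop <- simulate_population(oligomer_spec(c(`1` = 1), n_spots = 20, seed = 7))
#' table(pop$truth$n_fluorophores)
#' @export
simulate_population <- function(spec, phys = gfp_photophysics(), n_frames = 1600) {
  stopifnot(inherits(spec, "oligomer_spec"), inherits(phys, "gfp_photophysics"))
  with_seed(spec$seed, {
    n <- spec$n_spots
    k <- spec$sizes[sample.int(length(spec$sizes), n, replace = TRUE,
                               prob = spec$probs)]
    extra <- stats::rbinom(n, 1L, phys$self_dimer_fraction)
    apparent <- k + extra
    ids <- sprintf("spot_%05d", seq_len(n))
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      traces[[i]] <- simulate_trace(apparent[i], phys, n_frames,
                                    seed = NULL, spot_id = ids[i])
    }
    truth <- data.frame(spot_id = ids,
                        true_size = as.integer(k),
                        n_fluorophores = as.integer(apparent),
                        n_active = vapply(traces, function(t) t$truth$n_active, 0L),
                        stringsAsFactors = FALSE)
    list(traces = traces, truth = truth)
  })
}
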