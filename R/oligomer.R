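#' Build a normalized photobleaching-step distribution
#'
#' Tabulates valid per-spot step counts into a normalized frequency
#' distribution over step numbers 1..K. Zero-step traces (empty spots)
#' and rejected fits are excluded before normalization, so `n_traces`
#' is the per-trace N a figure legend would report.
#'
#' @param step_counts Either a numeric vector of per-spot step counts,
#'   or the result of [batch_detect()] (its `table` is used, filtered
#'   to valid fits).
#' @param condition Condition label.
#' @return An `oligomer_distribution`: `condition`, `frequencies`
#'   (named over 1..K, summing to 1), `counts` (raw tallies),
#'   `n_traces`, and `steps` (the retained per-trace counts, kept for
#'   bootstrapping).
#' @examples
#' build_distribution(c(1, 1, 1, 2), condition = "demo")$frequencies
#' @export
build_distribution <- function(step_counts, condition = "condition") {
  if (is.list(step_counts) && !is.null(step_counts$table))
    step_counts <- step_counts$table
  if (is.data.frame(step_counts)) {
    keep <- step_counts$valid & step_counts$step_count >= 1
    step_counts <- step_counts$step_count[keep]
  }
  step_counts <- step_counts[is.finite(step_counts) & step_counts >= 1]
  if (length(step_counts) == 0L)
    stop_input("no valid traces with >= 1 step")
  if (any(step_counts != round(step_counts)))
    stop_input("step counts must be integers")
  k_max <- max(step_counts)
  counts <- tabulate(step_counts, nbins = k_max)
  names(counts) <- seq_len(k_max)
  structure(list(condition = condition,
                 frequencies = counts / sum(counts),
                 counts = counts,
                 n_traces = length(step_counts),
                 steps = as.integer(step_counts),
                 correction = NULL),
            class = "oligomer_distribution")
}

#' @export
print.oligomer_distribution <- function(x, ...) {
  cat(sprintf("<oligomer_distribution '%s': n = %d%s>\n", x$condition,
              x$n_traces,
              if (!is.null(x$correction))
                paste0(", corrected (", x$correction$mode, ")") else ""))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Pool high step counts into a "k+" display bin
#'
#' Collapses bins beyond `k_max` into a single pooled bin for display,
#' mirroring how step histograms are conventionally plotted when only
#' a handful of spots show very high counts.
#'
#' @param dist An `oligomer_distribution`.
#' @param k_max Last individual bin (default 6).
#' @return Data.frame with columns `step` (character; last entry
#'   `"<k_max>+"` when pooling occurred) and `frequency`.
#' @export
pool_steps <- function(dist, k_max = 6) {
  stopifnot(inherits(dist, "oligomer_distribution"))
  f <- dist$frequencies
  if (length(f) <= k_max)
    return(data.frame(step = names(f), frequency = unname(f)))
  data.frame(step = c(names(f)[seq_len(k_max - 1L)], paste0(k_max, "+")),
             frequency = c(unname(f[seq_len(k_max - 1L)]),
                           sum(f[k_max:length(f)])))
}

#' GFP self-dimerization correction model
#'
#' @param gfp_dimer_fraction Fraction of total mass attributed to GFP
#'   self-dimerization, measured on a GFP-only control (default 0.30).
#' @param mode Correction rule. `"bin_shift"` (default) moves
#'   `min(f2, gfp_dimer_fraction)` of total mass from the 2-step bin to
#'   the 1-step bin -- the single-bin subtraction that maps the
#'   canonical 70/30 GFP-only control onto a pure monomer.
#'   `"deconvolve"` inverts the generative self-dimer model, in which
#'   each complex recruits one extra tagged partner with probability
#'   `gfp_dimer_fraction` (so the observed distribution is
#'   `g(k) = (1-p) D(k) + p D(k-1)`); this is the estimator that
#'   recovers an arbitrary underlying size distribution, not only a
#'   monomer control. `"none"` is the identity.
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(gfp_dimer_fraction = 0.30,
                             mode = c("bin_shift", "deconvolve", "none")) {
  check_prob(gfp_dimer_fraction, "gfp_dimer_fraction")
  mode <- match.arg(mode)
  structure(list(gfp_dimer_fraction = gfp_dimer_fraction, mode = mode),
            class = "correction_model")
}

.apply_correction <- function(freq, model) {
  p <- model$gfp_dimer_fraction
  if (model$mode == "none" || p == 0) return(freq)
  k_max <- length(freq)
  if (model$mode == "bin_shift") {
    if (k_max >= 2L) {
      m <- min(freq[2L], p)
      freq[2L] <- freq[2L] - m
      freq[1L] <- freq[1L] + m
    }
  } else {  # deconvolve: back-substitute g(k) = (1-p) D(k) + p D(k-1)
    D <- numeric(k_max)
    D[1L] <- freq[1L] / (1 - p)
    if (k_max >= 2L) for (k in 2L:k_max)
      D[k] <- (freq[k] - p * D[k - 1L]) / (1 - p)
    names(D) <- names(freq)
    freq <- pmax(D, 0)
  }
  s <- sum(freq)
  if (s > 0) freq <- freq / s
  freq
}

#' Subtract the GFP self-dimerization background
#'
#' Applies a [correction_model()] to an observed step distribution.
#' In the default `bin_shift` mode, mass `min(f2, gfp_dimer_fraction)`
#' is moved from the 2-step to the 1-step bin (clipped at zero) and the
#' result renormalized -- a no-op when the input is already normalized,
#' since mass is conserved. Applied to the GFP-only control
#' (70% one-step, 30% two-step) this yields a pure monomer, the
#' control's known truth.
#'
#' @param obs An `oligomer_distribution`.
#' @param model A [correction_model()] (or a bare fraction, taken as
#'   `bin_shift`).
#' @return A corrected `oligomer_distribution`; the applied model is
#'   recorded in `$correction` so bootstrap resampling can reapply it.
#' @examples
#' d <- build_distribution(c(rep(1, 70), rep(2, 30)))
#' correct_gfp_background(d, correction_model(0.30))$frequencies
#' @export
correct_gfp_background <- function(obs, model = correction_model()) {
  stopifnot(inherits(obs, "oligomer_distribution"))
  if (is.numeric(model)) model <- correction_model(model)
  stopifnot(inherits(model, "correction_model"))
  out <- obs
  out$frequencies <- .apply_correction(obs$frequencies, model)
  out$correction <- model
  out
}

#' Average photobleaching step with bootstrap SEM
#'
#' Computes the mean step number `sum(k * f(k))` of a distribution and
#' its standard error by nonparametric bootstrap over traces: raw
#' per-trace counts are resampled with replacement, the distribution is
#' rebuilt (and any recorded GFP correction reapplied), and the SEM is
#' the standard deviation of the resampled means.
#'
#' @param dist An `oligomer_distribution`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A `condition_summary` data.frame: condition, average_step,
#'   sem, n_traces.
#' @examples
#' average_step(build_distribution(c(1, 2, 1, 2)), n_boot = 100)
#' @export
average_step <- function(dist, n_boot = 1000, seed = 1) {
  stopifnot(inherits(dist, "oligomer_distribution"))
  k <- as.numeric(names(dist$frequencies))
  avg <- sum(k * dist$frequencies)
  sem <- NA_real_
  if (n_boot > 0 && !is.null(dist$steps)) {
    steps <- dist$steps
    model <- dist$correction
    sem <- with_seed(seed, {
      means <- vapply(seq_len(n_boot), function(i) {
        s <- steps[sample.int(length(steps), replace = TRUE)]
        f <- tabulate(s, nbins = max(s))
        f <- f / sum(f)
        if (!is.null(model)) f <- .apply_correction(f, model)
        sum(seq_along(f) * f)
      }, 0)
      stats::sd(means)
    })
  }
  out <- data.frame(condition = dist$condition, average_step = avg,
                    sem = sem, n_traces = dist$n_traces,
                    stringsAsFactors = FALSE)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Per-bin difference of step distributions before/after dissolution
#'
#' Computes `d(k) = f_after(k) - f_before(k)` over the union of the two
#' bin ranges (zero-filled). Both inputs must be normalized; the
#' differences sum to zero by construction. Optional percentile
#' bootstrap confidence intervals per bin resample each side's traces
#' independently.
#'
#' @param before,after `oligomer_distribution` objects.
#' @param n_boot Bootstrap resamples for CIs (0 = none).
#' @param conf CI level.
#' @param seed Bootstrap seed.
#' @return A data.frame: step, before, after, diff (and ci_lo/ci_hi
#'   when `n_boot > 0`).
#' @export
dissolution_difference <- function(before, after, n_boot = 0,
                                   conf = 0.95, seed = 1) {
  stopifnot(inherits(before, "oligomer_distribution"),
            inherits(after, "oligomer_distribution"))
  for (d in list(before, after))
    if (abs(sum(d$frequencies) - 1) > 1e-9)
      stop_input("distributions must be normalized (sum to 1 within 1e-9)")
  k_max <- max(length(before$frequencies), length(after$frequencies))
  pad <- function(f) c(f, numeric(k_max - length(f)))
  fb <- pad(before$frequencies)
  fa <- pad(after$frequencies)
  out <- data.frame(step = seq_len(k_max), before = fb, after = fa,
                    diff = fa - fb)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        rb <- before$steps[sample.int(length(before$steps), replace = TRUE)]
        ra <- after$steps[sample.int(length(after$steps), replace = TRUE)]
        pad2 <- function(s) {
          f <- tabulate(s, nbins = k_max)
          f / sum(f)
        }
        pad2(ra) - pad2(rb)
      }, numeric(k_max))
      a <- (1 - conf) / 2
      apply(matrix(reps, nrow = k_max), 1L, stats::quantile,
            probs = c(a, 1 - a))
    })
    out$ci_lo <- ci[1L, ]
    out$ci_hi <- ci[2L, ]
  }
  out
}

#' Compare step counts between conditions
#'
#' Standard significance tests on per-trace step counts: a two-sample
#' t-test for two groups, one-way ANOVA for more, or two-way ANOVA
#' when a second factor (e.g. stress) is supplied. Pairwise
#' comparisons, when applicable, use Holm-adjusted t-tests; the
#' adjustment method is recorded in the output.
#'
#' @param step_counts Numeric vector of per-trace step counts.
#' @param condition Factor (or coercible) of condition labels.
#' @param stress Optional second factor for a two-way design.
#' @param p_adjust Multiple-comparison adjustment for pairwise tests.
#' @return A list: `method`, `statistic`, `p_value`, `table` (the full
#'   test table), `pairwise` (adjusted pairwise p-values or NULL),
#'   `p_adjust`.
#' @examples
#' compare_conditions(c(1, 2, 1, 3, 3, 4), rep(c("a", "b"), each = 3))$p_value
#' @export
compare_conditions <- function(step_counts, condition, stress = NULL,
                               p_adjust = "holm") {
  condition <- factor(condition)
  if (nlevels(condition) < 2L)
    stop_input("need at least two groups to compare")
  if (length(step_counts) != length(condition))
    stop_input("step_counts and condition lengths differ")
  df <- data.frame(y = as.numeric(step_counts), condition = condition)
  pairwise <- NULL
  if (!is.null(stress)) {
    df$stress <- factor(stress)
    fit <- stats::aov(y ~ condition * stress, data = df)
    tab <- summary(fit)[[1L]]
    method <- "two-way ANOVA"
    statistic <- tab[["F value"]][1L]
    p_value <- tab[["Pr(>F)"]][1L]
  } else if (nlevels(condition) == 2L) {
    tt <- stats::t.test(y ~ condition, data = df)
    method <- "two-sample t-test"
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
    tab <- tt
  } else {
    fit <- stats::aov(y ~ condition, data = df)
    tab <- summary(fit)[[1L]]
    method <- "one-way ANOVA"
    statistic <- tab[["F value"]][1L]
    p_value <- tab[["Pr(>F)"]][1L]
    pairwise <- stats::pairwise.t.test(df$y, df$condition,
                                       p.adjust.method = p_adjust)$p.value
  }
  list(method = method, statistic = statistic, p_value = p_value,
       table = tab, pairwise = pairwise, p_adjust = p_adjust)
}
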