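#' Segmentation and granule-detection parameters
#'
#' @param nuclear_method,cell_method Thresholding method for the
#'   nuclear and GFP channels: `"otsu"`, `"background"` (median plus
#'   4 robust SDs of the image -- suited to a faint-cytoplasm GFP
#'   channel whose histogram is multi-modal, where Otsu cuts above the
#'   cytosol level), or `"fixed"`. Defaults: Otsu for the bimodal
#'   nuclear stain, background for the GFP channel.
#' @param nuclear_threshold,cell_threshold Fixed thresholds (on the
#'   raw intensity scale), used when the corresponding method is
#'   `"fixed"`.
#' @param min_cell_area,min_nucleus_area Minimum object size in pixels
#'   for a connected component to count as a cell / nucleus.
#' @param granule_contrast Local-contrast factor: a granule pixel must
#'   exceed this multiple of the reference median intensity of its
#'   compartment (> 1).
#' @param min_granule_area Minimum granule area in pixels.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(nuclear_method = c("otsu", "background", "fixed"),
                                cell_method = c("background", "otsu", "fixed"),
                                nuclear_threshold = NA,
                                cell_threshold = NA,
                                min_cell_area = 64,
                                min_nucleus_area = 16,
                                granule_contrast = 5,
                                min_granule_area = 4) {
  nuclear_method <- match.arg(nuclear_method)
  cell_method <- match.arg(cell_method)
  if (granule_contrast <= 1) stop_input("granule_contrast must be > 1")
  if (min_granule_area < 1) stop_input("min_granule_area must be >= 1")
  structure(list(nuclear_method = nuclear_method, cell_method = cell_method,
                 nuclear_threshold = nuclear_threshold,
                 cell_threshold = cell_threshold,
                 min_cell_area = min_cell_area,
                 min_nucleus_area = min_nucleus_area,
                 granule_contrast = granule_contrast,
                 min_granule_area = min_granule_area),
            class = "segmentation_params")
}

# threshold + connected components, labels renumbered by centroid
# (row-major: top-to-bottom, then left-to-right), small objects removed
.label_objects <- function(channel, method, fixed_threshold, min_area) {
  rng <- range(channel)
  if (diff(rng) == 0) return(matrix(0L, nrow(channel), ncol(channel)))
  if (method == "otsu") {
    norm <- (channel - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  } else if (method == "background") {
    bg <- stats::median(channel)
    mask <- channel > bg + 4 * stats::mad(channel)
  } else {
    if (!is.finite(fixed_threshold)) stop_input("fixed threshold not set")
    mask <- channel > fixed_threshold
  }
  mask <- EBImage::fillHull(EBImage::Image(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  lab <- matrix(as.integer(lab), nrow(channel), ncol(channel))
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(matrix(0L, nrow(channel), ncol(channel)))
  cy <- vapply(keep, function(l) mean(row(lab)[lab == l]), 0)
  cx <- vapply(keep, function(l) mean(col(lab)[lab == l]), 0)
  ord <- keep[order(cy, cx)]
  out <- matrix(0L, nrow(channel), ncol(channel))
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

#' Segment cells and nuclei from a two-channel image
#'
#' Thresholds the nuclear channel to find nuclei and the GFP channel to
#' find cell outlines, labels connected components deterministically by
#' centroid order, and pairs each nucleus with the cell containing it.
#' Cells without a nucleus, nuclei outside any single cell, and objects
#' below the minimum areas are dropped. An image with no detectable
#' cells yields empty (all-zero) label matrices with a warning.
#'
#' @param nuclear,gfp Registered channel matrices of identical shape.
#' @param params A [segmentation_params()].
#' @return List of `cells` and `nuclei` integer label matrices,
#'   renumbered so nucleus `i` lies inside cell `i`, plus `n_cells`.
#' @export
segment_cells_and_nuclei <- function(nuclear, gfp,
                                     params = segmentation_params()) {
  if (!all(dim(nuclear) == dim(gfp)))
    stop_input("channels must have identical shape")
  stopifnot(inherits(params, "segmentation_params"))
  nuc <- .label_objects(nuclear, params$nuclear_method,
                        params$nuclear_threshold, params$min_nucleus_area)
  cells <- .label_objects(gfp, params$cell_method,
                          params$cell_threshold, params$min_cell_area)
  if (max(cells) == 0L || max(nuc) == 0L) {
    warning("no cells found")
    z <- matrix(0L, nrow(gfp), ncol(gfp))
    return(list(cells = z, nuclei = z, n_cells = 0L))
  }
  # pair: a nucleus belongs to the unique cell covering all its pixels
  out_cells <- matrix(0L, nrow(gfp), ncol(gfp))
  out_nuc <- matrix(0L, nrow(gfp), ncol(gfp))
  next_id <- 0L
  used_cells <- integer(0)
  for (nl in seq_len(max(nuc))) {
    under <- cells[nuc == nl]
    host <- unique(under[under > 0L])
    if (length(host) != 1L || any(under == 0L)) next
    if (host %in% used_cells) next  # one nucleus per cell
    next_id <- next_id + 1L
    used_cells <- c(used_cells, host)
    out_cells[cells == host] <- next_id
    out_nuc[nuc == nl] <- next_id
  }
  if (next_id == 0L) warning("no nucleus-cell pairs found")
  list(cells = out_cells, nuclei = out_nuc, n_cells = next_id)
}

#' Nuclear and cytosolic GFP signal fractions per cell
#'
#' For each segmented cell, integrates background-subtracted GFP
#' signal over the nucleus and over the whole cell; the nuclear
#' fraction is their ratio and the cytosolic fraction its complement,
#' so the two always sum to one. Background is the median GFP
#' intensity over off-cell pixels.
#'
#' @param cells,nuclei Label matrices from
#'   [segment_cells_and_nuclei()] (nucleus `i` inside cell `i`).
#' @param gfp GFP channel matrix.
#' @return Data.frame: cell_id, nuclear_fraction, cytosolic_fraction,
#'   undefined (TRUE when the cell has no measurable signal).
#' @export
localization_ratio <- function(cells, nuclei, gfp) {
  if (!all(dim(cells) == dim(gfp)))
    stop_input("mask and channel shapes differ")
  n <- max(cells)
  bg <- if (any(cells == 0L)) stats::median(gfp[cells == 0L]) else 0
  sig <- pmax(gfp - bg, 0)
  out <- data.frame(cell_id = seq_len(n), nuclear_fraction = NA_real_,
                    cytosolic_fraction = NA_real_, undefined = FALSE)
  for (i in seq_len(n)) {
    tot <- sum(sig[cells == i])
    if (tot <= 0) {
      out$undefined[i] <- TRUE
      next
    }
    nf <- sum(sig[nuclei == i]) / tot
    out$nuclear_fraction[i] <- nf
    out$cytosolic_fraction[i] <- 1 - nf
  }
  out
}

#' Detect granules within cells and measure their areas
#'
#' Granules are connected components of pixels whose intensity exceeds
#' `granule_contrast` times the reference median of their compartment,
#' with at least `min_granule_area` pixels. The reference is the
#' median GFP intensity over the whole cell; when a nucleus mask is
#' supplied, nuclear and cytosolic pixels are each compared against
#' their own compartment median, so a brightly stained nucleus is not
#' itself called a granule. Because the threshold is relative, results
#' are invariant to rescaling the GFP channel.
#'
#' @param cells Cell label matrix.
#' @param gfp GFP channel matrix.
#' @param params A [segmentation_params()].
#' @param pixel_size Micrometers per pixel.
#' @param nuclei Optional nucleus label matrix for compartment-wise
#'   reference medians.
#' @return List: `granules` (data.frame cell_id, granule_id, area_px,
#'   area_um2) and `cells` (data.frame cell_id, n_granules,
#'   has_granules, total_granule_area_um2).
#' @export
quantify_granules <- function(cells, gfp, params = segmentation_params(),
                              pixel_size = 0.25, nuclei = NULL) {
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  n <- max(cells)
  gran <- list()
  per_cell <- data.frame(cell_id = seq_len(n), n_granules = 0L,
                         has_granules = FALSE,
                         total_granule_area_um2 = 0)
  for (i in seq_len(n)) {
    inc <- cells == i
    if (is.null(nuclei)) {
      thr_mask <- inc & gfp > params$granule_contrast * stats::median(gfp[inc])
    } else {
      innuc <- inc & nuclei == i
      incyt <- inc & nuclei != i
      thr_mask <- matrix(FALSE, nrow(gfp), ncol(gfp))
      if (any(innuc))
        thr_mask[innuc] <- gfp[innuc] >
          params$granule_contrast * stats::median(gfp[innuc])
      if (any(incyt))
        thr_mask[incyt] <- gfp[incyt] >
          params$granule_contrast * stats::median(gfp[incyt])
    }
    if (!any(thr_mask)) next
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(thr_mask)))
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$min_granule_area)
    if (length(keep) == 0L) next
    areas_px <- sizes[keep]
    gran[[length(gran) + 1L]] <- data.frame(
      cell_id = i, granule_id = seq_along(keep),
      area_px = areas_px, area_um2 = areas_px * pixel_size^2)
    per_cell$n_granules[i] <- length(keep)
    per_cell$has_granules[i] <- TRUE
    per_cell$total_granule_area_um2[i] <- sum(areas_px) * pixel_size^2
  }
  list(granules = if (length(gran)) do.call(rbind, gran)
       else data.frame(cell_id = integer(), granule_id = integer(),
                       area_px = integer(), area_um2 = numeric()),
       cells = per_cell)
}

#' Measure localization and granules for every cell in an image
#'
#' Convenience wrapper: segments, measures localization fractions and
#' granules, and returns one row per cell.
#'
#' @param nuclear,gfp Channel matrices.
#' @param params A [segmentation_params()].
#' @param pixel_size Micrometers per pixel.
#' @return Per-cell data.frame combining [localization_ratio()] and
#'   the per-cell granule summary.
#' @export
measure_cells <- function(nuclear, gfp, params = segmentation_params(),
                          pixel_size = 0.25) {
  seg <- segment_cells_and_nuclei(nuclear, gfp, params)
  if (seg$n_cells == 0L)
    return(data.frame(cell_id = integer(), nuclear_fraction = numeric(),
                      cytosolic_fraction = numeric(), undefined = logical(),
                      n_granules = integer(), has_granules = logical(),
                      total_granule_area_um2 = numeric()))
  loc <- localization_ratio(seg$cells, seg$nuclei, gfp)
  gr <- quantify_granules(seg$cells, gfp, params, pixel_size,
                          nuclei = seg$nuclei)
  merge(loc, gr$cells, by = "cell_id")
}

#' Summarize cell measurements per condition
#'
#' @param measurements Per-cell data.frame (as from [measure_cells()]),
#'   with an optional grouping column.
#' @param group Vector of condition labels (recycled from a column name
#'   if `measurements[[group]]` exists); `NULL` treats all cells as one
#'   group.
#' @return Per-group data.frame: n_cells, pct_granule_positive,
#'   mean_granule_area_um2, mean_nuclear_fraction,
#'   sem_nuclear_fraction. Empty groups are dropped with a warning.
#' @export
summarize_cells <- function(measurements, group = NULL) {
  if (is.character(group) && length(group) == 1L &&
      group %in% names(measurements))
    group <- measurements[[group]]
  if (is.null(group)) group <- rep("all", nrow(measurements))
  if (nrow(measurements) == 0L) {
    warning("no cells to summarize")
    return(data.frame(condition = character(), n_cells = integer(),
                      pct_granule_positive = numeric(),
                      mean_granule_area_um2 = numeric(),
                      mean_nuclear_fraction = numeric(),
                      sem_nuclear_fraction = numeric()))
  }
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(0)
    stats::sd(x) / sqrt(length(x))
  }
  res <- lapply(split(measurements, factor(group)), function(d) {
    pos <- d$has_granules
    data.frame(
      n_cells = nrow(d),
      pct_granule_positive = 100 * mean(pos),
      mean_granule_area_um2 = if (any(pos))
        mean(d$total_granule_area_um2[pos] / pmax(d$n_granules[pos], 1L))
      else NA_real_,
      mean_nuclear_fraction = mean(d$nuclear_fraction, na.rm = TRUE),
      sem_nuclear_fraction = sem(d$nuclear_fraction))
  })
  out <- cbind(condition = names(res), do.call(rbind, res))
  rownames(out) <- NULL
  out
}
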