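#' Specify one synthetic cell
#'
#' Geometry and signal model for a single cell in a synthetic
#' two-channel image: an elliptical cell containing an elliptical
#' nucleus, a configurable fraction of integrated GFP signal in the
#' nucleus, and optional circular granules of locally amplified
#' intensity. Coordinates are pixel-centered, (x = column, y = row).
#'
#' @param center Cell ellipse center `c(x, y)` in pixels.
#' @param axes Cell semi-axes `c(ax, ay)` in pixels.
#' @param nucleus_center,nucleus_axes Nucleus ellipse (must lie inside
#'   the cell).
#' @param total_intensity Integrated GFP signal of the cell (counts).
#' @param nuclear_signal_fraction Fraction of `total_intensity`
#'   allocated to nuclear pixels, in `[0, 1]`.
#' @param granules Optional data.frame with columns `x`, `y`,
#'   `radius` (pixels) and `amplification` (multiplicative intensity
#'   factor); centers must lie inside the cell.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center, axes, nucleus_center = center,
                      nucleus_axes = axes / 2, total_intensity = 1e5,
                      nuclear_signal_fraction = 0.5, granules = NULL) {
  check_prob(nuclear_signal_fraction, "nuclear_signal_fraction")
  if (total_intensity <= 0) stop_input("total_intensity must be > 0")
  if (!is.null(granules)) {
    need <- c("x", "y", "radius", "amplification")
    if (!all(need %in% names(granules)))
      stop_input("granules needs columns x, y, radius, amplification")
    inside <- ((granules$x - center[1]) / axes[1])^2 +
      ((granules$y - center[2]) / axes[2])^2 <= 1
    if (!all(inside)) stop_input("granule center(s) outside the cell ellipse")
  }
  list(center = center, axes = axes, nucleus_center = nucleus_center,
       nucleus_axes = nucleus_axes, total_intensity = total_intensity,
       nuclear_signal_fraction = nuclear_signal_fraction,
       granules = granules)
}

#' Specify a synthetic two-channel image
#'
#' @param width,height Field size in pixels.
#' @param pixel_size Pixel calibration in micrometers per pixel
#'   (default 0.25).
#' @param cells List of [cell_spec()] objects.
#' @param noise_sd SD of additive Gaussian noise, in counts.
#' @param nuclear_stain_level Per-pixel intensity of the nuclear stain
#'   channel inside nuclei.
#' @param seed Integer seed for the noise.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(width, height, pixel_size = 0.25,
                                 cells = list(), noise_sd = 0,
                                 nuclear_stain_level = 1000, seed = 1) {
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, cells = cells,
                 noise_sd = noise_sd,
                 nuclear_stain_level = nuclear_stain_level,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

.ellipse_mask <- function(width, height, center, axes) {
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}

.disk_mask <- function(width, height, center, radius) {
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Render a synthetic two-channel cell image
#'
#' Rasterizes the cells of a [synthetic_image_spec()] into a nuclear
#' stain channel and a GFP channel with ground-truth label masks. Each
#' cell's integrated GFP signal is split so that nuclear pixels carry
#' exactly `nuclear_signal_fraction` of it (uniform per-pixel
#' intensity within each compartment); granules multiply the local
#' intensity by their amplification factor. Gaussian noise is added
#' per pixel and clipped at zero.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list: `gfp` and `nuclear` (height x width matrices),
#'   `cell_labels` and `nucleus_labels` (integer label matrices),
#'   and `truth` (per-cell data.frame and per-granule data.frame with
#'   analytic disk areas in square micrometers).
#' @examples
#' sp <- synthetic_image_spec(64, 64, cells = list(
#'   cell_spec(c(32, 32), c(24, 18), nucleus_axes = c(10, 8))))
#' img <- simulate_cell_image(sp)
#' sum(img$gfp[img$nucleus_labels == 1]) / sum(img$gfp)
#' @export
simulate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  w <- spec$width; h <- spec$height
  gfp <- matrix(0, h, w)
  nuc_ch <- matrix(0, h, w)
  cell_lab <- matrix(0L, h, w)
  nuc_lab <- matrix(0L, h, w)
  cell_rows <- list()
  gran_rows <- list()
  for (i in seq_along(spec$cells)) {
    cs <- spec$cells[[i]]
    cmask <- .ellipse_mask(w, h, cs$center, cs$axes)
    nmask <- .ellipse_mask(w, h, cs$nucleus_center, cs$nucleus_axes)
    if (any(nmask & !cmask))
      stop_input("cell ", i, ": nucleus not contained in cell")
    if (any(cmask & cell_lab > 0L))
      stop_input("cell ", i, ": overlaps another cell")
    cyt <- cmask & !nmask
    f <- cs$nuclear_signal_fraction
    n_nuc <- sum(nmask); n_cyt <- sum(cyt)
    if (n_nuc > 0) gfp[nmask] <- cs$total_intensity * f / n_nuc
    if (n_cyt > 0) gfp[cyt] <- cs$total_intensity * (1 - f) / n_cyt
    if (!is.null(cs$granules) && nrow(cs$granules) > 0) {
      for (g in seq_len(nrow(cs$granules))) {
        gr <- cs$granules[g, ]
        gmask <- .disk_mask(w, h, c(gr$x, gr$y), gr$radius) & cmask
        gfp[gmask] <- gfp[gmask] * gr$amplification
        gran_rows[[length(gran_rows) + 1L]] <- data.frame(
          cell_id = i, x = gr$x, y = gr$y, radius_px = gr$radius,
          area_um2 = pi * (gr$radius * spec$pixel_size)^2)
      }
    }
    nuc_ch[nmask] <- spec$nuclear_stain_level
    cell_lab[cmask] <- i
    nuc_lab[nmask] <- i
    cell_rows[[i]] <- data.frame(
      cell_id = i, total_intensity = cs$total_intensity,
      nuclear_signal_fraction = f,
      n_granules = if (is.null(cs$granules)) 0L else nrow(cs$granules))
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      gfp <- pmax(gfp + stats::rnorm(length(gfp), 0, spec$noise_sd), 0)
      nuc_ch <- pmax(nuc_ch + stats::rnorm(length(nuc_ch), 0, spec$noise_sd), 0)
    })
    dim(gfp) <- dim(nuc_ch) <- c(h, w)
  }
  list(gfp = gfp, nuclear = nuc_ch,
       cell_labels = cell_lab, nucleus_labels = nuc_lab,
       truth = list(
         cells = if (length(cell_rows)) do.call(rbind, cell_rows)
                 else data.frame(),
         granules = if (length(gran_rows)) do.call(rbind, gran_rows)
                    else data.frame()))
}

#' Write a two-channel image as 16-bit multi-page TIFF
#'
#' Page 1 is the nuclear stain, page 2 the GFP channel; intensities are
#' scaled jointly by the image maximum into 16-bit range. Label masks
#' can be written alongside as a label TIFF.
#'
#' @param img Result of [simulate_cell_image()].
#' @param path Output TIFF path.
#' @param labels_path Optional path for a two-page label TIFF
#'   (cell labels, nucleus labels).
#' @return Invisibly, the scale factor used.
#' @export
write_cell_image <- function(img, path, labels_path = NULL) {
  mx <- max(img$gfp, img$nuclear, 1)
  pages <- list(img$nuclear / mx, img$gfp / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(labels_path)) {
    lmx <- max(img$cell_labels, 1)
    tiff::writeTIFF(list(img$cell_labels / lmx, img$nucleus_labels / lmx),
                    labels_path, bits.per.sample = 16L)
  }
  invisible(mx)
}

#' Read a two-channel TIFF written by [write_cell_image()]
#'
#' @param path TIFF path.
#' @param scale Intensity scale to undo the 16-bit normalization
#'   (the value returned by [write_cell_image()]); default 1 returns
#'   values in `[0, 1]`.
#' @return List with `nuclear` and `gfp` matrices.
#' @export
read_cell_image <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) stop_input("expected a two-page TIFF")
  list(nuclear = pages[[1L]] * scale, gfp = pages[[2L]] * scale)
}
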