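#' Segmentation parameters
#'
#' Tunable parameters of the nucleus segmentation stage. Area gates default
#' to the native acquisition scale (2728 x 2192 pixels); pass `scale_to` to
#' rescale them linearly with field area for smaller fields (morphology and
#' smoothing radii are kept in absolute pixels, since nucleus texture does
#' not shrink with the imaged field of view).
#'
#' @param min_area_px,max_area_px nucleus area gates in pixels; regions
#'   outside are flagged `TOO_SMALL`/`TOO_LARGE` and excluded.
#' @param min_solidity regions with solidity (area / convex-hull area) below
#'   this are flagged `AGGREGATED` (overlapping or clumped nuclei).
#' @param smoothing_sigma_px Gaussian smoothing applied to DAPI before
#'   thresholding.
#' @param morphology_radius_px disc radius for opening/closing; also sets
#'   the watershed peak separation.
#' @param exclude_border flag regions touching the field border.
#' @param scale_to optional `c(height, width)`; linearly rescales the area
#'   gates by `height*width / (2728*2192)`. The scaled gates are floored
#'   (`min_area_px` at 4 px, `max_area_px` at 3000 px) so that small
#'   crops or mini-fields holding a full-size nucleus are not rejected
#'   wholesale.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_area_px = 200, max_area_px = 50000,
                       min_solidity = 0.85, smoothing_sigma_px = 2,
                       morphology_radius_px = 5, exclude_border = TRUE,
                       scale_to = NULL) {
  if (!is.null(scale_to)) {
    f <- prod(scale_to[1:2]) / (2728 * 2192)
    min_area_px <- max(4, round(min_area_px * f))
    max_area_px <- max(3000, min_area_px + 1, round(max_area_px * f))
  }
  stopifnot(min_area_px > 0, min_area_px < max_area_px,
            min_solidity > 0, min_solidity <= 1, morphology_radius_px >= 1)
  structure(list(min_area_px = min_area_px, max_area_px = max_area_px,
                 min_solidity = min_solidity,
                 smoothing_sigma_px = smoothing_sigma_px,
                 morphology_radius_px = morphology_radius_px,
                 exclude_border = isTRUE(exclude_border)),
            class = "seg_params")
}

#' Convert an RGB raster to luminance gray
#'
#' ITU-R BT.601 luminance: `round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param rgb array `height x width x 3`, values on the integer intensity
#'   range (0..255 for 8-bit).
#' @param role channel role to declare on the result (default DAPI, the
#'   usual downstream consumer).
#' @param bit_depth output bit depth.
#' @return A [channel_image].
#' @export
to_gray <- function(rgb, role = "DAPI", bit_depth = 8) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stopf("rgb must be a height x width x 3 array")
  g <- round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
  channel_image(g, role, bit_depth)
}

# Mirror-pad a matrix by one pixel (reflection about the border pixel,
# excluding it: row 0 reflects to row 2).
pad_reflect1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- if (h > 1) c(2L, 1:h, h - 1L) else c(1L, 1L, 1L)
  ci <- if (w > 1) c(2L, 1:w, w - 1L) else c(1L, 1L, 1L)
  m[ri, ci, drop = FALSE]
}

# 3x3 correlation on a reflect-padded image, vectorized via shifted views.
conv3 <- function(m, k) {
  p <- pad_reflect1(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 0:2) for (j in 0:2) {
    if (k[i + 1, j + 1] == 0) next
    out <- out + k[i + 1, j + 1] * p[i + 1:h, j + 1:w, drop = FALSE]
  }
  out
}

#' Sobel gradient magnitude
#'
#' Per-pixel `sqrt(Gx^2 + Gy^2)` with 3x3 Sobel kernels and reflective
#' border handling, rounded and clipped to the channel's bit range.
#'
#' @param gray a [channel_image].
#' @return A [channel_image] of the same role and bit depth.
#' @export
gradient_magnitude <- function(gray) {
  stopifnot(inherits(gray, "channel_image"))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3(gray$pixels, kx)
  gy <- conv3(gray$pixels, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  channel_image(clip(round(mag), 0, max_intensity(gray$bit_depth)),
                gray$role, gray$bit_depth)
}

#' Otsu threshold of an integer intensity sample
#'
#' Exhaustive between-class-variance maximizer over all candidate integer
#' thresholds; foreground is defined as strictly greater than the returned
#' threshold. Ties are broken toward the lower threshold. Returns `NA` when
#' fewer than two distinct values are present (no meaningful split).
#'
#' @param values integer vector (or matrix) of intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth intensity bit depth (8 or 16).
#' @return Integer threshold, or `NA_integer_`.
#' @export
otsu_threshold <- function(values, bit_depth = 8) {
  v <- as.integer(round(as.vector(values)))
  L <- max_intensity(bit_depth)
  cnt <- tabulate(v + 1L, nbins = L + 1L)
  if (sum(cnt > 0) < 2L) return(NA_integer_)
  n <- length(v)
  p <- cnt / n
  lev <- 0:L
  omega <- cumsum(p)            # P(intensity <= t), t = 0..L
  mu <- cumsum(p * lev)
  muT <- mu[L + 1L]
  t <- 0:(L - 1L)
  w0 <- omega[t + 1L]
  m0 <- mu[t + 1L]
  sb <- (muT * w0 - m0)^2 / (w0 * (1 - w0))
  sb[w0 <= 0 | w0 >= 1] <- -Inf
  as.integer(t[which.max(sb)])  # which.max takes the first (lowest) maximum
}

#' Binarize a channel by Otsu thresholding
#'
#' Foreground is the set of pixels strictly above the Otsu threshold of the
#' image histogram. A constant (or single-valued) image yields an
#' all-background mask.
#'
#' @param gray a [channel_image] or integer matrix.
#' @param bit_depth bit depth when `gray` is a bare matrix.
#' @return Logical matrix mask, with the threshold in `attr(, "threshold")`.
#' @export
binarize <- function(gray, bit_depth = 8) {
  if (inherits(gray, "channel_image")) {
    px <- gray$pixels; bit_depth <- gray$bit_depth
  } else px <- gray
  th <- otsu_threshold(px, bit_depth)
  mask <- if (is.na(th)) matrix(FALSE, nrow(px), ncol(px)) else px > th
  attr(mask, "threshold") <- th
  mask
}

disc_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, shape = "disc")

#' Morphological cleaning of a binary mask
#'
#' Opening (disc of `morphology_radius_px`) to remove noise and thin
#' bridges, hole filling, closing with the same disc to smooth boundaries,
#' then removal of connected components smaller than `min_area_px`.
#'
#' @param mask logical matrix.
#' @param params a [seg_params].
#' @return Cleaned logical matrix.
#' @export
morph_clean <- function(mask, params = seg_params()) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  br <- disc_brush(params$morphology_radius_px)
  img <- as_ebi(mask * 1)
  img <- EBImage::closing(EBImage::fillHull(EBImage::opening(img, br)), br)
  out <- from_ebi(img) > 0.5
  lab <- .cc_label(out, 8L)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < params$min_area_px)
  if (length(drop)) out[lab %in% drop] <- FALSE
  out
}

# ---- nucleus regions ---------------------------------------------------

# Area of the convex hull of a pixel set, computed on the pixels' corner
# lattice (each pixel is the unit square [r,r+1) x [c,c+1)) by the shoelace
# formula. Exact for axis-aligned rectangles.
convex_hull_area <- function(rows, cols) {
  pts <- cbind(c(rows, rows + 1, rows, rows + 1),
               c(cols, cols, cols + 1, cols + 1))
  hull <- grDevices::chull(pts)
  p <- pts[hull, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(length(rows))
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

new_region <- function(label, idx, dims, params) {
  nr <- dims[1]
  rows <- (idx - 1L) %% nr        # 0-based image rows
  cols <- (idx - 1L) %/% nr
  area <- length(idx)
  bbox <- c(min(rows), max(rows) + 1L, min(cols), max(cols) + 1L)
  hull_area <- convex_hull_area(rows, cols)
  solidity <- min(1, area / hull_area)
  flags <- character(0)
  if (area < params$min_area_px) flags <- c(flags, "TOO_SMALL")
  if (area > params$max_area_px) flags <- c(flags, "TOO_LARGE")
  if (solidity < params$min_solidity) flags <- c(flags, "AGGREGATED")
  if (params$exclude_border &&
      (bbox[1] == 0 || bbox[3] == 0 || bbox[2] == dims[1] || bbox[4] == dims[2]))
    flags <- c(flags, "TOUCHES_BORDER")
  structure(list(label = label, pixels = idx, dim = dims,
                 bbox = as.integer(bbox),
                 centroid = c(mean(rows), mean(cols)),
                 area = area, solidity = solidity, qc_flags = flags,
                 excluded = length(flags) > 0),
            class = "nucleus_region")
}

#' @export
print.nucleus_region <- function(x, ...) {
  cat(sprintf(
    "<nucleus_region> label=%d area=%d centroid=(%.1f, %.1f) solidity=%.3f%s\n",
    x$label, x$area, x$centroid[1], x$centroid[2], x$solidity,
    if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Recover a region's binary mask
#'
#' @param region a `nucleus_region`.
#' @return Logical matrix of the full field size.
#' @export
region_mask <- function(region) {
  m <- matrix(FALSE, region$dim[1], region$dim[2])
  m[region$pixels] <- TRUE
  m
}

regions_from_labels <- function(lab, params) {
  labs <- lab[lab > 0L]
  if (!length(labs)) return(list())
  idx_by_label <- split(which(lab > 0L), lab[lab > 0L])
  # relabel in raster-scan order (row-major) of each component's first pixel
  nr <- nrow(lab)
  first_pix <- vapply(idx_by_label, min, numeric(1))
  key <- (first_pix - 1) %% nr * ncol(lab) + (first_pix - 1) %/% nr
  ord <- order(key)
  out <- vector("list", length(ord))
  for (i in seq_along(ord))
    out[[i]] <- new_region(i, idx_by_label[[ord[i]]], dim(lab), params)
  out
}

#' Label nuclei in a cleaned binary mask
#'
#' 8-connected components are labeled `1..n` in raster-scan order of their
#' topmost-leftmost pixel. Each region receives QC flags: `TOO_SMALL` /
#' `TOO_LARGE` from the area gates, `AGGREGATED` when solidity falls below
#' `min_solidity`, and `TOUCHES_BORDER` when any pixel lies on the field
#' border and `exclude_border` is set. Flagged regions are retained but
#' marked `excluded`.
#'
#' @param mask logical matrix.
#' @param params a [seg_params].
#' @return List of `nucleus_region` objects.
#' @export
label_nuclei <- function(mask, params = seg_params()) {
  storage.mode(mask) <- "logical"
  regions_from_labels(.cc_label(mask, 8L), params)
}

smoothed_dapi <- function(stack, params) {
  dapi <- stack$channels$DAPI
  if (is.null(dapi)) stopf("stack has no DAPI channel")
  mx <- max_intensity(dapi$bit_depth)
  if (params$smoothing_sigma_px > 0) {
    sm <- from_ebi(EBImage::gblur(as_ebi(dapi$pixels, mx),
                                  sigma = params$smoothing_sigma_px))
    px <- clip(round(sm * mx), 0, mx)
  } else px <- dapi$pixels
  channel_image(px, "DAPI", dapi$bit_depth)
}

#' Segment nuclei from the DAPI channel
#'
#' The primary segmentation path: Gaussian smoothing, Otsu binarization,
#' morphological cleaning ([morph_clean()]) and 8-connected labeling with QC
#' flagging ([label_nuclei()]).
#'
#' @param stack a [channel_stack] with a DAPI channel.
#' @param params a [seg_params]; defaults to gates auto-scaled to the
#'   field's area.
#' @return List of `nucleus_region` objects.
#' @export
segment_dapi <- function(stack, params = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(params)) params <- seg_params(scale_to = c(stack$height, stack$width))
  sm <- smoothed_dapi(stack, params)
  label_nuclei(morph_clean(binarize(sm), params), params)
}

#' Segment nuclei with a marker-controlled watershed
#'
#' Baseline segmenter for comparison with [segment_dapi()]: Otsu
#' binarization, opening and hole filling (closing is deliberately omitted
#' here — it fattens the neck between touching nuclei and erases the
#' distance-map saddle the watershed relies on), then the Euclidean
#' distance transform is flooded from its regional maxima (minimum peak
#' separation = `morphology_radius_px`) so that touching nuclei are split
#' along watershed lines. QC flagging is identical to [label_nuclei()].
#'
#' @inheritParams segment_dapi
#' @return List of `nucleus_region` objects.
#' @export
segment_watershed <- function(stack, params = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(params)) params <- seg_params(scale_to = c(stack$height, stack$width))
  sm <- smoothed_dapi(stack, params)
  br <- disc_brush(params$morphology_radius_px)
  img <- EBImage::fillHull(EBImage::opening(as_ebi(binarize(sm) * 1), br))
  mask <- from_ebi(img) > 0.5
  lab0 <- .cc_label(mask, 8L)
  sizes <- tabulate(lab0[lab0 > 0L])
  drop <- which(sizes < params$min_area_px)
  if (length(drop)) mask[lab0 %in% drop] <- FALSE
  if (!any(mask)) return(list())
  dm <- EBImage::distmap(as_ebi(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = params$morphology_radius_px)
  lab <- from_ebi(ws)
  storage.mode(lab) <- "integer"
  regions_from_labels(lab, params)
}

#' Export regions as a data frame
#'
#' @param regions list of `nucleus_region` objects.
#' @param field_id optional field identifier column.
#' @return data.frame with label, centroid, area, solidity and flags.
#' @export
regions_table <- function(regions, field_id = NULL) {
  df <- data.frame(
    label = vapply(regions, function(r) r$label, integer(1)),
    centroid_row = vapply(regions, function(r) r$centroid[1], numeric(1)),
    centroid_col = vapply(regions, function(r) r$centroid[2], numeric(1)),
    area = vapply(regions, function(r) r$area, integer(1)),
    solidity = vapply(regions, function(r) r$solidity, numeric(1)),
    flags = vapply(regions, function(r) paste(r$qc_flags, collapse = ";"),
                   character(1)))
  if (!is.null(field_id)) df <- cbind(field_id = field_id, df)
  df
}
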