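#' Construct a single-channel image
#'
#' A `channel_image` is a 2-D integer raster with a declared fluorescence
#' role. Intensities are stored unscaled on the native integer range of the
#' declared bit depth (0..255 for 8-bit, 0..65535 for 16-bit). Coordinates
#' throughout the package are 0-based `(row, col)`.
#'
#' @param pixels numeric or integer matrix (rows = image rows).
#' @param role one of `"DAPI"`, `"CD45"`, `"CEP8"`, `"CEP17"`.
#' @param bit_depth 8 or 16.
#' @return A `channel_image` object.
#' @export
channel_image <- function(pixels, role, bit_depth = 8) {
  role <- match.arg(role, CHANNEL_ROLES)
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stopf("pixels must be a non-empty matrix")
  if (anyNA(pixels)) stopf("pixels contain NA")
  mx <- max_intensity(bit_depth)
  if (min(pixels) < 0 || max(pixels) > mx)
    stopf("intensities outside [0, %d] for bit depth %d", mx, bit_depth)
  structure(
    list(pixels = round(pixels), role = role, bit_depth = as.integer(bit_depth)),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> role=%s %dx%d %d-bit, intensity range [%d, %d]\n",
              x$role, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Bundle aligned channel images into a field stack
#'
#' A `channel_stack` holds one microscopy field: up to four aligned
#' single-channel images keyed by role. DAPI is required; CD45, CEP8 and
#' CEP17 are optional but needed for full rule-based calling. All present
#' channels must share dimensions.
#'
#' @param channels named list of [channel_image] objects (names = roles).
#' @param field_id character identifier for the field.
#' @return A `channel_stack` object with `height`/`width` in pixels.
#' @export
channel_stack <- function(channels, field_id = "field") {
  if (is.null(names(channels)) || !all(names(channels) %in% CHANNEL_ROLES))
    stopf("channels must be a named list with names among %s",
          paste(CHANNEL_ROLES, collapse = ", "))
  if (!"DAPI" %in% names(channels)) stopf("DAPI channel is required")
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- names(channels)[dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]]
    stopf("channel dimension mismatch (relative to %s): %s",
          names(channels)[1], paste(bad, collapse = ", "))
  }
  structure(list(field_id = field_id, channels = channels,
                 height = unname(dims[1, 1]), width = unname(dims[2, 1])),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> '%s' %dx%d, channels: %s\n", x$field_id,
              x$height, x$width, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a single-channel image file
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG. 16-bit intensities are
#' preserved without rescaling.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param role channel role to declare on the result.
#' @return A [channel_image].
#' @export
read_channel <- function(path, role) {
  role <- match.arg(role, CHANNEL_ROLES)
  if (!file.exists(path)) stopf("cannot read '%s': file does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
    if (length(dim(img)) == 3L)
      stopf("'%s' has %d channels; expected a single-channel image",
            path, dim(img)[3])
    channel_image(img, role, bit_depth = as.integer(bits))
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(img)) == 3L)
      stopf("'%s' has %d channels; expected a single-channel image",
            path, dim(img)[3])
    # readPNG scales to [0,1]; restore native integer range
    channel_image(round(img * max_intensity(bits)), role,
                  bit_depth = as.integer(bits))
  } else stopf("unsupported image format '%s' (use TIFF or PNG)", ext)
}

#' Write a channel image to disk
#'
#' Inverse of [read_channel()]: writes TIFF (8- or 16-bit) or PNG (8-bit),
#' preserving intensities bit-exactly. 16-bit rasters must go to TIFF.
#'
#' @param channel a [channel_image].
#' @param path destination path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_channel <- function(channel, path) {
  stopifnot(inherits(channel, "channel_image"))
  mx <- max_intensity(channel$bit_depth)
  scaled <- channel$pixels / mx
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = channel$bit_depth)
  } else if (ext == "png") {
    if (channel$bit_depth != 8L)
      stopf("PNG output is 8-bit; write %d-bit channels as TIFF",
            channel$bit_depth)
    png::writePNG(scaled, path)
  } else stopf("unsupported image format '%s'", ext)
  invisible(path)
}

#' Load a field from a JSON manifest
#'
#' The manifest format is
#' `{"field_id": "...", "channels": {"DAPI": "path", "CD45": "path", ...}}`.
#' Relative channel paths are resolved against the manifest's directory.
#' All channels are dimension-checked against each other.
#'
#' @param manifest path to a manifest JSON file, or an equivalent list.
#' @return A [channel_stack]; absent optional channels are recorded in
#'   `attr(, "missing_channels")`.
#' @export
load_field <- function(manifest) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- jsonlite::fromJSON(manifest)
  } else dir <- "."
  if (is.null(manifest$channels) || is.null(manifest$channels$DAPI))
    stopf("manifest must list a DAPI channel")
  chans <- lapply(names(manifest$channels), function(role) {
    p <- manifest$channels[[role]]
    if (!file.exists(p)) p <- file.path(dir, p)
    read_channel(p, role)
  })
  names(chans) <- names(manifest$channels)
  stack <- channel_stack(chans, field_id = manifest$field_id %||% "field")
  attr(stack, "missing_channels") <- setdiff(CHANNEL_ROLES, names(chans))
  stack
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hue windows for RGB composite decomposition
#'
#' Hue intervals (degrees, half-open, wrapping at 360) assigning composite
#' colors to channel roles: blue to DAPI, red to CD45, orange to CEP8,
#' green to CEP17. Red and orange are adjacent hues and cannot be separated
#' with slack: the CD45 window ends where the CEP8 window begins (15
#' degrees) so the defaults are pairwise disjoint. All windows are
#' configurable per acquisition.
#'
#' @return Named list of `c(start, end)` degree pairs.
#' @export
default_hue_windows <- function() {
  list(DAPI = c(200, 260), CD45 = c(330, 15), CEP8 = c(15, 45),
       CEP17 = c(90, 150))
}

hue_in_window <- function(h, win) {
  if (win[1] <= win[2]) h >= win[1] & h < win[2]
  else h >= win[1] | h < win[2]  # wraps through 0
}

#' Decompose an RGB composite into channel images by hue
#'
#' Splits a color composite into per-role grayscale channels: a pixel whose
#' hue falls in a role's window contributes its HSV value (scaled to the
#' output bit range) to that role's channel, and 0 elsewhere. Unsaturated
#' (gray) pixels carry no hue and are assigned to no role.
#'
#' @param rgb numeric array `height x width x 3` with values in \[0, 1\] or
#'   \[0, 255\].
#' @param hue_windows named list of degree intervals; see
#'   [default_hue_windows()]. Must be pairwise disjoint on the hue circle.
#' @param field_id field identifier for the resulting stack.
#' @return A [channel_stack] of 8-bit channels.
#' @export
decompose_composite <- function(rgb, hue_windows = default_hue_windows(),
                                field_id = "composite") {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stopf("rgb must be a height x width x 3 array")
  check_windows_disjoint(hue_windows)
  if (max(rgb) > 1) rgb <- rgb / 255
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]
  chans <- lapply(names(hue_windows), function(role) {
    sel <- hue_in_window(hue, hue_windows[[role]]) & sat > 0
    px <- matrix(ifelse(sel, round(val * 255), 0), nrow = h, ncol = w)
    channel_image(px, role, bit_depth = 8)
  })
  names(chans) <- names(hue_windows)
  channel_stack(chans, field_id = field_id)
}

check_windows_disjoint <- function(windows) {
  probe <- seq(0, 359.5, by = 0.5)
  hits <- vapply(windows, function(w) hue_in_window(probe, w), logical(length(probe)))
  if (any(rowSums(hits) > 1)) {
    deg <- probe[which(rowSums(hits) > 1)[1]]
    stopf("hue windows overlap (e.g. at %.1f degrees)", deg)
  }
  invisible(TRUE)
}

# Render a channel_stack as an RGB array in [0,1] using the display hues:
# DAPI -> blue, CD45 -> red, CEP8 -> orange, CEP17 -> green.
merge_channels_rgb <- function(stack) {
  grab <- function(role) {
    ch <- stack$channels[[role]]
    if (is.null(ch)) matrix(0, stack$height, stack$width)
    else ch$pixels / max_intensity(ch$bit_depth)
  }
  dapi <- grab("DAPI"); cd45 <- grab("CD45")
  cep8 <- grab("CEP8"); cep17 <- grab("CEP17")
  r <- clip(cd45 + cep8, 0, 1)
  g <- clip(cep17 + 0.5 * cep8, 0, 1)
  b <- clip(dapi, 0, 1)
  array(c(r, g, b), dim = c(stack$height, stack$width, 3))
}

#' Write an annotated overlay image
#'
#' Merges the stack's channels into an RGB image (DAPI blue, CD45 red, CEP8
#' orange, CEP17 green) and draws a red rectangle around the bounding box of
#' every CTC-positive call. Output bytes are deterministic for fixed input.
#'
#' @param stack a [channel_stack].
#' @param calls list of `cell_call` objects (see [classify_nucleus()]).
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(stack, calls, path) {
  rgb <- merge_channels_rgb(stack)
  for (call in calls) {
    bb <- call$nucleus$bbox
    if (bb[1] < 0 || bb[3] < 0 || bb[2] > stack$height || bb[4] > stack$width)
      stopf("call bounding box [%d,%d)x[%d,%d) outside field bounds",
            bb[1], bb[2], bb[3], bb[4])
    if (call$label != "CTC_POSITIVE") next
    r0 <- bb[1] + 1; r1 <- bb[2]; c0 <- bb[3] + 1; c1 <- bb[4]  # 1-based
    rows <- r0:r1; cols <- c0:c1
    rgb[c(r0, r1), cols, 1] <- 1; rgb[c(r0, r1), cols, 2:3] <- 0
    rgb[rows, c(c0, c1), 1] <- 1; rgb[rows, c(c0, c1), 2:3] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
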