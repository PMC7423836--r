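#' Spot detection parameters
#'
#' @param max_spot_radius_px disc radius of the white top-hat filter;
#'   FISH signal points larger than this are suppressed as background.
#'   Default 8 px, matching the observed upper bound of ~10 px on CTC
#'   feature sizes.
#' @param min_spot_area_px minimum connected-component area for a signal
#'   point.
#' @param margin_px the nucleus mask is dilated by this margin before spot
#'   search, so probe signals on the nuclear rim are not missed.
#' @param merge_rule how "the diameter of one point" is read for a pair of
#'   unequal spots when testing the merge distance: mean (default), min or
#'   max of the two equivalent diameters.
#' @return A `spot_params` list.
#' @export
spot_params <- function(max_spot_radius_px = 8, min_spot_area_px = 4,
                        margin_px = 5, merge_rule = c("mean", "min", "max")) {
  merge_rule <- match.arg(merge_rule)
  stopifnot(max_spot_radius_px >= 1, min_spot_area_px >= 1, margin_px >= 0)
  structure(list(max_spot_radius_px = max_spot_radius_px,
                 min_spot_area_px = min_spot_area_px,
                 margin_px = margin_px, merge_rule = merge_rule),
            class = "spot_params")
}

signal_point <- function(centroid, area, channel, peak_intensity) {
  structure(list(centroid = centroid, area = area,
                 equiv_diameter = 2 * sqrt(area / pi),
                 channel = channel, peak_intensity = peak_intensity),
            class = "signal_point")
}

points_order <- function(points) {
  r <- vapply(points, function(p) p$centroid[1], numeric(1))
  c <- vapply(points, function(p) p$centroid[2], numeric(1))
  order(r, c)
}

#' Detect FISH signal points within a nucleus
#'
#' Within the nucleus mask dilated by `margin_px`: a white top-hat filter
#' (disc of radius `max_spot_radius_px`) isolates compact bright features,
#' the top-hat response restricted to the region is Otsu-thresholded, and
#' 8-connected components with at least `min_spot_area_px` pixels become
#' signal points. Returns the raw (pre-merge) list sorted by (row, col).
#'
#' @param channel a [channel_image] with role CEP8 or CEP17.
#' @param region a `nucleus_region`.
#' @param params a [spot_params].
#' @return List of `signal_point` objects.
#' @export
detect_spots <- function(channel, region, params = spot_params()) {
  stopifnot(inherits(channel, "channel_image"), inherits(region, "nucleus_region"))
  if (!channel$role %in% c("CEP8", "CEP17"))
    stopf("detect_spots expects a CEP8 or CEP17 channel, got %s", channel$role)
  h <- region$dim[1]; w <- region$dim[2]
  if (nrow(channel$pixels) != h || ncol(channel$pixels) != w)
    stopf("channel and region dimensions differ")
  pad <- params$margin_px + params$max_spot_radius_px + 1
  r0 <- max(region$bbox[1] - pad, 0); r1 <- min(region$bbox[2] + pad, h)
  c0 <- max(region$bbox[3] - pad, 0); c1 <- min(region$bbox[4] + pad, w)
  crop <- channel$pixels[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  mask <- region_mask(region)[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  if (params$margin_px > 0)
    mask <- from_ebi(EBImage::dilate(as_ebi(mask * 1),
                                     disc_brush(params$margin_px))) > 0.5
  mx <- max_intensity(channel$bit_depth)
  th_img <- from_ebi(EBImage::whiteTopHat(as_ebi(crop, mx),
                                          disc_brush(params$max_spot_radius_px)))
  th_img <- clip(round(th_img * mx), 0, mx)
  vals <- th_img[mask]
  if (!length(vals)) return(list())
  cut <- otsu_threshold(vals, channel$bit_depth)
  if (is.na(cut)) return(list())
  fg <- th_img > cut & mask
  lab <- .cc_label(fg, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  pts <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) < params$min_spot_area_px) next
    rows <- (idx - 1L) %% nrow(lab) + r0   # 0-based absolute rows
    cols <- (idx - 1L) %/% nrow(lab) + c0
    peak <- max(channel$pixels[cbind(rows + 1L, cols + 1L)])
    pts[[length(pts) + 1L]] <-
      signal_point(c(mean(rows), mean(cols)), length(idx), channel$role, peak)
  }
  pts[points_order(pts)]
}

merge_distance <- function(d1, d2, rule) {
  switch(rule, mean = (d1 + d2) / 2, min = min(d1, d2), max = max(d1, d2))
}

#' Merge nearby signal points into single signals
#'
#' Two signal points closer (centroid Euclidean distance) than one spot
#' diameter are regarded as a single point. For unequal spots the diameter
#' is taken as the mean of the pair's equivalent diameters by default
#' (`merge_rule`). Merging is transitive: connected components of the
#' "closer than one diameter" graph each collapse to one point with summed
#' area, area-weighted centroid and recomputed equivalent diameter; because
#' a collapsed point has a larger diameter than its members, the collapse
#' repeats until no further pair qualifies, so the operation is idempotent
#' and permutation-invariant.
#'
#' @param points list of `signal_point`s from one nucleus and one channel.
#' @param params a [spot_params] (for `merge_rule`).
#' @return List of merged `signal_point`s sorted by (row, col).
#' @export
merge_spots <- function(points, params = spot_params()) {
  repeat {
    merged <- merge_spots_once(points, params)
    if (length(merged) == length(points)) return(merged)
    points <- merged
  }
}

merge_spots_once <- function(points, params) {
  n <- length(points)
  if (n <= 1L) return(points[points_order(points)])
  chans <- unique(vapply(points, function(p) p$channel, character(1)))
  if (length(chans) > 1L)
    stopf("merge_spots expects points from a single channel, got %s",
          paste(chans, collapse = ", "))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((points[[i]]$centroid - points[[j]]$centroid)^2))
    lim <- merge_distance(points[[i]]$equiv_diameter,
                          points[[j]]$equiv_diameter, params$merge_rule)
    if (d < lim) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), comp), function(ids) {
    areas <- vapply(points[ids], function(p) p$area, numeric(1))
    cents <- t(vapply(points[ids], function(p) p$centroid, numeric(2)))
    signal_point(colSums(cents * areas) / sum(areas), sum(areas),
                 points[[ids[1]]]$channel,
                 max(vapply(points[ids], function(p) p$peak_intensity, numeric(1))))
  })
  merged <- unname(merged)
  merged[points_order(merged)]
}

#' Count FISH signals of one probe in a nucleus
#'
#' Detected spots ([detect_spots()]) after merge ([merge_spots()]). When the
#' requested probe channel is absent from the stack the count is
#' *unavailable* and `NA_integer_` is returned — never 0, so a missing probe
#' cannot silently read as a diploid signal count.
#'
#' @param stack a [channel_stack].
#' @param region a `nucleus_region`.
#' @param channel_role `"CEP8"` or `"CEP17"`.
#' @param params a [spot_params].
#' @return Integer count, or `NA_integer_` if the channel is absent.
#' @export
count_signals <- function(stack, region, channel_role, params = spot_params()) {
  channel_role <- match.arg(channel_role, c("CEP8", "CEP17"))
  ch <- stack$channels[[channel_role]]
  if (is.null(ch)) return(NA_integer_)
  length(merge_spots(detect_spots(ch, region, params), params))
}

#' Tabulate signal points
#'
#' @param points list of `signal_point`s.
#' @param field_id,nucleus_label optional identifier columns.
#' @return data.frame with one row per point.
#' @export
spots_table <- function(points, field_id = NULL, nucleus_label = NULL) {
  df <- data.frame(
    channel = vapply(points, function(p) p$channel, character(1)),
    row = vapply(points, function(p) p$centroid[1], numeric(1)),
    col = vapply(points, function(p) p$centroid[2], numeric(1)),
    area = vapply(points, function(p) p$area, numeric(1)),
    equiv_diameter = vapply(points, function(p) p$equiv_diameter, numeric(1)))
  if (!is.null(nucleus_label)) df <- cbind(nucleus_label = nucleus_label, df)
  if (!is.null(field_id)) df <- cbind(field_id = field_id, df)
  df
}
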