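#' Simulation parameters for synthetic imFISH fields
#'
#' The simulator emulates the imaging regime of the pipeline's inputs:
#' elliptical DAPI-bright nuclei, CD45-stained leukocytes, per-nucleus
#' CEP8/CEP17 probe spots (hyperdiploid cells carry >= 3 signals per probe,
#' normal diploid cells 1-2), additive Gaussian noise, and optional
#' deliberately overlapping nuclei. All randomness flows from `seed`.
#'
#' Nucleus profiles have a flat core with a Gaussian shoulder (so the
#' rendered ground-truth boundary is sharp enough for IoU comparison);
#' spots are Gaussian blobs placed on a jittered ring inside the nucleus,
#' which guarantees pairwise separation above the merge distance unless
#' `confluent_spots` is set.
#'
#' @param height,width field size in pixels (desk scale 512 x 512; set
#'   2728 x 2192 for native-scale fields).
#' @param n_cells number of cells per field.
#' @param ctc_fraction fraction of cells that are hyperdiploid CTCs.
#' @param leukocyte_fraction fraction that are CD45-positive leukocytes
#'   (`ctc_fraction + leukocyte_fraction <= 1`; the remainder are
#'   CD45-negative diploid cells).
#' @param nucleus_radius_px `c(mean, sd)` of the nucleus semi-major axis.
#' @param spot_count_ctc integer support for per-probe signal counts of CTC
#'   cells (all values >= 3 so labels are consistent with the caller rule).
#' @param spot_count_normal support for diploid cells (values in 1..2).
#' @param spot_radius_px nominal spot radius.
#' @param spot_intensity,dapi_intensity peak intensities (channel units).
#' @param cd45_positive_intensity,cd45_negative_intensity CD45 staining
#'   intensity for leukocytes / background level elsewhere.
#' @param noise_sigma additive Gaussian noise, clipped to the bit range.
#' @param overlap_fraction fraction of cells rendered overlapping a
#'   neighbouring nucleus (for watershed exercises).
#' @param confluent_spots place one spot pair closer than the merge
#'   distance (to exercise the merge rule; ground-truth counts then refer
#'   to rendered, pre-merge spots).
#' @param bit_depth channel bit depth.
#' @param seed integer RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(height = 512, width = 512, n_cells = 30,
                       ctc_fraction = 0.3, leukocyte_fraction = 0.4,
                       nucleus_radius_px = c(16, 2.5),
                       spot_count_ctc = 3:6, spot_count_normal = 1:2,
                       spot_radius_px = 2, spot_intensity = 220,
                       dapi_intensity = 200,
                       cd45_positive_intensity = 180,
                       cd45_negative_intensity = 8,
                       noise_sigma = 4, overlap_fraction = 0,
                       confluent_spots = FALSE, bit_depth = 8, seed = 1) {
  stopifnot(ctc_fraction >= 0, ctc_fraction <= 1,
            leukocyte_fraction >= 0, ctc_fraction + leukocyte_fraction <= 1,
            all(spot_count_ctc >= 3), all(spot_count_normal %in% 1:2),
            overlap_fraction >= 0, overlap_fraction <= 1, n_cells >= 0)
  structure(as.list(environment()), class = "sim_params")
}

# Fold 1-based indices into [1, n] by mirror reflection (for crop padding).
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

# Soft-edged elliptical profile: 1 inside q <= core, Gaussian shoulder
# beyond; ~0 past q = 1.4.
soft_profile <- function(q, core = 0.7, shoulder = 0.25) {
  out <- exp(-pmax(q - core, 0)^2 / (2 * shoulder^2))
  out[q > 1.6] <- 0
  out
}

# Normalized elliptical radius of grid points around a center.
ellipse_q <- function(rows, cols, center, a, b, theta) {
  dr <- rows - center[1]; dc <- cols - center[2]
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  sqrt(u^2 + v^2)
}

place_cells <- function(params) {
  n <- params$n_cells
  if (n == 0L) return(list())
  rmean <- params$nucleus_radius_px[1]; rsd <- params$nucleus_radius_px[2]
  n_overlap <- round(params$overlap_fraction * n)
  cells <- list()
  for (i in seq_len(n)) {
    a <- max(8, rnorm(1, rmean, rsd))
    b <- a * runif(1, 0.75, 1)
    theta <- runif(1, 0, pi)
    margin <- 1.4 * a + 2
    overlapping <- i > 1 && i <= n_overlap + 1 && n_overlap > 0 &&
      i %% 2 == 0  # pair overlap cells with the previous placement
    placed <- FALSE
    for (attempt in 1:200) {
      if (overlapping) {
        partner <- cells[[i - 1]]
        ang <- runif(1, 0, 2 * pi)
        d <- 1.8 * (a + partner$a) / 2   # overlap ~20% of a radius
        center <- partner$center + d * c(cos(ang), sin(ang))
        if (any(center < margin) || center[1] > params$height - margin ||
            center[2] > params$width - margin) next
        ok <- TRUE
        if (i > 2) for (j in seq_len(i - 2)) {
          dj <- sqrt(sum((center - cells[[j]]$center)^2))
          if (dj < 1.35 * (a + cells[[j]]$a) + 14) { ok <- FALSE; break }
        }
        if (!ok) next
      } else {
        center <- c(runif(1, margin, params$height - margin),
                    runif(1, margin, params$width - margin))
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          dj <- sqrt(sum((center - cells[[j]]$center)^2))
          # clearance beyond the boundary gap: smoothing plus a closing
          # disc can bridge gaps up to ~2x the morphology radius
          if (dj < 1.35 * (a + cells[[j]]$a) + 14) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("could not place %d cells in a %dx%d field (packing infeasible)",
            n, params$height, params$width)
    cells[[i]] <- list(center = center, a = a, b = b, theta = theta,
                       overlapped = overlapping)
    if (overlapping) cells[[i - 1]]$overlapped <- TRUE
  }
  cells
}

# Ring placement of k spot centers inside the nucleus. The ring radius is
# floored so the chord between neighbours stays above the merge distance
# of detected spots (~one detected diameter, with margin) for k <= 6.
spot_centers <- function(k, cell, params) {
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  m <- min(cell$a, cell$b)
  rho <- 0.55 * m
  if (k == 1L) {
    jit <- runif(2, -0.15, 0.15) * rho
    return(matrix(cell$center + jit, 1, 2))
  }
  min_chord <- 2.3 * params$spot_radius_px + 1.5
  rho <- min(max(rho, min_chord / (2 * sin(pi / k))), 0.9 * m)
  ang <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi)
  jitter <- runif(k, -0.04, 0.04) * rho
  cbind(cell$center[1] + (rho + jitter) * cos(ang),
        cell$center[2] + (rho + jitter) * sin(ang))
}

render_blob <- function(img, center, sigma, amplitude) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sigma)
  r0 <- max(1, floor(center[1] + 1 - ext)); r1 <- min(h, ceiling(center[1] + 1 + ext))
  c0 <- max(1, floor(center[2] + 1 - ext)); c1 <- min(w, ceiling(center[2] + 1 + ext))
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - 1 - center[1]; dc <- cols - 1 - center[2]
  g <- amplitude * exp(-(outer(dr^2, dc^2, "+")) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

#' Simulate one synthetic imFISH field with ground truth
#'
#' Renders a four-channel field (DAPI, CD45, CEP8, CEP17) and its exact
#' ground truth. Each ground-truth cell's `true_label` is computed by
#' applying the rule-based caller's classification to the cell's true
#' features under default [caller_params()], so generator and rule agree by
#' construction. Fully determined by `params$seed`.
#'
#' @param params a [sim_params].
#' @param field_id identifier for the resulting stack.
#' @return List with elements `stack` (a [channel_stack]) and `truth`
#'   (list of `ground_truth_cell` objects).
#' @export
simulate_field <- function(params = sim_params(), field_id = "synthetic") {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_field_impl(params, field_id))
}

simulate_field_impl <- function(params, field_id) {
  h <- params$height; w <- params$width
  mx <- max_intensity(params$bit_depth)
  dapi <- matrix(0, h, w); cd45 <- matrix(params$cd45_negative_intensity, h, w)
  cep8 <- matrix(0, h, w); cep17 <- matrix(0, h, w)
  cells <- place_cells(params)
  n <- length(cells)
  n_ctc <- round(params$ctc_fraction * n)
  n_leuk <- round(params$leukocyte_fraction * n)
  classes <- sample(c(rep("CTC", n_ctc), rep("LEUK", n_leuk),
                      rep("NORMAL", n - n_ctc - n_leuk)))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- cells[[i]]; cls <- classes[i]
    ext <- ceiling(1.7 * cell$a)
    r0 <- max(1, floor(cell$center[1] + 1 - ext))
    r1 <- min(h, ceiling(cell$center[1] + 1 + ext))
    c0 <- max(1, floor(cell$center[2] + 1 - ext))
    c1 <- min(w, ceiling(cell$center[2] + 1 + ext))
    rows <- r0:r1; cols <- c0:c1
    rr <- matrix(rows - 1, length(rows), length(cols))
    cc <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
    q <- ellipse_q(rr, cc, cell$center, cell$a, cell$b, cell$theta)
    dapi[rows, cols] <- dapi[rows, cols] +
      params$dapi_intensity * soft_profile(q)
    mask_idx <- which(q <= 1)
    abs_idx <- (cols[(mask_idx - 1L) %/% length(rows) + 1L] - 1L) * h +
      rows[(mask_idx - 1L) %% length(rows) + 1L]
    cd45_pos <- cls == "LEUK"
    if (cd45_pos) {
      qc <- ellipse_q(rr, cc, cell$center, 1.15 * cell$a, 1.15 * cell$b,
                      cell$theta)
      cd45[rows, cols] <- cd45[rows, cols] +
        params$cd45_positive_intensity * soft_profile(qc)
    }
    counts <- if (cls == "CTC") params$spot_count_ctc else params$spot_count_normal
    k8 <- if (length(counts) == 1L) counts else sample(counts, 1)
    k17 <- if (length(counts) == 1L) counts else sample(counts, 1)
    s8 <- spot_centers(k8, cell, params)
    s17 <- spot_centers(k17, cell, params)
    if (isTRUE(params$confluent_spots) && k8 >= 2) {
      # shove the second spot next to the first, inside the merge distance
      s8[2, ] <- s8[1, ] + c(0, 1.2 * params$spot_radius_px)
    }
    sig <- params$spot_radius_px / 2
    for (s in seq_len(nrow(s8)))
      cep8 <- render_blob(cep8, s8[s, ], sig, params$spot_intensity)
    for (s in seq_len(nrow(s17)))
      cep17 <- render_blob(cep17, s17[s, ], sig, params$spot_intensity)
    feats <- cell_features(TRUE, if (cd45_pos) 1 else 0, k8, k17)
    truth[[i]] <- structure(list(
      cell_id = i, centroid = cell$center, pixels = abs_idx, dim = c(h, w),
      a = cell$a, b = cell$b, theta = cell$theta,
      cd45_positive = cd45_pos, true_cep8_count = k8, true_cep17_count = k17,
      spots = list(CEP8 = s8, CEP17 = s17),
      true_label = classify_nucleus(feats)$label,
      overlapped = isTRUE(cell$overlapped)), class = "ground_truth_cell")
  }
  finish <- function(m) {
    if (params$noise_sigma > 0)
      m <- m + matrix(rnorm(h * w, 0, params$noise_sigma), h, w)
    round(clip(m, 0, mx))
  }
  stack <- channel_stack(list(
    DAPI = channel_image(finish(dapi), "DAPI", params$bit_depth),
    CD45 = channel_image(finish(cd45), "CD45", params$bit_depth),
    CEP8 = channel_image(finish(cep8), "CEP8", params$bit_depth),
    CEP17 = channel_image(finish(cep17), "CEP17", params$bit_depth)),
    field_id = field_id)
  list(stack = stack, truth = truth)
}

#' Ground truth as a data frame
#'
#' @param truth list of `ground_truth_cell`s (from [simulate_field()]).
#' @param field_id optional identifier column.
#' @return data.frame, one row per cell.
#' @export
truth_table <- function(truth, field_id = NULL) {
  df <- data.frame(
    cell_id = vapply(truth, function(x) x$cell_id, integer(1)),
    centroid_row = vapply(truth, function(x) x$centroid[1], numeric(1)),
    centroid_col = vapply(truth, function(x) x$centroid[2], numeric(1)),
    label = vapply(truth, function(x) x$true_label, character(1)),
    cd45 = vapply(truth, function(x) x$cd45_positive, logical(1)),
    cep8_count = vapply(truth, function(x) x$true_cep8_count, integer(1)),
    cep17_count = vapply(truth, function(x) x$true_cep17_count, integer(1)),
    overlapped = vapply(truth, function(x) x$overlapped, logical(1)))
  if (!is.null(field_id)) df <- cbind(field_id = field_id, df)
  df
}

#' Simulate a multi-field dataset
#'
#' Per-field seeds are derived deterministically from the master seed. When
#' `out_dir` is given, per-channel TIFFs, [load_field()]-compatible JSON
#' manifests and a ground-truth CSV are written there.
#'
#' @param n_fields number of fields.
#' @param params a [sim_params] (its `seed` is ignored in favour of `seed`).
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return List with `fields` (list of `simulate_field()` results),
#'   `manifests` (paths or `NULL`) and `truth` (combined data.frame).
#' @export
simulate_dataset <- function(n_fields, params = sim_params(), seed = 1,
                             out_dir = NULL) {
  stopifnot(n_fields >= 1)
  seeds <- derive_seeds(seed, n_fields)
  fields <- vector("list", n_fields)
  manifests <- if (is.null(out_dir)) NULL else character(n_fields)
  truths <- vector("list", n_fields)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_fields)) {
    p <- params; p$seed <- seeds[i]
    fid <- sprintf("field_%03d", i)
    fields[[i]] <- simulate_field(p, field_id = fid)
    truths[[i]] <- truth_table(fields[[i]]$truth, field_id = fid)
    if (!is.null(out_dir)) {
      paths <- list()
      for (role in names(fields[[i]]$stack$channels)) {
        fp <- file.path(out_dir, sprintf("%s_%s.tif", fid, role))
        write_channel(fields[[i]]$stack$channels[[role]], fp)
        paths[[role]] <- basename(fp)
      }
      mp <- file.path(out_dir, sprintf("%s.json", fid))
      jsonlite::write_json(list(field_id = fid, channels = paths), mp,
                           auto_unbox = TRUE)
      manifests[i] <- mp
    }
  }
  truth <- do.call(rbind, truths)
  if (!is.null(out_dir))
    write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  list(fields = fields, manifests = manifests, truth = truth)
}

#' Build a labeled crop benchmark
#'
#' Generates a crop-level dataset with exact class counts by simulating one
#' small field per cell and cropping around the ground-truth nucleus.
#' Difficulty tiers: `"easy"` (noise-free, separated cells), `"noisy"`
#' (high additive noise), `"overlapping"` (a second nucleus overlaps the
#' focal cell in 20% of crops). Negatives are an even mix of leukocytes and
#' CD45-negative diploid cells.
#'
#' @param n_pos,n_neg class counts (positives are hyperdiploid CTCs).
#' @param difficulty one of `"easy"`, `"noisy"`, `"overlapping"`.
#' @param seed master seed.
#' @param size_px crop side length after resizing.
#' @param field_px side of the per-cell mini-field.
#' @return A `crop_dataset`: list with `crops` (array
#'   `size_px x size_px x 4 x n`, intensities in \[0, 1\]), `labels`
#'   (factor with levels CTC_POSITIVE/CTC_NEGATIVE) and `meta`
#'   (data.frame).
#' @export
make_benchmark <- function(n_pos, n_neg, difficulty = c("easy", "noisy",
                                                        "overlapping"),
                           seed = 1, size_px = 64, field_px = 128) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_pos >= 1, n_neg >= 1)
  n <- n_pos + n_neg
  labels <- rep(c("CTC_POSITIVE", "CTC_NEGATIVE"), c(n_pos, n_neg))
  noise <- switch(difficulty, easy = 0, noisy = 12, overlapping = 4)
  seeds <- derive_seeds(seed, n)
  crops <- array(0, dim = c(size_px, size_px, 4L, n))
  meta <- vector("list", n)
  sp <- seg_params(scale_to = c(field_px, field_px))
  for (i in seq_len(n)) {
    pos <- labels[i] == "CTC_POSITIVE"
    overlap <- difficulty == "overlapping" && (seeds[i] %% 5 == 0)
    p <- sim_params(
      height = field_px, width = field_px,
      n_cells = if (overlap) 2L else 1L,
      ctc_fraction = if (pos) 1 else 0,
      # negatives alternate leukocyte / plain diploid
      leukocyte_fraction = if (pos) 0 else (i %% 2),
      nucleus_radius_px = c(14, 2),
      noise_sigma = noise,
      overlap_fraction = if (overlap) 1 else 0,
      seed = seeds[i])
    if (overlap) p$leukocyte_fraction <- if (pos) 0 else 0.5
    fld <- simulate_field(p, field_id = sprintf("bench_%05d", i))
    # focal cell: the one whose label matches the requested class
    want <- if (pos) "CTC_POSITIVE" else "CTC_NEGATIVE"
    focal <- which(vapply(fld$truth, function(x) x$true_label, character(1)) ==
                     want)[1]
    gt <- fld$truth[[focal]]
    region <- new_region(1L, gt$pixels, gt$dim, sp)
    crop <- extract_crops(fld$stack, list(region), size_px = size_px)[[1]]
    crops[, , , i] <- crop$pixels
    meta[[i]] <- data.frame(index = i, label = want, cd45 = gt$cd45_positive,
                            cep8 = gt$true_cep8_count,
                            cep17 = gt$true_cep17_count,
                            overlapped = gt$overlapped, seed = seeds[i])
  }
  structure(list(crops = crops,
                 labels = factor(labels, levels = c("CTC_POSITIVE",
                                                    "CTC_NEGATIVE")),
                 meta = do.call(rbind, meta), difficulty = difficulty,
                 size_px = size_px),
            class = "crop_dataset")
}

#' @export
print.crop_dataset <- function(x, ...) {
  cat(sprintf("<crop_dataset> %d crops (%d positive / %d negative), %dx%d, tier '%s'\n",
              length(x$labels), sum(x$labels == "CTC_POSITIVE"),
              sum(x$labels == "CTC_NEGATIVE"), x$size_px, x$size_px,
              x$difficulty))
  invisible(x)
}
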