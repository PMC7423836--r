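test_that("luminance conversion applies the BT.601 weights", {
  mk <- function(r, g, b) array(rep(c(r, g, b), each = 4), c(2, 2, 3))
  expect_true(all(to_gray(mk(0, 0, 0))$pixels == 0))
  expect_true(all(to_gray(mk(255, 255, 255))$pixels == 255))
  expect_true(all(to_gray(mk(100, 0, 0))$pixels == 30))  # round(29.9)
  expect_error(to_gray(array(0, c(2, 2, 4))), "3")
})

test_that("Sobel magnitude is zero on flat fields and 4h on a step edge", {
  flat <- channel_image(matrix(37, 12, 12), "DAPI", 8)
  expect_true(all(gradient_magnitude(flat)$pixels == 0))
  h <- 20
  step <- matrix(0, 16, 16); step[, 9:16] <- h
  g <- gradient_magnitude(channel_image(step, "DAPI", 8))
  expect_true(all(g$pixels[2:15, 9] == 4 * h))   # interior of the edge column
  expect_true(all(g$pixels[, c(3:6, 12:15)] == 0))
  gt <- gradient_magnitude(channel_image(t(step), "DAPI", 8))
  expect_equal(gt$pixels, t(g$pixels), ignore_attr = TRUE)
})

test_that("Otsu matches exhaustive between-class-variance maximization", {
  # forced bimodal case
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  th <- otsu_threshold(img, 8)
  expect_gt(th, 10 - 1); expect_lt(th, 200)
  m <- binarize(channel_image(img, "DAPI", 8))
  expect_equal(sum(m), 50)
  expect_true(all(img[m] == 200))
  # degenerate constant image
  expect_true(is.na(otsu_threshold(matrix(7, 5, 5), 8)))
  expect_false(any(binarize(channel_image(matrix(7, 5, 5), "DAPI", 8))))
  # three-level image with known counts
  v3 <- c(rep(0, 37), rep(100, 41), rep(200, 22))
  expect_equal(otsu_threshold(v3, 8), otsu_brute(v3, 8))
  # random histograms against the brute-force oracle
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    v <- sample(0:255, n, replace = TRUE, prob = runif(256)^3)
    expect_equal(otsu_threshold(v, 8), otsu_brute(v, 8))
  }
})

test_that("morphological cleaning removes specks, fills holes, and is idempotent", {
  p <- seg_params(min_area_px = 5, max_area_px = 5000,
                  morphology_radius_px = 2)
  m <- matrix(FALSE, 40, 40); m[10, 10] <- TRUE   # isolated pixel
  expect_false(any(morph_clean(m, p)))
  disk <- disk_mask(60, 60, cbind(30, 30), 20)
  holed <- disk; holed[29:31, 29:31] <- FALSE
  cleaned <- morph_clean(holed, p)
  expect_true(all(cleaned[29:31, 29:31]))          # hole filled
  expect_gt(sum(cleaned & disk) / sum(cleaned | disk), 0.97)
  # idempotence on random blobby masks
  set.seed(21)
  for (i in 1:8) {
    centers <- cbind(sample(10:70, 4), sample(10:70, 4))
    blob <- disk_mask(80, 80, centers, sample(4:9, 1))
    blob[sample(6400, 150)] <- TRUE                # salt noise
    once <- morph_clean(blob, p)
    expect_identical(morph_clean(once, p), once)
  }
})

test_that("labeling orders regions by raster scan and flags QC failures", {
  p <- seg_params(min_area_px = 10, max_area_px = 400, min_solidity = 0.85)
  m <- disk_mask(60, 80, rbind(c(40, 10), c(12, 50)), 6)
  regs <- label_nuclei(m, p)
  expect_length(regs, 2)
  expect_equal(vapply(regs, function(r) r$label, integer(1)), 1:2)
  # raster order: the (12,50) disk starts on an earlier row
  expect_lt(regs[[1]]$centroid[1], regs[[2]]$centroid[1])
  expect_true(all(!vapply(regs, function(r) r$excluded, logical(1))))
  expect_length(label_nuclei(matrix(FALSE, 10, 10), p), 0)
  # heavily overlapping disks form a low-solidity dumbbell
  dumb <- disk_mask(60, 80, rbind(c(30, 25), c(30, 43)), 10)
  regs2 <- label_nuclei(dumb, p)
  expect_length(regs2, 1)
  expect_true("AGGREGATED" %in% regs2[[1]]$qc_flags ||
                "TOO_LARGE" %in% regs2[[1]]$qc_flags)
  expect_true(regs2[[1]]$excluded)
  # area gates
  tiny <- label_nuclei(disk_mask(30, 30, cbind(15, 15), 1.5),
                       seg_params(min_area_px = 50, max_area_px = 400))
  expect_true("TOO_SMALL" %in% tiny[[1]]$qc_flags)
})

test_that("region masks are disjoint, in-bounds, and deterministic", {
  sim <- simulate_field(sim_params(n_cells = 8, seed = 31))
  for (f in list(segment_dapi, segment_watershed)) {
    regs <- f(sim$stack)
    all_pix <- unlist(lapply(regs, function(r) r$pixels))
    expect_equal(length(all_pix), length(unique(all_pix)))
    expect_true(all(all_pix >= 1 & all_pix <= 512 * 512))
    regs2 <- f(sim$stack)
    expect_identical(regions_table(regs2), regions_table(regs))
  }
})

test_that("DAPI segmentation recovers noise-free nuclei with IoU >= 0.7", {
  sim <- simulate_field(sim_params(n_cells = 5, noise_sigma = 0, seed = 41))
  regs <- segment_dapi(sim$stack)
  expect_length(regs, 5)
  expect_true(all(!vapply(regs, function(r) r$excluded, logical(1))))
  for (gt in sim$truth) expect_gte(iou_best(gt, regs), 0.7)
  # blank field
  blank <- channel_stack(list(DAPI = channel_image(matrix(0, 64, 64), "DAPI")))
  expect_length(segment_dapi(blank), 0)
  expect_length(segment_watershed(blank), 0)
  nodapi <- blank
  nodapi$channels$DAPI <- NULL
  expect_error(segment_dapi(nodapi), "DAPI")
})

test_that("border-clipped nuclei are flagged when exclusion is on", {
  px <- matrix(0, 100, 100)
  px[disk_mask(100, 100, cbind(2, 50), 12)] <- 200
  stack <- channel_stack(list(DAPI = channel_image(px, "DAPI")))
  p <- seg_params(min_area_px = 20, max_area_px = 5000, exclude_border = TRUE)
  regs <- segment_dapi(stack, p)
  expect_length(regs, 1)
  expect_true("TOUCHES_BORDER" %in% regs[[1]]$qc_flags)
  p2 <- seg_params(min_area_px = 20, max_area_px = 5000, exclude_border = FALSE)
  expect_false("TOUCHES_BORDER" %in% segment_dapi(stack, p2)[[1]]$qc_flags)
})

test_that("watershed splits touching nuclei that the plain path merges", {
  sim <- simulate_field(sim_params(n_cells = 8, noise_sigma = 0,
                                   overlap_fraction = 0.5, seed = 51))
  plain <- segment_dapi(sim$stack)
  ws <- segment_watershed(sim$stack)
  expect_gt(length(ws), length(plain))
  expect_equal(length(ws), 8)
  # agreement for well-separated fields
  sim2 <- simulate_field(sim_params(n_cells = 6, noise_sigma = 0, seed = 52))
  expect_equal(length(segment_watershed(sim2$stack)),
               length(segment_dapi(sim2$stack)))
})
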