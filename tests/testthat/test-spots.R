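make_spot_field <- function(spots8, h = 96, w = 96, nucleus_center = c(48, 48),
                            nucleus_radius = 24, amplitude = 220) {
  cep8 <- matrix(0, h, w)
  for (i in seq_len(nrow(spots8)))
    cep8 <- ctcscope:::render_blob(cep8, spots8[i, ], 1, amplitude)
  dapi <- matrix(0, h, w)
  dapi[disk_mask(h, w, rbind(nucleus_center), nucleus_radius)] <- 200
  stack <- channel_stack(list(
    DAPI = channel_image(dapi, "DAPI"),
    CEP8 = channel_image(round(pmin(cep8, 255)), "CEP8")))
  region <- label_nuclei(dapi > 0, seg_params(min_area_px = 50,
                                              max_area_px = 5000))[[1]]
  list(stack = stack, region = region)
}

test_that("spot detection finds rendered spots at their centroids", {
  centers <- rbind(c(38, 40), c(48, 58), c(60, 44))
  f <- make_spot_field(centers)
  pts <- detect_spots(f$stack$channels$CEP8, f$region)
  expect_length(pts, 3)
  found <- t(vapply(pts, function(p) p$centroid, numeric(2)))
  ord <- order(centers[, 1], centers[, 2])
  expect_true(all(abs(found - centers[ord, ]) <= 1))
  expect_true(all(vapply(pts, function(p) p$area, numeric(1)) >= 4))
  # a zero channel yields nothing
  z <- channel_image(matrix(0, 96, 96), "CEP8")
  expect_length(detect_spots(z, f$region), 0)
  # spots outside the dilated region mask are not returned
  far <- make_spot_field(rbind(c(48, 48), c(10, 88)))
  pts2 <- detect_spots(far$stack$channels$CEP8, far$region)
  expect_length(pts2, 1)
  expect_true(all(abs(pts2[[1]]$centroid - c(48, 48)) <= 1))
  expect_error(detect_spots(f$stack$channels$DAPI, f$region), "CEP8 or CEP17")
})

test_that("the merge rule collapses close pairs and leaves distant ones", {
  # distance 3 < diameter 5: one merged point at the midpoint
  pts <- make_points(rbind(c(0, 0), c(3, 0)), areas = rep(pi * 2.5^2, 2))
  m <- merge_spots(pts)
  expect_length(m, 1)
  expect_equal(m[[1]]$centroid, c(1.5, 0))
  expect_equal(m[[1]]$area, 2 * pi * 2.5^2)
  expect_equal(m[[1]]$equiv_diameter, 2 * sqrt(m[[1]]$area / pi))
  # distance 10 >= diameter 5: unchanged
  far <- make_points(rbind(c(0, 0), c(10, 0)), areas = rep(pi * 2.5^2, 2))
  expect_length(merge_spots(far), 2)
  # chain merges transitively into one point
  chain <- make_points(rbind(c(0, 0), c(4, 0), c(8, 0)),
                       areas = rep(pi * 2.5^2, 3))
  expect_length(merge_spots(chain), 1)
  # mixed channels are rejected
  bad <- c(make_points(rbind(c(0, 0)), 10, "CEP8"),
           make_points(rbind(c(1, 0)), 10, "CEP17"))
  expect_error(merge_spots(bad), "single channel")
})

test_that("merging agrees with the brute-force transitive-closure oracle", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(1:10, 1)
    cents <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    areas <- runif(n, 3, 60)
    rule <- sample(c("mean", "min", "max"), 1)
    got <- merge_spots(make_points(cents, areas),
                       spot_params(merge_rule = rule))
    want <- merge_brute(cents, areas, rule)
    expect_equal(length(got), nrow(want))
    gc <- t(vapply(got, function(p) c(p$centroid, p$area), numeric(3)))
    expect_equal(unname(gc), unname(want), tolerance = 1e-10)
  }
})

test_that("merging is idempotent, permutation-invariant and area-conserving", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(2:9, 1)
    cents <- cbind(runif(n, 0, 25), runif(n, 0, 25))
    areas <- runif(n, 3, 50)
    pts <- make_points(cents, areas)
    m1 <- merge_spots(pts)
    expect_lte(length(m1), n)
    expect_equal(sum(vapply(m1, function(p) p$area, numeric(1))), sum(areas))
    expect_equal(merge_spots(m1), m1)
    perm <- sample(n)
    m2 <- merge_spots(pts[perm])
    expect_equal(m2, m1)
  }
})

test_that("signal counting merges confluent spots and reports absences as NA", {
  centers <- rbind(c(36, 36), c(36, 60), c(60, 36), c(60, 60))
  f <- make_spot_field(centers)
  expect_equal(count_signals(f$stack, f$region, "CEP8"), 4L)
  # two of the four closer than the merge distance
  close_pair <- rbind(c(36, 36), c(36, 60), c(60, 36), c(60, 40))
  f2 <- make_spot_field(close_pair)
  expect_equal(count_signals(f2$stack, f2$region, "CEP8"), 3L)
  # absent channel: unavailable, never zero
  expect_true(is.na(count_signals(f$stack, f$region, "CEP17")))
  expect_false(identical(count_signals(f$stack, f$region, "CEP17"), 0L))
})

test_that("rendered ground-truth spot counts survive detection + merge", {
  sim <- simulate_field(sim_params(n_cells = 6, noise_sigma = 0, seed = 71))
  regs <- segment_dapi(sim$stack)
  for (gt in sim$truth) {
    d <- vapply(regs, function(r) sqrt(sum((r$centroid - gt$centroid)^2)),
                numeric(1))
    reg <- regs[[which.min(d)]]
    expect_equal(count_signals(sim$stack, reg, "CEP8"), gt$true_cep8_count)
    expect_equal(count_signals(sim$stack, reg, "CEP17"), gt$true_cep17_count)
  }
  # confluent toggle: rendered spots merge down
  simc <- simulate_field(sim_params(n_cells = 4, ctc_fraction = 1, leukocyte_fraction = 0,
                                    noise_sigma = 0, confluent_spots = TRUE,
                                    seed = 72))
  regsc <- segment_dapi(simc$stack)
  merged_less <- FALSE
  for (gt in simc$truth) {
    d <- vapply(regsc, function(r) sqrt(sum((r$centroid - gt$centroid)^2)),
                numeric(1))
    cnt <- count_signals(simc$stack, regsc[[which.min(d)]], "CEP8")
    expect_lte(cnt, gt$true_cep8_count)
    if (cnt < gt$true_cep8_count) merged_less <- TRUE
  }
  expect_true(merged_less)
})
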