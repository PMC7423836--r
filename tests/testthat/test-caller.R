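region_from_mask <- function(mask) {
  label_nuclei(mask, seg_params(min_area_px = 1, max_area_px = 1e6,
                                min_solidity = 0.01,
                                exclude_border = FALSE))[[1]]
}

test_that("red proportion counts CD45-positive nucleus pixels", {
  mask <- matrix(FALSE, 60, 60); mask[21:40, 21:40] <- TRUE  # 400 px square
  reg <- region_from_mask(mask)
  # all-zero CD45
  expect_equal(red_proportion(channel_image(matrix(0, 60, 60), "CD45"), reg), 0)
  # all nucleus pixels saturated
  expect_equal(red_proportion(channel_image(matrix(255, 60, 60), "CD45"), reg), 1)
  # exactly half the mask pixels above threshold (fixed threshold mode)
  px <- matrix(0, 60, 60)
  idx <- which(mask)
  px[idx[seq_len(length(idx) / 2)]] <- 200
  expect_equal(
    red_proportion(channel_image(px, "CD45"), reg,
                   caller_params(cd45_threshold_mode = "fixed",
                                 cd45_fixed_threshold = 100)),
    0.5)
  # and under global Otsu on a channel with genuine signal
  expect_equal(red_proportion(channel_image(px, "CD45"), reg), 0.5)
  empty <- reg; empty$area <- 0L
  expect_error(red_proportion(channel_image(px, "CD45"), empty), "empty")
})

test_that("the four-condition standard classifies the worked cases", {
  # aneuploid, CD45-negative: positive under OR logic
  c1 <- classify_nucleus(cell_features(TRUE, 0.25, 4L, 2L))
  expect_equal(c1$label, "CTC_POSITIVE")
  # red proportion above 30%: leukocyte, negative despite 5 CEP8 signals
  c2 <- classify_nucleus(cell_features(TRUE, 0.35, 5L, NA))
  expect_equal(c2$label, "CTC_NEGATIVE")
  expect_match(paste(c2$reasons, collapse = " "), "CD45 positive")
  # diploid on both probes: negative
  c3 <- classify_nucleus(cell_features(TRUE, 0.10, 2L, 2L))
  expect_equal(c3$label, "CTC_NEGATIVE")
  # boundary: exactly 0.30 still passes the CD45 gate (strictly "higher than")
  c4 <- classify_nucleus(cell_features(TRUE, 0.30, 3L, 1L))
  expect_equal(c4$label, "CTC_POSITIVE")
  # QC flags exclude regardless of features
  c5 <- classify_nucleus(cell_features(TRUE, 0.0, 5L, 5L),
                         qc_flags = "AGGREGATED")
  expect_equal(c5$label, "EXCLUDED")
  expect_match(c5$reasons[1], "AGGREGATED")
  # unavailable counts fail their condition; both unavailable -> negative
  c6 <- classify_nucleus(cell_features(TRUE, 0.0, NA, NA))
  expect_equal(c6$label, "CTC_NEGATIVE")
  expect_match(paste(c6$reasons, collapse = " "), "unavailable")
  # AND logic requires both probes
  and <- caller_params(signal_logic = "AND")
  expect_equal(classify_nucleus(cell_features(TRUE, 0, 4L, 2L), params = and)$label,
               "CTC_NEGATIVE")
  expect_equal(classify_nucleus(cell_features(TRUE, 0, 4L, 3L), params = and)$label,
               "CTC_POSITIVE")
  # reasons trace all four conditions in order
  expect_length(c1$reasons, 4)
  expect_match(c1$reasons[1], "^\\(1\\)")
  expect_match(c1$reasons[4], "^\\(4\\)")
})

test_that("classification is pure and monotone in its gates", {
  set.seed(81)
  for (i in 1:50) {
    rp <- runif(1)
    c8 <- sample(c(NA, 0:6), 1)
    c17 <- sample(c(NA, 0:6), 1)
    f <- cell_features(TRUE, rp, c8, c17)
    a <- classify_nucleus(f); b <- classify_nucleus(f)
    expect_identical(a, b)
    # raising red proportion can never turn a negative positive
    if (rp < 0.95) {
      worse <- classify_nucleus(cell_features(TRUE, min(1, rp + 0.3), c8, c17))
      if (a$label == "CTC_NEGATIVE") expect_equal(worse$label, "CTC_NEGATIVE")
    }
    # adding a signal point can never turn a positive negative
    more <- cell_features(TRUE, rp, if (is.na(c8)) 1L else c8 + 1L, c17)
    if (a$label == "CTC_POSITIVE")
      expect_equal(classify_nucleus(more)$label, "CTC_POSITIVE")
  }
})

test_that("field-level calling matches ground truth on noise-free fields", {
  sim <- simulate_field(sim_params(n_cells = 10, ctc_fraction = 0.2,
                                   noise_sigma = 0, seed = 91))
  calls <- call_field(sim$stack)
  expect_length(calls, 10)
  got <- match_calls(sim$truth, calls)
  want <- vapply(sim$truth, function(x) x$true_label, character(1))
  expect_equal(got, want)
  expect_equal(sum(want == "CTC_POSITIVE"), 2)
  # blank field: no calls
  blank <- channel_stack(list(DAPI = channel_image(matrix(0, 64, 64), "DAPI")))
  expect_length(call_field(blank), 0)
  # leukocyte-only field: zero positives
  leuk <- simulate_field(sim_params(n_cells = 8, ctc_fraction = 0,
                                    leukocyte_fraction = 1, noise_sigma = 0,
                                    seed = 92))
  labs <- vapply(call_field(leuk$stack), function(x) x$label, character(1))
  expect_false(any(labs == "CTC_POSITIVE"))
})

test_that("calls without a CD45 channel fall back to a zero red proportion", {
  sim <- simulate_field(sim_params(n_cells = 4, ctc_fraction = 1, leukocyte_fraction = 0,
                                   noise_sigma = 0, seed = 93))
  stack <- sim$stack
  stack$channels$CD45 <- NULL
  calls <- call_field(stack)
  expect_true(all(vapply(calls, function(x) x$features$red_proportion,
                         numeric(1)) == 0))
  expect_true(all(vapply(calls, function(x) x$label, character(1)) ==
                    "CTC_POSITIVE"))
})
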