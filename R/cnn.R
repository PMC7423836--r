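#' CNN configuration
#'
#' Architecture and hyper-parameters of the AlexNet-style classifier: eight
#' weighted layers — five "same" convolution layers (max-pooling after
#' layers 1, 2 and 5) and three fully connected layers ending in a 2-way
#' softmax. The searched hyper-parameters are the hidden activation
#' (softmax, ReLU or tanh; "softmax" acts per-position across channels),
#' the fully-connected kernel regularizer (l1 or l2) and its factor
#' (0.01 or 0.02). ReLU / l2 / 0.01 is the documented best default.
#'
#' Filter counts below 16 trigger a warning: training does not converge
#' reliably in that range. Filter sizes above 10 px are likewise warned
#' against — CTC image features are no larger than about 10 px.
#'
#' @param activation hidden-layer activation.
#' @param regularizer kernel regularizer on the fully connected layers.
#' @param reg_factor regularization factor.
#' @param filters convolution filter counts (5 values; the desk-scale
#'   default keeps every layer inside the converging 16-128 range while
#'   staying tractable on a single CPU).
#' @param filter_size square kernel side (odd).
#' @param input_size crop side in pixels; must be divisible by 8 (three
#'   2x2 poolings). 64 at desk scale; 224 for fidelity-scale experiments.
#' @param n_channels input planes (DAPI, CD45, CEP8, CEP17).
#' @param fc_sizes widths of the two hidden fully connected layers.
#' @param n_classes output classes (2: CTC / non-CTC).
#' @param seed integer seed for weight initialization and batch order.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(activation = c("ReLU", "softmax", "tanh"),
                       regularizer = c("l2", "l1"), reg_factor = 0.01,
                       filters = c(16, 32, 32, 48, 64), filter_size = 5,
                       input_size = 64, n_channels = 4,
                       fc_sizes = c(128, 64), n_classes = 2, seed = 1) {
  activation <- match.arg(activation)
  regularizer <- match.arg(regularizer)
  if (length(filters) != 5L)
    stopf("an AlexNet-style model has 5 convolution layers; got %d filter counts",
          length(filters))
  if (length(fc_sizes) != 2L)
    stopf("expected 2 hidden fully-connected widths (3 FC layers total)")
  if (any(filters < 16))
    warning("filter counts below 16 are in the non-convergence range (16-128 converges)",
            call. = FALSE)
  if (filter_size > 10)
    warning("filter sizes above 10 px exceed the CTC feature scale and slow convergence",
            call. = FALSE)
  if (filter_size %% 2 == 0) stopf("filter_size must be odd")
  if (input_size %% 8 != 0) stopf("input_size must be divisible by 8")
  if (reg_factor < 0) stopf("reg_factor must be non-negative")
  structure(list(
    activation = activation, regularizer = regularizer,
    reg_factor = reg_factor, filters = as.integer(filters),
    filter_size = as.integer(filter_size), input_size = as.integer(input_size),
    n_channels = as.integer(n_channels), fc_sizes = as.integer(fc_sizes),
    n_classes = as.integer(n_classes), seed = as.integer(seed),
    n_conv_layers = 5L, n_fc_layers = 3L),
    class = "cnn_config")
}

act_code <- function(a) match(a, c("ReLU", "tanh", "softmax")) - 1L
reg_code <- function(r) match(r, c("l1", "l2")) - 1L

cfg_to_cpp <- function(config) {
  list(input_size = config$input_size, n_channels = config$n_channels,
       filter_size = config$filter_size, act_code = act_code(config$activation),
       reg_code = reg_code(config$regularizer), n_classes = config$n_classes,
       reg_factor = config$reg_factor, filters = config$filters,
       fc_sizes = config$fc_sizes)
}

# Layer input/output sizes; weights in fixed order cw1,cb1..cw5,cb5,
# fw1,fb1..fw3,fb3 (conv kernels stored as filters x (C_in*k*k)).
layer_dims <- function(config) {
  k <- config$filter_size
  cin <- c(config$n_channels, config$filters[-5])
  conv <- lapply(1:5, function(l) c(config$filters[l], cin[l] * k * k))
  flat <- config$filters[5] * (config$input_size / 8)^2
  fcin <- c(flat, config$fc_sizes)
  fcout <- c(config$fc_sizes, config$n_classes)
  fc <- lapply(1:3, function(l) c(fcout[l], fcin[l]))
  list(conv = conv, fc = fc)
}

init_weights <- function(config) {
  d <- layer_dims(config)
  with_seed(config$seed, {
    w <- vector("list", 16)
    for (l in 1:5) {
      fan_in <- d$conv[[l]][2]
      w[[2 * l - 1]] <- matrix(rnorm(prod(d$conv[[l]]), 0, sqrt(2 / fan_in)),
                               d$conv[[l]][1], d$conv[[l]][2])
      w[[2 * l]] <- rep(0, d$conv[[l]][1])
    }
    for (l in 1:3) {
      fan_in <- d$fc[[l]][2]
      w[[10 + 2 * l - 1]] <- matrix(rnorm(prod(d$fc[[l]]), 0, sqrt(2 / fan_in)),
                                    d$fc[[l]][1], d$fc[[l]][2])
      w[[10 + 2 * l]] <- rep(0, d$fc[[l]][1])
    }
    w
  })
}

#' Build an (untrained) CNN model
#'
#' Initializes weights deterministically from `config$seed` (He-scaled
#' normal draws). The returned object reports its exact trainable weight
#' count, a pure function of the configuration.
#'
#' @param config a [cnn_config].
#' @return A `ctc_cnn` model object.
#' @export
cnn_build <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  weights <- init_weights(config)
  structure(list(config = config, weights = weights,
                 n_params = sum(vapply(weights, length, numeric(1))),
                 history = NULL, trained = FALSE),
            class = "ctc_cnn")
}

#' @export
print.ctc_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ctc_cnn> %d weighted layers (5 conv + 3 FC), input %dx%dx%d\n",
    cfg$n_conv_layers + cfg$n_fc_layers, cfg$input_size, cfg$input_size,
    cfg$n_channels))
  cat(sprintf("  activation=%s regularizer=%s(%.3g) filters=(%s)\n",
              cfg$activation, cfg$regularizer, cfg$reg_factor,
              paste(cfg$filters, collapse = ",")))
  cat(sprintf("  %s trainable weights; %s\n", format(x$n_params, big.mark = ","),
              if (x$trained) sprintf("trained %d epochs (final loss %.4f)",
                                     length(x$history$loss),
                                     utils::tail(x$history$loss, 1))
              else "untrained"))
  invisible(x)
}

#' @export
summary.ctc_cnn <- function(object, ...) {
  d <- layer_dims(object$config)
  cat("Layer summary (weights x inputs):\n")
  for (l in 1:5)
    cat(sprintf("  conv%d: %d filters x %d (%s%s)\n", l, d$conv[[l]][1],
                d$conv[[l]][2], object$config$activation,
                if (l %in% c(1, 2, 5)) " + maxpool 2x2" else ""))
  for (l in 1:3)
    cat(sprintf("  fc%d:   %d x %d%s\n", l, d$fc[[l]][1], d$fc[[l]][2],
                if (l == 3) " (softmax output)" else ""))
  print(object)
  invisible(object)
}

crops_to_array <- function(x) {
  if (inherits(x, "crop_dataset")) return(x$crops)
  if (is.list(x) && all(vapply(x, function(c) inherits(c, "labeled_crop"),
                               logical(1)))) {
    d <- dim(x[[1]]$pixels)
    arr <- array(0, c(d, length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]$pixels
    return(arr)
  }
  stopifnot(is.array(x), length(dim(x)) == 4L)
  x
}

labels01 <- function(y) {
  # positive class CTC_POSITIVE -> 0 (first softmax unit), else 1
  as.integer(ifelse(as.character(y) == "CTC_POSITIVE", 0L, 1L))
}

#' Train the CNN
#'
#' Mini-batch Adam on cross-entropy loss (plus the configured kernel
#' regularizer on the fully connected layers). Deterministic given the
#' seed: weight initialization, batch order and the single-threaded C++
#' engine all flow from it.
#'
#' @param x crops: a `crop_dataset`, a list of `labeled_crop`s, or an array
#'   `H x W x C x N` with intensities in \[0, 1\].
#' @param y labels (`CTC_POSITIVE`/`CTC_NEGATIVE`); taken from `x` when it
#'   is a `crop_dataset`.
#' @param config a [cnn_config].
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param verbose print per-epoch loss.
#' @return A trained `ctc_cnn` with a `history` (per-epoch mean loss and
#'   training accuracy).
#' @export
cnn_train <- function(x, y = NULL, config = cnn_config(), epochs = 10,
                      lr = 1e-3, batch_size = 32, verbose = FALSE) {
  if (inherits(x, "crop_dataset") && is.null(y)) y <- x$labels
  arr <- crops_to_array(x)
  if (dim(arr)[1] != config$input_size)
    stopf("crop size %d does not match config input_size %d",
          dim(arr)[1], config$input_size)
  yy <- labels01(y)
  n <- length(yy)
  if (n == 0L) stopf("empty training data")
  if (length(unique(yy)) < 2L) stopf("training data must contain both classes")
  if (epochs < 0) stopf("epochs must be >= 0")
  model <- cnn_build(config)
  w <- model$weights
  cpp_cfg <- cfg_to_cpp(config)
  m <- lapply(w, function(wi) wi * 0)
  v <- lapply(w, function(wi) wi * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  hist_loss <- hist_acc <- numeric(0)
  if (epochs > 0) with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1, n)]
        xb <- arr[, , , ids, drop = FALSE]
        res <- .cnn_batch_grad(w, xb, yy[ids], cpp_cfg)
        t <- t + 1
        for (j in seq_along(w)) {
          g <- res$grads[[j]]
          m[[j]] <- b1 * m[[j]] + (1 - b1) * g
          v[[j]] <- b2 * v[[j]] + (1 - b2) * g^2
          mhat <- m[[j]] / (1 - b1^t)
          vhat <- v[[j]] / (1 - b2^t)
          w[[j]] <- w[[j]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + res$loss * length(ids)
        ep_correct <- ep_correct + sum(max.col(res$probs) - 1L == yy[ids])
      }
      hist_loss <- c(hist_loss, ep_loss / n)
      hist_acc <- c(hist_acc, ep_correct / n)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", ep, epochs,
                        utils::tail(hist_loss, 1), utils::tail(hist_acc, 1)))
    }
  })
  model$weights <- w
  model$history <- list(loss = hist_loss, accuracy = hist_acc)
  model$trained <- epochs > 0
  model
}

#' Predict with a trained CNN
#'
#' @param object a `ctc_cnn`.
#' @param x crops (see [cnn_train()]).
#' @param type `"prob"` for class probabilities (columns `CTC_POSITIVE`,
#'   `CTC_NEGATIVE`, rows summing to 1) or `"class"` for labels.
#' @param ... unused.
#' @return Matrix of probabilities or character vector of labels.
#' @export
predict.ctc_cnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  arr <- crops_to_array(x)
  if (dim(arr)[1] != object$config$input_size)
    stopf("crop size %d does not match model input_size %d",
          dim(arr)[1], object$config$input_size)
  probs <- .cnn_forward(object$weights, arr, cfg_to_cpp(object$config))
  colnames(probs) <- c("CTC_POSITIVE", "CTC_NEGATIVE")
  if (type == "prob") probs
  else colnames(probs)[max.col(probs)]
}

#' Extract per-nucleus crops from a field
#'
#' For each region: a square crop centered on the nucleus centroid with
#' side `1.5 x` the larger bounding-box side, reflectively padded at field
#' borders, channels stacked in fixed order DAPI, CD45, CEP8, CEP17
#' (a missing channel yields a zero plane, recorded in the crop), then
#' resized to `size_px` (bilinear) and scaled to \[0, 1\].
#'
#' @param stack a [channel_stack].
#' @param regions list of `nucleus_region`s.
#' @param size_px output crop side.
#' @return List of `labeled_crop` objects (`pixels`, `provenance`,
#'   `missing_channels`; `label` is filled by the benchmark builders).
#' @export
extract_crops <- function(stack, regions, size_px = 64) {
  lapply(regions, function(reg) {
    bb <- reg$bbox
    side <- max(3L, ceiling(1.5 * max(bb[2] - bb[1], bb[4] - bb[3])))
    r0 <- round(reg$centroid[1]) - side %/% 2
    c0 <- round(reg$centroid[2]) - side %/% 2
    ri <- reflect_idx(r0 + seq_len(side), stack$height)
    ci <- reflect_idx(c0 + seq_len(side), stack$width)
    planes <- array(0, c(side, side, 4L))
    missing <- character(0)
    for (j in seq_along(CHANNEL_ROLES)) {
      ch <- stack$channels[[CHANNEL_ROLES[j]]]
      if (is.null(ch)) { missing <- c(missing, CHANNEL_ROLES[j]); next }
      planes[, , j] <- ch$pixels[ri, ci] / max_intensity(ch$bit_depth)
    }
    out <- array(0, c(size_px, size_px, 4L))
    for (j in 1:4)
      out[, , j] <- from_ebi(EBImage::resize(as_ebi(planes[, , j]),
                                             w = size_px, h = size_px))
    structure(list(pixels = clip(out, 0, 1),
                   provenance = list(field_id = stack$field_id,
                                     nucleus_label = reg$label),
                   missing_channels = missing, label = NA_character_),
              class = "labeled_crop")
  })
}

#' Hyper-parameter grid of the model
#'
#' Three activations x two regularizer types x two factors (12 cells).
#'
#' @return List of vectors defining the grid, in search order.
#' @export
default_grid <- function() {
  list(activation = c("softmax", "ReLU", "tanh"),
       regularizer = c("l1", "l2"),
       reg_factor = c(0.01, 0.02))
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ids <- sample(which(y == cls))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    fold
  })
}

#' Grid search under stratified k-fold cross-validation
#'
#' Evaluates every configuration of the hyper-parameter grid by stratified
#' k-fold cross-validation (seeded folds, identical across cells) and
#' selects the configuration with the highest mean validation accuracy.
#' Ties break by grid order (activation, then regularizer, then factor).
#'
#' @param x crops (see [cnn_train()]).
#' @param y labels; taken from `x` when it is a `crop_dataset`.
#' @param grid hyper-parameter grid as from [default_grid()].
#' @param k folds (default 5).
#' @param seed seed for folds and training.
#' @param base_config template [cnn_config()] providing the architecture.
#' @param epochs training epochs per fold.
#' @param ... passed to [cnn_train()] (`lr`, `batch_size`).
#' @return A `ctc_grid`: list with `best_config`, `scores` (long
#'   data.frame: activation, regularizer, reg_factor, mean_accuracy) and
#'   `table` (wide, rows = activation x regularizer, columns = factors,
#'   mirroring the usual reporting layout).
#' @export
grid_search_cv <- function(x, y = NULL, grid = default_grid(), k = 5,
                           seed = 1, base_config = cnn_config(),
                           epochs = 3, ...) {
  if (inherits(x, "crop_dataset") && is.null(y)) y <- x$labels
  arr <- crops_to_array(x)
  yy <- as.character(y)
  if (length(unique(yy)) < 2L) stopf("grid search needs both classes present")
  if (k < 2) stopf("k must be >= 2")
  fold <- stratified_folds(yy, k, seed)
  cells <- expand.grid(reg_factor = grid$reg_factor,
                       regularizer = grid$regularizer,
                       activation = grid$activation,
                       stringsAsFactors = FALSE)
  # reorder columns to search order for reporting
  cells <- cells[, c("activation", "regularizer", "reg_factor")]
  acc <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$activation <- cells$activation[ci]
    cfg$regularizer <- cells$regularizer[ci]
    cfg$reg_factor <- cells$reg_factor[ci]
    cfg$seed <- as.integer(seed)
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- cnn_train(arr[, , , tr, drop = FALSE], yy[tr], config = cfg,
                       epochs = epochs, ...)
      pred <- predict(fit, arr[, , , !tr, drop = FALSE], type = "class")
      fold_acc[f] <- mean(pred == yy[!tr])
    }
    acc[ci] <- mean(fold_acc)
  }
  scores <- cbind(cells, mean_accuracy = acc)
  best <- which.max(acc)   # first maximum = grid order tie-break
  best_config <- base_config
  best_config$activation <- cells$activation[best]
  best_config$regularizer <- cells$regularizer[best]
  best_config$reg_factor <- cells$reg_factor[best]
  wide <- stats::reshape(
    scores, idvar = c("activation", "regularizer"), timevar = "reg_factor",
    direction = "wide")
  names(wide) <- sub("^mean_accuracy\\.", "factor_", names(wide))
  rownames(wide) <- NULL
  structure(list(best_config = best_config, scores = scores, table = wide,
                 k = k, seed = seed),
            class = "ctc_grid")
}

#' @export
print.ctc_grid <- function(x, ...) {
  cat(sprintf("<ctc_grid> %d-fold CV over %d configurations\n", x$k,
              nrow(x$scores)))
  print(x$table, digits = 3)
  cat(sprintf("best: activation=%s regularizer=%s factor=%.3g (accuracy %.3f)\n",
              x$best_config$activation, x$best_config$regularizer,
              x$best_config$reg_factor, max(x$scores$mean_accuracy)))
  invisible(x)
}
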