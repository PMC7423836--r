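#' Rule-based caller parameters
#'
#' Parameters of the four-condition manual interpretation standard:
#' (1) exclude aggregated/superposed nuclei and impurities (carried by the
#' segmentation QC flags), (2) DAPI positive, (3) CD45 negative — a nucleus
#' whose red proportion exceeds `red_proportion_cutoff` is a common
#' leukocyte, (4) at least `min_signal_points` CEP8/CEP17 signal points.
#'
#' @param red_proportion_cutoff fraction of nucleus pixels that may be
#'   CD45-positive before the cell is called a leukocyte; strictly greater
#'   than the cutoff flags the leukocyte, so exactly 0.30 still passes.
#' @param min_signal_points hyperdiploidy threshold on the per-probe merged
#'   signal count.
#' @param signal_logic `"OR"` (default: aneuploidy of either chromosome 8
#'   or 17 suffices) or `"AND"` over the two probes.
#' @param cd45_threshold_mode `"otsu"` (global Otsu over the CD45 channel)
#'   or `"fixed"` (use `cd45_fixed_threshold`).
#' @param cd45_fixed_threshold intensity threshold when mode is `"fixed"`.
#' @return A `caller_params` list.
#' @export
caller_params <- function(red_proportion_cutoff = 0.30, min_signal_points = 3,
                          signal_logic = c("OR", "AND"),
                          cd45_threshold_mode = c("otsu", "fixed"),
                          cd45_fixed_threshold = NULL) {
  signal_logic <- match.arg(signal_logic)
  cd45_threshold_mode <- match.arg(cd45_threshold_mode)
  stopifnot(red_proportion_cutoff > 0, red_proportion_cutoff < 1,
            min_signal_points >= 1)
  if (cd45_threshold_mode == "fixed" && is.null(cd45_fixed_threshold))
    stopf("cd45_fixed_threshold required when cd45_threshold_mode = 'fixed'")
  structure(list(red_proportion_cutoff = red_proportion_cutoff,
                 min_signal_points = as.integer(min_signal_points),
                 signal_logic = signal_logic,
                 cd45_threshold_mode = cd45_threshold_mode,
                 cd45_fixed_threshold = cd45_fixed_threshold),
            class = "caller_params")
}

cd45_threshold <- function(cd45, params) {
  mx <- max_intensity(cd45$bit_depth)
  if (params$cd45_threshold_mode == "fixed") return(params$cd45_fixed_threshold)
  th <- otsu_threshold(cd45$pixels, cd45$bit_depth)
  # Weak-signal guard: on a channel with no real CD45 staining (noise only,
  # or constant), Otsu splits the noise and would mark ~half of every
  # nucleus "red". A threshold in the bottom tenth of the bit range cannot
  # correspond to genuine antibody signal; fall back to half range.
  if (is.na(th) || th < 0.1 * mx) th <- mx / 2
  th
}

#' CD45 red proportion of a nucleus
#'
#' Fraction of nucleus-mask pixels whose CD45 intensity exceeds the CD45
#' positivity threshold (global Otsu by default, with a weak-signal guard;
#' see [caller_params()]).
#'
#' @param cd45 the CD45 [channel_image].
#' @param region a `nucleus_region`.
#' @param params a [caller_params].
#' @return Fraction in \[0, 1\].
#' @export
red_proportion <- function(cd45, region, params = caller_params()) {
  stopifnot(inherits(cd45, "channel_image"), inherits(region, "nucleus_region"))
  if (region$area == 0) stopf("region has an empty mask")
  th <- cd45_threshold(cd45, params)
  mean(cd45$pixels[region$pixels] > th)
}

#' Per-nucleus feature set for the rule-based caller
#'
#' @param dapi_positive logical; satisfied by construction for any
#'   DAPI-segmented nucleus, recorded explicitly for traceability.
#' @param red_proportion fraction in \[0, 1\].
#' @param cep8_count,cep17_count merged signal counts, or `NA` when the
#'   probe channel is unavailable.
#' @return A `cell_features` list.
#' @export
cell_features <- function(dapi_positive, red_proportion,
                          cep8_count, cep17_count) {
  stopifnot(red_proportion >= 0, red_proportion <= 1)
  structure(list(dapi_positive = isTRUE(dapi_positive),
                 red_proportion = red_proportion,
                 cep8_count = as.integer(cep8_count),
                 cep17_count = as.integer(cep17_count)),
            class = "cell_features")
}

#' Classify a nucleus by the manual interpretation standard
#'
#' Applies the four conditions in order. A nucleus with any segmentation QC
#' flag is `EXCLUDED` (condition 1). Otherwise it is `CTC_POSITIVE` iff it
#' is DAPI positive (2), its red proportion does not exceed the cutoff (3),
#' and the signal logic over the available CEP8/CEP17 counts reaches
#' `min_signal_points` (4). An unavailable count participates as "fails";
#' with OR logic and both probes unavailable the cell is `CTC_NEGATIVE`
#' with the reason recorded. The `reasons` field traces each condition's
#' outcome in order.
#'
#' @param features a [cell_features].
#' @param qc_flags character vector of segmentation QC flags.
#' @param params a [caller_params].
#' @param nucleus optional `nucleus_region` to attach to the call.
#' @return A `cell_call` with fields `label`
#'   (`CTC_POSITIVE`/`CTC_NEGATIVE`/`EXCLUDED`), `features`, `reasons`.
#' @export
classify_nucleus <- function(features, qc_flags = character(0),
                             params = caller_params(), nucleus = NULL) {
  stopifnot(inherits(features, "cell_features"))
  reasons <- character(0)
  if (length(qc_flags)) {
    reasons <- sprintf("(1) excluded: %s", paste(qc_flags, collapse = ","))
    label <- "EXCLUDED"
  } else {
    reasons <- "(1) clean single nucleus"
    dapi_ok <- features$dapi_positive
    reasons <- c(reasons,
                 if (dapi_ok) "(2) DAPI positive" else "(2) DAPI negative")
    cd45_ok <- features$red_proportion <= params$red_proportion_cutoff
    reasons <- c(reasons, sprintf(
      "(3) CD45 %s (red proportion %.3f %s %.2f)",
      if (cd45_ok) "negative" else "positive", features$red_proportion,
      if (cd45_ok) "<=" else ">", params$red_proportion_cutoff))
    c8 <- features$cep8_count; c17 <- features$cep17_count
    hit8 <- !is.na(c8) && c8 >= params$min_signal_points
    hit17 <- !is.na(c17) && c17 >= params$min_signal_points
    sig_ok <- if (params$signal_logic == "OR") hit8 || hit17 else hit8 && hit17
    sig_txt <- sprintf("CEP8=%s, CEP17=%s",
                       ifelse(is.na(c8), "unavailable", c8),
                       ifelse(is.na(c17), "unavailable", c17))
    if (params$signal_logic == "OR" && is.na(c8) && is.na(c17))
      reasons <- c(reasons, sprintf(
        "(4) signal counts unavailable for both probes (%s)", sig_txt))
    else
      reasons <- c(reasons, sprintf(
        "(4) %s %d signal points (%s, logic %s)",
        if (sig_ok) "at least" else "fewer than", params$min_signal_points,
        sig_txt, params$signal_logic))
    label <- if (dapi_ok && cd45_ok && sig_ok) "CTC_POSITIVE" else "CTC_NEGATIVE"
  }
  structure(list(nucleus = nucleus, features = features, label = label,
                 reasons = reasons),
            class = "cell_call")
}

#' @export
print.cell_call <- function(x, ...) {
  cat(sprintf("<cell_call> %s\n", x$label))
  for (r in x$reasons) cat("  ", r, "\n", sep = "")
  invisible(x)
}

#' Call every nucleus in a field
#'
#' End-to-end rule-based pipeline: [segment_dapi()], then per nucleus the
#' CD45 red proportion and the merged CEP8/CEP17 signal counts, then
#' [classify_nucleus()]. Deterministic.
#'
#' @param stack a [channel_stack] with a DAPI channel.
#' @param seg_params a [seg_params] (default: gates scaled to the field).
#' @param caller_params a [caller_params].
#' @param spot_params a [spot_params].
#' @return List of `cell_call` objects (one per segmented nucleus).
#' @export
call_field <- function(stack, seg_params = NULL,
                       caller_params = ctcscope::caller_params(),
                       spot_params = ctcscope::spot_params()) {
  regions <- segment_dapi(stack, seg_params)
  cd45 <- stack$channels$CD45
  lapply(regions, function(reg) {
    rp <- if (is.null(cd45)) 0 else red_proportion(cd45, reg, caller_params)
    feats <- cell_features(
      dapi_positive = TRUE,  # segmented on DAPI
      red_proportion = rp,
      cep8_count = count_signals(stack, reg, "CEP8", spot_params),
      cep17_count = count_signals(stack, reg, "CEP17", spot_params))
    classify_nucleus(feats, reg$qc_flags, caller_params, nucleus = reg)
  })
}

#' Tabulate cell calls
#'
#' @param calls list of `cell_call`s.
#' @param field_id optional field identifier column.
#' @return data.frame with one row per call.
#' @export
calls_table <- function(calls, field_id = NULL) {
  df <- data.frame(
    nucleus_label = vapply(calls, function(x)
      if (is.null(x$nucleus)) NA_integer_ else x$nucleus$label, integer(1)),
    label = vapply(calls, function(x) x$label, character(1)),
    red_proportion = vapply(calls, function(x) x$features$red_proportion,
                            numeric(1)),
    cep8_count = vapply(calls, function(x) x$features$cep8_count, integer(1)),
    cep17_count = vapply(calls, function(x) x$features$cep17_count, integer(1)),
    reasons = vapply(calls, function(x) paste(x$reasons, collapse = " | "),
                     character(1)))
  if (!is.null(field_id)) df <- cbind(field_id = field_id, df)
  df
}
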