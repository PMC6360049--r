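#' Extract the blood-pool ROI by fractional-maximum thresholding
#'
#' Multiplies the anatomical segment mask with a reconstructed PET image
#' and keeps only the voxels whose value is at least
#' `threshold_fraction * max` of the segmented values (default 75%). This
#' discards the segment rim voxels most affected by partial volume
#' spill-out, so the ROI mean tracks the true blood activity more closely
#' than the full-segment mean. Ties at exactly the threshold are included.
#'
#' @param segment_mask logical array: the anatomical (MR-derived) segment.
#' @param pet_image reconstructed activity image, same shape.
#' @param threshold_fraction fraction of the segment maximum, in (0, 1].
#' @return logical ROI array (subset of the segment) with attributes
#'   `threshold_fraction` and `n_voxels`.
#' @export
extract_roi <- function(segment_mask, pet_image, threshold_fraction = 0.75) {
  segment_mask <- segment_mask & TRUE
  if (!any(segment_mask)) stop("anatomical segment is empty")
  if (!all(is.finite(pet_image[segment_mask])))
    stop("PET image contains non-finite values inside the segment")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  vals <- pet_image * segment_mask
  m <- max(vals[segment_mask])
  if (m <= 0)
    stop("segmented PET values are all <= 0; ROI undefined - review the ",
         "threshold or the source frame")
  roi <- segment_mask & (vals >= threshold_fraction * m)
  if (!any(roi))
    stop("ROI empty after thresholding; review the threshold fraction")
  structure(roi, threshold_fraction = threshold_fraction,
            n_voxels = sum(roi))
}

#' ROI mean
#'
#' Arithmetic mean of the image over the ROI voxels (the per-frame IDIF
#' value t_k).
#'
#' @param roi logical ROI array.
#' @param image activity image.
#' @return scalar mean.
#' @export
roi_mean <- function(roi, image) {
  if (!any(roi)) stop("ROI is empty")
  mean(image[roi & TRUE])
}

#' Percent bias of a measured value against truth
#'
#' `100 * (t - truth) / truth` (signed); summaries use the absolute value.
#'
#' @param t measured value(s).
#' @param truth true value(s), > 0.
#' @return signed percent bias.
#' @export
percent_bias <- function(t, truth) {
  if (any(truth <= 0)) stop("true activity must be positive")
  100 * (t - truth) / truth
}

#' Percent coefficient of variation
#'
#' `100 * sample SD / mean` over the supplied values (the ROI voxel values
#' of one frame).
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return CoV in percent.
#' @export
percent_cov <- function(values) {
  if (length(values) < 2L) stop("CoV needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("CoV undefined for non-positive mean")
  100 * stats::sd(values) / m
}

#' IDIF curve and per-frame figures of merit for one realisation
#'
#' Applies one fixed ROI to every reconstructed frame and computes the
#' per-frame ROI mean t_k, its signed percent bias against the true
#' frame-averaged blood activity, and the percent CoV over ROI voxels.
#'
#' @param frames list of reconstructed activity images, one per frame.
#' @param roi logical ROI array (same for all frames).
#' @param truth true frame-averaged blood activity, one value per frame.
#' @param scheme optional [make_frame_scheme()] for the time axis.
#' @return data.frame with columns `frame`, `time` (frame midpoint, s, if a
#'   scheme is given), `mean`, `bias`, `cov`.
#' @export
compute_idif <- function(frames, roi, truth, scheme = NULL) {
  if (length(frames) != length(truth))
    stop("number of frames (", length(frames),
         ") does not match truth length (", length(truth), ")")
  means <- vapply(frames, function(f) roi_mean(roi, f), numeric(1))
  covs <- vapply(frames, function(f) {
    v <- f[roi & TRUE]
    if (length(v) >= 2L && mean(v) > 0) percent_cov(v) else NA_real_
  }, numeric(1))
  out <- data.frame(frame = seq_along(frames),
                    mean = means,
                    bias = percent_bias(means, truth),
                    cov = covs)
  if (!is.null(scheme)) out$time <- scheme$mid[seq_along(frames)]
  out
}

#' Study-level bias / CoV summary
#'
#' Pools per-frame, per-realisation metrics into the summary layout of the
#' simulation comparison:
#' * `mode = "pooled"` — mean / max / min of |bias_k| and of CoV_k over the
#'   flat (frame x realisation) pool (the all-frames table);
#' * `mode = "peak_frame"` — at a single frame index: signed bias of the
#'   realisation-mean ROI value against truth, and CoV across the
#'   realisation means (the repeatability table).
#'
#' @param bias matrix of signed percent bias, frames x realisations.
#' @param cov matrix of percent CoV, frames x realisations.
#' @param mode `"pooled"` or `"peak_frame"`.
#' @param peak_frame frame index for `"peak_frame"` mode.
#' @param truth true activity per frame (needed for `"peak_frame"` mode
#'   together with `means`).
#' @param means matrix of ROI means, frames x realisations
#'   (`"peak_frame"` mode).
#' @return one-row data.frame of summary statistics.
#' @export
summarise_study <- function(bias, cov, mode = c("pooled", "peak_frame"),
                            peak_frame = NULL, truth = NULL, means = NULL) {
  mode <- match.arg(mode)
  bias <- as.matrix(bias); cov <- as.matrix(cov)
  if (length(bias) == 0L) stop("empty metrics")
  if (mode == "pooled") {
    ab <- abs(as.vector(bias))
    cv <- as.vector(cov); cv <- cv[is.finite(cv)]
    # single-voxel ROIs have no within-ROI CoV; report NA rather than warn
    cstat <- if (length(cv)) c(mean(cv), max(cv), min(cv))
      else rep(NA_real_, 3)
    data.frame(mean_bias = mean(ab), max_bias = max(ab), min_bias = min(ab),
               mean_cov = cstat[1], max_cov = cstat[2], min_cov = cstat[3])
  } else {
    if (is.null(peak_frame) || is.null(truth) || is.null(means))
      stop("peak_frame mode needs peak_frame, truth and means")
    mk <- means[peak_frame, ]
    data.frame(bias = percent_bias(mean(mk), truth[peak_frame]),
               mean_cov = if (length(mk) >= 2L) percent_cov(mk) else NA_real_)
  }
}
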