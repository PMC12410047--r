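#' Scan a dF/F0 movie for active cells
#'
#' Each inverted frame (AP-up) is noise-reduced with a grayscale
#' morphological opening (erosion then dilation, disc structuring element)
#' so that single-pixel noise cannot survive while cell-sized dark
#' transients do. A per-pixel activity heat-map counts the frames on which
#' the opened signal exceeds `z_thresh` robust SDs of that pixel's opened
#' trace; connected components of the heat-map above the area threshold
#' become provisional ROIs.
#'
#' @param movie A [movie_stack()] with `dff = TRUE`.
#' @param opening_radius_um Radius of the disc structuring element
#'   (micrometres); rounded to pixels, minimum 1 px.
#' @param z_thresh Per-pixel z threshold on the opened signal
#'   (calibrated on synthetic movies: recovers all planted cells while
#'   silent movies yield no false component).
#' @param min_frames Minimum supra-threshold frame count for a pixel to
#'   enter the heat-map mask (1 keeps single-AP cells detectable).
#' @param min_area_um2 Minimum component area in square micrometres
#'   (default: a 7 um diameter disc, well under a soma).
#' @return List with `heatmap` (matrix of counts) and `rois` (list of
#'   [roi()] objects).
#' @export
activity_scan <- function(movie, opening_radius_um = 1.5, z_thresh = 3,
                          min_frames = 1, min_area_um2 = NULL) {
  stopifnot(inherits(movie, "voltcon_movie"), movie$dff)
  px_um <- movie$pixel_size
  if (is.null(min_area_um2)) min_area_um2 <- pi * 3.5^2
  r_px <- max(1L, round(opening_radius_um / px_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  nfr <- dim(movie$data)[1]
  nr <- dim(movie$data)[2]; nc <- dim(movie$data)[3]

  opened <- array(0, dim = dim(movie$data))
  for (f in seq_len(nfr)) {
    frame <- -movie$data[f, , ]
    # opening commutes with adding a constant; shift into the positive
    # range first because EBImage clips negative intensities to zero
    off <- min(frame)
    opened[f, , ] <- EBImage::opening(frame - off, brush) + off
  }
  mu <- apply(opened, c(2, 3), stats::median)
  sdv <- apply(opened, c(2, 3), stats::mad)
  sdv[sdv == 0] <- Inf
  heat <- matrix(0L, nr, nc)
  for (f in seq_len(nfr)) {
    heat <- heat + ((opened[f, , ] - mu) / sdv > z_thresh)
  }
  mask <- heat >= min_frames
  labels <- EBImage::bwlabel(mask)
  rois <- list()
  min_area_px <- min_area_um2 / px_um^2
  for (lab in seq_len(max(labels))) {
    px <- which(labels == lab, arr.ind = TRUE)
    if (nrow(px) >= min_area_px) {
      rois[[length(rois) + 1]] <- roi(px,
                                      cell_id = sprintf("prov%02d",
                                                        length(rois) + 1),
                                      pixel_size = px_um)
    }
  }
  list(heatmap = heat, rois = rois)
}

#' Detect optical action potentials on a filtered trace
#'
#' Threshold crossings at `thresh_factor` times the RMS noise of the
#' AP-free part of the trace, with local-maximum peak assignment. The RMS
#' is estimated iteratively: detect, mask a guard window around every
#' event, recompute the RMS on the remainder, re-detect, until the spike
#' set is stable (at most `max_iter` rounds; non-convergence keeps the
#' last iterate and flags the cell).
#'
#' @param trace A bleach-corrected, low-pass filtered [cell_trace()].
#' @param thresh_factor Threshold in multiples of the AP-free RMS
#'   (operating default 5).
#' @param min_isi_ms Minimum inter-spike interval for peak assignment.
#' @param guard_ms Mask half-width around detected events during RMS
#'   re-estimation.
#' @param max_iter Maximum detect/re-estimate rounds.
#' @return List with `spike_times` (ms, strictly increasing), `threshold`,
#'   `rms`, and `converged`.
#' @export
detect_spikes <- function(trace, thresh_factor = 5, min_isi_ms = 5,
                          guard_ms = 10, max_iter = 5) {
  stopifnot(inherits(trace, "voltcon_trace"))
  v <- trace$values - stats::median(trace$values)
  n <- length(v)
  rms <- stats::sd(v)
  prev <- integer(0)
  converged <- FALSE
  peaks <- integer(0)
  for (it in seq_len(max_iter)) {
    thr <- thresh_factor * rms
    peaks <- find_peaks(v, thr, min_isi_ms)
    if (identical(peaks, prev)) { converged <- TRUE; break }
    prev <- peaks
    mask <- rep(FALSE, n)
    for (p in peaks) {
      mask[max(1, p - guard_ms):min(n, p + guard_ms)] <- TRUE
    }
    if (sum(!mask) < 100) break
    rms <- stats::sd(v[!mask])
  }
  list(spike_times = peaks - 1, threshold = thresh_factor * rms,
       rms = rms, converged = converged)
}

# local maxima above thr, greedily enforcing the minimum ISI from the
# largest peak down; a secondary peak within afterwave_ms of a >= 2x
# larger one is treated as part of that AP's afterwave (ADP), not a spike
find_peaks <- function(v, thr, min_isi, afterwave_ms = 30) {
  n <- length(v)
  above <- which(v > thr)
  if (!length(above)) return(integer(0))
  is_peak <- above[vapply(above, function(i) {
    (i == 1 || v[i] >= v[i - 1]) && (i == n || v[i] > v[i + 1])
  }, logical(1))]
  if (!length(is_peak)) return(integer(0))
  ord <- is_peak[order(v[is_peak], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_isi)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  shadowed <- vapply(seq_along(kept), function(i) {
    prev <- kept[kept < kept[i] & kept[i] - kept <= afterwave_ms]
    any(v[prev] >= 2 * v[kept[i]])
  }, logical(1))
  kept[!shadowed]
}

#' Per-spike peak amplitudes from the unfiltered trace
#'
#' @param trace Bleach-corrected (unfiltered) [cell_trace()].
#' @param spike_times Spike times in ms.
#' @param search_ms Search half-width around each nominal peak.
#' @return Numeric vector of peak amplitudes.
#' @export
spike_peak_amplitudes <- function(trace, spike_times, search_ms = 2) {
  v <- trace$values
  vapply(spike_times, function(t) {
    i <- t + 1
    lo <- max(1, i - search_ms); hi <- min(length(v), i + search_ms)
    max(v[lo:hi])
  }, numeric(1))
}

#' Quality control for a detected cell
#'
#' Exclusion rules: fewer than 10 APs (`"min_spikes"`); inconsistent AP
#' waveforms, operationalised as a coefficient of variation of per-spike
#' peak amplitudes above `cv_thresh` (`"waveform_cv"` — an automated
#' stand-in for visual verification); and the abnormal transient-spiking
#' pattern, a run of at least 5 spikes within 200 ms whose amplitudes
#' decrease monotonically to under half of the first
#' (`"abnormal_transient"`).
#'
#' @param spike_times Spike times (ms).
#' @param peak_amps Per-spike peak amplitudes (same length).
#' @param min_spikes Minimum AP count (10).
#' @param cv_thresh Peak-amplitude CV threshold (0.5).
#' @return List with `excluded` (logical) and `reason` (`NA` if retained).
#' @export
qc_cell <- function(spike_times, peak_amps, min_spikes = 10,
                    cv_thresh = 0.5) {
  if (length(spike_times) < min_spikes) {
    return(list(excluded = TRUE, reason = "min_spikes"))
  }
  if (abnormal_transient(spike_times, peak_amps)) {
    return(list(excluded = TRUE, reason = "abnormal_transient"))
  }
  cv <- stats::sd(peak_amps) / mean(peak_amps)
  if (is.finite(cv) && cv > cv_thresh) {
    return(list(excluded = TRUE, reason = "waveform_cv"))
  }
  list(excluded = FALSE, reason = NA_character_)
}

abnormal_transient <- function(spike_times, peak_amps, run_len = 5,
                               span_ms = 200, drop_frac = 0.5) {
  n <- length(spike_times)
  if (n < run_len) return(FALSE)
  for (i in seq_len(n - run_len + 1)) {
    j <- i + run_len - 1
    if (spike_times[j] - spike_times[i] > span_ms) next
    a <- peak_amps[i:j]
    if (all(diff(a) < 0) && a[run_len] < drop_frac * a[1]) return(TRUE)
  }
  FALSE
}
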