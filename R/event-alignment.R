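#' Spike-time cross-correlogram
#'
#' Histogram of lags `t_post - t_pre` over all spike pairs within +-100 ms,
#' in 5 ms bins (40 bins, edges -100, -95, ..., +100; each bin is
#' half-open `[a, b)`).
#'
#' @param pre_times,post_times Spike times (ms).
#' @param window Half-width of the lag window (ms).
#' @param bin_ms Bin width (ms).
#' @return A `voltcon_crosscorr` list with `breaks`, `counts`, `centers`,
#'   `n_ref` (number of reference spikes).
#' @export
crosscorr <- function(pre_times, post_times, window = 100, bin_ms = 5) {
  breaks <- seq(-window, window, by = bin_ms)
  counts <- integer(length(breaks) - 1)
  if (length(pre_times) && length(post_times)) {
    post <- sort(post_times)
    for (t in pre_times) {
      lo <- findInterval(t - window, post) + 1
      hi <- findInterval(t + window, post, left.open = TRUE)
      if (hi >= lo) {
        lags <- post[lo:hi] - t
        b <- findInterval(lags, breaks, rightmost.closed = FALSE)
        b <- b[b >= 1 & b <= length(counts)]
        for (bb in b) counts[bb] <- counts[bb] + 1L
      }
    }
  }
  structure(list(breaks = breaks, counts = counts,
                 centers = breaks[-length(breaks)] + bin_ms / 2,
                 n_ref = length(pre_times)),
            class = "voltcon_crosscorr")
}

# bins entirely outside the +-exclude_ms window around zero
baseline_bins <- function(cc, exclude_ms = 20) {
  lo <- cc$breaks[-length(cc$breaks)]
  hi <- cc$breaks[-1]
  hi <= -exclude_ms | lo >= exclude_ms
}

#' Flag cross-detection between neighbouring cells
#'
#' Cross-detection (the same AP picked up on both ROIs) appears as a sharp
#' peak in the correlogram bin containing zero lag. The flag is raised
#' when that bin exceeds the baseline mean by `k` baseline SDs, the
#' baseline being all bins outside +-20 ms.
#'
#' @param cc A [crosscorr()].
#' @param k Threshold in baseline SDs.
#' @param min_frac Minimum fraction of reference spikes in the zero bin;
#'   co-detection duplicates a large share of the reference train, while
#'   a strong synaptic connection only adds a few counts near zero lag.
#' @return Logical.
#' @export
flag_cross_detection <- function(cc, k = 5, min_frac = 0.05) {
  zero_bin <- which(cc$breaks[-length(cc$breaks)] <= 0 & cc$breaks[-1] > 0)
  base <- cc$counts[baseline_bins(cc)]
  m <- mean(base); s <- stats::sd(base)
  if (!is.finite(s) || s == 0) s <- sqrt(max(m, 1)) # Poisson fallback
  z <- cc$counts[zero_bin]
  z > m + k * s && z >= max(3, min_frac * cc$n_ref)
}

#' Suprathreshold excitation summary from a correlogram
#'
#' Compares the postsynaptic firing rate in the 0 to +20 ms window with
#' the baseline rate (bins outside +-20 ms) and attaches a binomial test
#' of the window count against its expected share. Pairs with fewer than
#' 20 reference spikes are marked insufficient.
#'
#' @param cc A [crosscorr()].
#' @param min_ref Minimum reference-spike count (20).
#' @return List with `window_rate_hz`, `baseline_rate_hz`, `p_value`,
#'   `excitatory` and `insufficient`.
#' @export
suprathreshold_effect <- function(cc, min_ref = 20) {
  lo <- cc$breaks[-length(cc$breaks)]; hi <- cc$breaks[-1]
  win <- lo >= 0 & hi <= 20
  base <- baseline_bins(cc)
  win_ms <- sum(hi[win] - lo[win])
  base_ms <- sum(hi[base] - lo[base])
  n_win <- sum(cc$counts[win]); n_base <- sum(cc$counts[base])
  wr <- if (cc$n_ref > 0) n_win / (cc$n_ref * win_ms / 1000) else 0
  br <- if (cc$n_ref > 0) n_base / (cc$n_ref * base_ms / 1000) else 0
  p <- if (n_win + n_base > 0) {
    stats::binom.test(n_win, n_win + n_base,
                      p = win_ms / (win_ms + base_ms),
                      alternative = "greater")$p.value
  } else 1
  list(window_rate_hz = wr, baseline_rate_hz = br, p_value = p,
       excitatory = wr > br && p < 0.01,
       insufficient = cc$n_ref < min_ref)
}

#' Peri-AP postsynaptic firing rates
#'
#' Baseline rate from the -100..-10 ms window before each presynaptic AP
#' peak and response rate in the fixed 4-19 ms window after it, both in Hz
#' (counts / (n_pre x window length)).
#'
#' @param pre_times,post_times Spike times (ms).
#' @param response Response window (ms after the presynaptic peak).
#' @param baseline Baseline window (ms, negative = before the peak).
#' @return List with `baseline_hz`, `response_hz` and the raw counts.
#' @export
peri_ap_rate <- function(pre_times, post_times, response = c(4, 19),
                         baseline = c(-100, -10)) {
  n_pre <- length(pre_times)
  if (n_pre == 0 || length(post_times) == 0) {
    return(list(baseline_hz = 0, response_hz = 0,
                n_baseline = 0L, n_response = 0L, n_pre = n_pre))
  }
  post <- sort(post_times)
  n_resp <- 0L; n_base <- 0L
  for (t in pre_times) {
    lags <- post - t
    n_resp <- n_resp + sum(lags >= response[1] & lags <= response[2])
    n_base <- n_base + sum(lags >= baseline[1] & lags <= baseline[2])
  }
  list(baseline_hz = n_base / (n_pre * diff(baseline) / 1000),
       response_hz = n_resp / (n_pre * diff(response) / 1000),
       n_baseline = n_base, n_response = n_resp, n_pre = n_pre)
}

#' AP-triggered average video
#'
#' Mean dF/F0 frame stack over the -45..+50 ms window around every spike
#' of one cell (96 frames); segments crossing trial boundaries are
#' dropped.
#'
#' @param movie A dF/F0 [movie_stack()].
#' @param spike_times Spike times (ms) of the cell.
#' @param window Alignment window (ms relative to the AP peak).
#' @return A `voltcon_triggered_video` list with `frames` (window frames x
#'   rows x cols), `window`, `n_events`.
#' @export
ap_triggered_video <- function(movie, spike_times, window = c(-45, 50)) {
  stopifnot(inherits(movie, "voltcon_movie"), movie$dff)
  fpt <- movie$frames_per_trial
  offs <- window[1]:window[2]
  nfr <- length(offs)
  acc <- array(0, dim = c(nfr, dim(movie$data)[2], dim(movie$data)[3]))
  n_used <- 0L
  for (t in spike_times) {
    i <- t + 1 # frame index of the peak
    idx <- i + offs
    if (idx[1] < 1 || idx[nfr] > dim(movie$data)[1]) next
    if (((idx[1] - 1) %/% fpt) != ((idx[nfr] - 1) %/% fpt)) next
    acc <- acc + movie$data[idx, , , drop = FALSE]
    n_used <- n_used + 1L
  }
  if (n_used > 0) acc <- acc / n_used
  structure(list(frames = acc, window = window, n_events = n_used),
            class = "voltcon_triggered_video")
}

#' Minimal-intensity projection around the AP peak
#'
#' Per-pixel minimum over the 5 frames centred on the AP-peak frame
#' (peak +- 2 frames) of a triggered video.
#'
#' @param tv A [ap_triggered_video()].
#' @return Matrix (rows x cols) of minima (dF/F0; APs are negative).
#' @export
min_projection <- function(tv) {
  peak_idx <- which(tv$window[1]:tv$window[2] == 0)
  idx <- max(1, peak_idx - 2):min(dim(tv$frames)[1], peak_idx + 2)
  apply(tv$frames[idx, , , drop = FALSE], c(2, 3), min)
}

#' Refine an ROI from the minimal-intensity projection
#'
#' Thresholds the projection at `-z_roi` robust SDs of the projection
#' noise and keeps the connected component with the largest overlap with
#' the provisional ROI (or the one containing the darkest pixel when no
#' seed is given).
#'
#' @param projection Output of [min_projection()].
#' @param seed_roi Provisional [roi()] (optional).
#' @param z_roi Threshold in projection-noise SDs.
#' @param pixel_size Micrometres per pixel.
#' @param cell_id Identifier for the refined ROI.
#' @return A [roi()], or `NULL` when nothing survives the threshold.
#' @export
refine_roi <- function(projection, seed_roi = NULL, z_roi = 4,
                       pixel_size = 1.87, cell_id = NA_character_) {
  noise <- stats::mad(projection, center = stats::median(projection))
  if (noise == 0) noise <- stats::sd(projection)
  mask <- projection < stats::median(projection) - z_roi * noise
  if (!any(mask)) return(NULL)
  labels <- EBImage::bwlabel(mask)
  pick <- if (!is.null(seed_roi)) {
    seed_lab <- labels[seed_roi$pixels]
    seed_lab <- seed_lab[seed_lab > 0]
    if (!length(seed_lab)) return(NULL)
    as.integer(names(sort(table(seed_lab), decreasing = TRUE))[1])
  } else {
    labels[which.min(projection)]
  }
  if (pick == 0) return(NULL)
  px <- which(labels == pick, arr.ind = TRUE)
  roi(px, cell_id = cell_id, pixel_size = pixel_size)
}

#' Resolve overlaps between refined ROIs
#'
#' Contested pixels are assigned to the cell with the larger projection
#' magnitude there; the result is pairwise disjoint.
#'
#' @param rois List of refined [roi()]s.
#' @param projections List of the matching minimal projections.
#' @return List of disjoint [roi()]s (possibly dropping emptied ROIs).
#' @export
resolve_roi_overlaps <- function(rois, projections) {
  if (length(rois) < 2) return(rois)
  dims <- dim(projections[[1]])
  owner <- matrix(0L, dims[1], dims[2])
  strength <- matrix(-Inf, dims[1], dims[2])
  for (i in seq_along(rois)) {
    px <- rois[[i]]$pixels
    s <- abs(projections[[i]][px])
    for (k in seq_len(nrow(px))) {
      if (s[k] > strength[px[k, 1], px[k, 2]]) {
        strength[px[k, 1], px[k, 2]] <- s[k]
        owner[px[k, 1], px[k, 2]] <- i
      }
    }
  }
  out <- list()
  for (i in seq_along(rois)) {
    px <- which(owner == i, arr.ind = TRUE)
    if (nrow(px)) {
      out[[length(out) + 1]] <- roi(px, cell_id = rois[[i]]$cell_id,
                                    pixel_size = 1.87)
    }
  }
  out
}

#' Optical AP peak amplitude from the triggered video
#'
#' Mean refined-ROI amplitude at the AP-peak frame, in AP-up polarity
#' (positive).
#'
#' @param tv A [ap_triggered_video()].
#' @param roi The refined [roi()].
#' @return AP peak in dF/F0 units.
#' @export
ap_amplitude <- function(tv, roi) {
  peak_idx <- which(tv$window[1]:tv$window[2] == 0)
  frame <- tv$frames[peak_idx, , ]
  -mean(frame[roi$pixels])
}

#' AP template from a trace
#'
#' Mean spike-aligned waveform (AP-up) of the unfiltered corrected trace,
#' and its peak amplitude. Because detection at 1 kHz carries +-2 ms
#' alignment jitter, the averaged template is slightly broader and smaller
#' than single events.
#'
#' @param trace Bleach-corrected [cell_trace()].
#' @param spike_times Spike times (ms).
#' @param window Alignment window (ms).
#' @return List with `template`, `time` (ms relative to peak), `peak`
#'   (template maximum) and `n_events`.
#' @export
ap_template <- function(trace, spike_times, window = c(-45, 50)) {
  fpt <- trace$frames_per_trial
  offs <- window[1]:window[2]
  v <- trace$values
  acc <- numeric(length(offs)); n_used <- 0L
  for (t in spike_times) {
    i <- t + 1
    idx <- i + offs
    if (idx[1] < 1 || idx[length(idx)] > length(v)) next
    if (((idx[1] - 1) %/% fpt) != ((idx[length(idx)] - 1) %/% fpt)) next
    acc <- acc + v[idx]; n_used <- n_used + 1L
  }
  if (n_used > 0) acc <- acc / n_used
  list(template = acc, time = offs, peak = max(acc), n_events = n_used)
}
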