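#' Trigger-aligned segments of a postsynaptic trace
#'
#' Cuts the -45..+50 ms window around every presynaptic AP peak out of the
#' postsynaptic trace. Segments that would cross a trial boundary are
#' dropped.
#'
#' @param post_values Numeric per-frame trace (AP-up).
#' @param pre_times Presynaptic spike times (ms, global).
#' @param frames_per_trial Trial length in frames.
#' @param window Window in ms relative to the presynaptic peak.
#' @return List with `segments` (n x window-length matrix) and `triggers`
#'   (the spike times actually used).
#' @export
pair_segments <- function(post_values, pre_times, frames_per_trial,
                          window = c(-45, 50)) {
  offs <- window[1]:window[2]
  nfr <- length(offs)
  keep <- logical(length(pre_times))
  segs <- matrix(NA_real_, length(pre_times), nfr)
  for (k in seq_along(pre_times)) {
    i <- pre_times[k] + 1
    idx <- i + offs
    if (idx[1] < 1 || idx[nfr] > length(post_values)) next
    if (((idx[1] - 1) %/% frames_per_trial) !=
        ((idx[nfr] - 1) %/% frames_per_trial)) next
    segs[k, ] <- post_values[idx]
    keep[k] <- TRUE
  }
  list(segments = segs[keep, , drop = FALSE], triggers = pre_times[keep],
       window = window)
}

#' Average the trigger-aligned segments
#'
#' @param segs Output of [pair_segments()].
#' @return Numeric average trace (window length), or `NULL` when no
#'   segment survived.
#' @export
pair_average <- function(segs) {
  if (nrow(segs$segments) == 0) return(NULL)
  colMeans(segs$segments)
}

#' Silent-cell baseline correction
#'
#' Shared photometric artifacts (residual bleach, illumination noise) are
#' estimated as the mean trigger-aligned average of "silent" cells —
#' cells other than the pair members that show neither AP contamination
#' (own spikes inside the trigger windows) nor an EPSP/IPSP-like
#' deflection in their own average — and subtracted element-wise. When
#' fewer than `min_eligible` silent cells exist the global median trace
#' across all non-pair cells is subtracted instead and the result is
#' flagged.
#'
#' @param avg_traces Named list of trigger-aligned average traces (same
#'   trigger set), one per cell, in dF/F0 AP-up units.
#' @param contaminated Named logical: cell had spikes in >5 % of trigger
#'   windows.
#' @param exclude Cell ids to leave out (the pair members).
#' @param deflection_z Threshold (in baseline SDs of each average) for an
#'   event-like deflection after the trigger.
#' @param min_eligible Minimum number of eligible silent cells (3).
#' @param window The alignment window (ms).
#' @return List with `correction` (trace), `eligible` (ids used) and
#'   `fallback` (logical).
#' @export
silent_cell_baseline <- function(avg_traces, contaminated, exclude,
                                 deflection_z = 4, min_eligible = 3,
                                 window = c(-45, 50)) {
  offs <- window[1]:window[2]
  pre_idx <- which(offs <= -5)
  post_idx <- which(offs >= 0 & offs <= 30)
  ids <- setdiff(names(avg_traces), exclude)
  pool <- avg_traces[ids]
  pool <- pool[!vapply(pool, is.null, logical(1))]
  med <- if (length(pool) >= 2) {
    apply(do.call(rbind, pool), 2, stats::median)
  } else numeric(length(offs))
  eligible <- character(0)
  for (id in ids) {
    if (isTRUE(contaminated[[id]])) next
    a <- avg_traces[[id]]
    if (is.null(a)) next
    # event screen on the residual after removing the shared component,
    # so a common photometric artifact does not disqualify every cell
    r <- a - med
    b0 <- mean(r[pre_idx]); bs <- stats::sd(r[pre_idx])
    if (bs == 0) bs <- 1e-12
    if (max(abs(r[post_idx] - b0)) > deflection_z * bs) next
    eligible <- c(eligible, id)
  }
  if (length(eligible) >= min_eligible) {
    corr <- Reduce(`+`, avg_traces[eligible]) / length(eligible)
    list(correction = corr, eligible = eligible, fallback = FALSE)
  } else {
    pool <- avg_traces[ids]
    pool <- pool[!vapply(pool, is.null, logical(1))]
    if (!length(pool)) {
      return(list(correction = numeric(length(offs)),
                  eligible = character(0), fallback = TRUE))
    }
    m <- do.call(rbind, pool)
    list(correction = apply(m, 2, stats::median), eligible = character(0),
         fallback = TRUE)
  }
}

#' Normalise a trace to the cell's AP peak
#'
#' Expresses subthreshold amplitudes in AP% — percent of the same cell's
#' optical action-potential peak — which removes cell-to-cell variability
#' in fluorescence gain. The cell's own AP peak maps to exactly 100.
#'
#' @param values Trace in dF/F0 AP-up units.
#' @param ap_peak The cell's AP peak in the same units.
#' @return Trace in AP%.
#' @export
normalize_ap_percent <- function(values, ap_peak) {
  stopifnot(ap_peak > 0)
  100 * values / ap_peak
}

#' Screen an averaged pair trace for EPSP candidacy
#'
#' Exclusions are applied first: pre/post somata closer than the
#' cross-talk radius (`crosstalk_adjacent`); a deflection already rising
#' at the presynaptic peak with AP-like kinetics (`simultaneous_onset`);
#' and a baseline SD above threshold (`unstable_baseline`). A surviving
#' trace is a candidate when its onset falls just after the presynaptic
#' peak (the loose `onset_range` sanity band; the precise 0-2 frame onset
#' criterion is enforced downstream by the shifting-window fit, whose
#' accepted-shift window is a far more noise-robust timing estimate than
#' a single threshold crossing on the average), its amplitude lies in
#' 0.2-15 AP%, and the waveform is asymmetric in the EPSP sense (time to
#' peak shorter than the decay half-time).
#'
#' @param avg AP%-normalised average trace over the window.
#' @param window Window (ms).
#' @param distance_um Pre/post centroid distance (um); `NA` skips the
#'   cross-talk exclusion.
#' @param crosstalk_radius Exclusion radius (um).
#' @param amp_range Allowed amplitude range (AP%).
#' @param baseline_sd_max Maximum baseline SD (AP%).
#' @return List with `status` (`"candidate"` or `"rejected"` or
#'   `"excluded"`), `reason`, and the measured `onset`, `amp`, `peak_t`.
#' @export
candidate_screen <- function(avg, window = c(-45, 50), distance_um = NA,
                             crosstalk_radius = 50,
                             amp_range = c(0.2, 15),
                             baseline_sd_max = 1.5,
                             onset_range = c(-3, 8)) {
  offs <- window[1]:window[2]
  if (!is.na(distance_um) && distance_um < crosstalk_radius) {
    return(list(status = "excluded", reason = "crosstalk_adjacent",
                onset = NA, amp = NA, peak_t = NA))
  }
  base_idx <- which(offs <= -5)
  b0 <- mean(avg[base_idx])
  bsd <- stats::sd(avg[base_idx])
  if (bsd > baseline_sd_max) {
    return(list(status = "excluded", reason = "unstable_baseline",
                onset = NA, amp = NA, peak_t = NA))
  }
  # waveform features are read off a 5-point smoothed copy so single noisy
  # frames cannot flip the kinetic checks; the constrained fit downstream
  # consumes the unsmoothed average
  sm <- running_mean5(avg)
  post_idx <- which(offs >= 0 & offs <= 30)
  rel <- sm[post_idx] - b0
  peak_k <- which.max(rel)
  amp <- (avg[post_idx] - b0)[peak_k]
  amp_sm <- rel[peak_k]
  peak_t <- offs[post_idx][peak_k]
  # onset: last time at or before the peak where the trace is still below
  # 20 % of the amplitude
  pre_peak <- which(offs <= peak_t)
  below <- which(sm[pre_peak] - b0 <= 0.2 * amp_sm)
  onset <- if (length(below)) offs[pre_peak][max(below)] else offs[1]
  # half-rise time (last upward 50 % crossing to peak) vs half-decay time
  # (peak to first downward 50 % crossing): the EPSP asymmetry comparison
  # at matched levels
  below50 <- which(sm[pre_peak] - b0 <= 0.5 * amp_sm)
  rise_half <- if (length(below50)) peak_t - offs[pre_peak][max(below50)]
    else Inf
  after_peak <- which(offs > peak_t)
  half <- which(sm[after_peak] - b0 <= 0.5 * amp_sm)
  decay_half <- if (length(half)) offs[after_peak][min(half)] - peak_t else Inf

  if (onset <= 0 && is.finite(decay_half) && decay_half <= 5) {
    return(list(status = "excluded", reason = "simultaneous_onset",
                onset = onset, amp = amp, peak_t = peak_t))
  }
  # EPSP-like asymmetry: faster rise than decay; a half-decay of 6 ms or
  # more is never AP-like even when noise displaces the smoothed peak
  asymmetric <- rise_half < decay_half ||
    (is.finite(decay_half) && decay_half >= 5)
  ok <- onset >= onset_range[1] && onset <= onset_range[2] &&
    amp >= amp_range[1] && amp <= amp_range[2] &&
    asymmetric
  list(status = if (ok) "candidate" else "rejected",
       reason = if (ok) NA_character_ else "criteria",
       onset = onset, amp = amp, peak_t = peak_t)
}

# centred 5-point running mean, ends kept as-is
running_mean5 <- function(x) {
  f <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  f <- as.numeric(f)
  f[is.na(f)] <- x[is.na(f)]
  f
}

# unit-peak biexponential EPSP template on an integer time base
epsp_template <- function(tau_decay, tau_rise = 3, length_ms = 40) {
  t <- seq_len(length_ms) - 1
  g <- exp(-t / tau_decay) - exp(-t / tau_rise)
  g / max(g)
}

#' Shifting-window constrained EPSP fit
#'
#' An idealised EPSP waveform — unit-peak biexponential with the rise time
#' constant fixed at 3 ms — is fitted to the averaged trace by bounded
#' least squares over a 40 ms window starting at every shift from 17
#' frames before to 17 frames after the presynaptic AP peak (35 fits,
#' 1 frame = 1 ms). At each shift the amplitude is constrained to 1-20
#' AP%, the decay time constant to 8-22 ms, and the baseline shift to
#' -1..+1 AP%. Noise-baseline RMSE statistics come from the 16 pre-AP
#' shifts (fits whose windows start before the presynaptic spike). The
#' fit is accepted when the overall best shift lies +1..+5 frames after
#' the presynaptic AP, its RMSE is below the baseline mean minus `k_sd`
#' baseline SDs — i.e. the RMSE drops right after the presynaptic spike —
#' and the fitted amplitude sits strictly above its mandatory 1 AP% lower
#' bound (a fit pinned at the bound reflects the constraint, not an
#' EPSP; with this guard pure-noise traces are accepted well under the
#' 5 % calibration target).
#'
#' @param avg AP%-normalised average trace.
#' @param window Trace window (ms).
#' @param shifts Shift range in frames.
#' @param fit_len Fit window length (ms).
#' @param rise_tau Fixed rise time constant (ms).
#' @param tau_range Decay constraint (ms).
#' @param amp_range Amplitude constraint (AP%).
#' @param base_range Baseline-shift constraint (AP%).
#' @param accept_shifts Shifts (frames after the AP) where the best fit
#'   must land.
#' @param k_sd RMSE-drop criterion in baseline SDs (calibrated so that
#'   pure-noise traces are accepted at no more than ~5 %).
#' @param tau_grid_step Step of the decay-constant grid search.
#' @return A `voltcon_epsp_fit` list: per-shift `shift_rmse`, `best_shift`,
#'   `amp`, `tau_decay`, `baseline_shift`, `baseline_rmse_mean`,
#'   `baseline_rmse_sd`, `accepted`.
#' @export
shift_window_fit <- function(avg, window = c(-45, 50), shifts = -17:17,
                             fit_len = 40, rise_tau = 3,
                             tau_range = c(8, 22), amp_range = c(1, 20),
                             base_range = c(-1, 1), accept_shifts = 1:5,
                             k_sd = 2, tau_grid_step = 0.5) {
  offs <- window[1]:window[2]
  taus <- seq(tau_range[1], tau_range[2], by = tau_grid_step)
  G <- vapply(taus, epsp_template, numeric(fit_len),
              tau_rise = rise_tau, length_ms = fit_len)
  gbar <- colMeans(G)
  gg <- colSums(G * G)

  ns <- length(shifts)
  rmse <- rep(Inf, ns); amp_s <- numeric(ns); tau_s <- numeric(ns)
  base_s <- numeric(ns)
  for (si in seq_len(ns)) {
    s <- shifts[si]
    idx <- match(s:(s + fit_len - 1), offs)
    if (anyNA(idx)) next
    y <- avg[idx]
    ybar <- mean(y)
    yg <- colSums(y * G)
    n <- fit_len
    # unconstrained LS per tau: A = (yg - n ybar gbar) / (gg - n gbar^2)
    A <- (yg - n * ybar * gbar) / (gg - n * gbar^2)
    A <- pmin(pmax(A, amp_range[1]), amp_range[2])
    b <- ybar - A * gbar
    b <- pmin(pmax(b, base_range[1]), base_range[2])
    # one more pass of coordinate clamping for A given clamped b
    A2 <- (yg - b * colSums(G)) / gg
    A2 <- pmin(pmax(A2, amp_range[1]), amp_range[2])
    sse <- vapply(seq_along(taus), function(k) {
      r <- y - b[k] - A2[k] * G[, k]
      sum(r * r)
    }, numeric(1))
    k <- which.min(sse)
    rmse[si] <- sqrt(sse[k] / n)
    amp_s[si] <- A2[k]; tau_s[si] <- taus[k]; base_s[si] <- b[k]
  }

  # noise reference: the 16 pre-AP fits. Post-AP fits cannot serve as a
  # noise baseline because for a real connection their windows contain the
  # EPSP itself, inflating both their mean and spread with amplitude.
  base_idx <- seq_len(16)
  b_rmse <- rmse[base_idx][is.finite(rmse[base_idx])]
  b_mean <- mean(b_rmse); b_sd <- stats::sd(b_rmse)
  best <- which.min(rmse)
  best_shift <- shifts[best]
  # a fit pinned at the mandatory amplitude lower bound carries no
  # evidence of a real EPSP: the constraint, not the data, set A
  interior <- amp_s[best] > amp_range[1] + 1e-6
  accepted <- is.finite(rmse[best]) &&
    best_shift %in% accept_shifts &&
    interior &&
    rmse[best] < b_mean - k_sd * b_sd

  structure(list(shifts = shifts, shift_rmse = rmse,
                 best_shift = best_shift,
                 amp = amp_s[best], tau_decay = tau_s[best],
                 baseline_shift = base_s[best],
                 rise_tau = rise_tau,
                 baseline_rmse_mean = b_mean, baseline_rmse_sd = b_sd,
                 accepted = accepted),
            class = "voltcon_epsp_fit")
}

#' Remove trigger segments contaminated by postsynaptic spikes
#'
#' Drops every trigger whose postsynaptic cell fired within 15 ms before
#' or 50 ms after the presynaptic AP peak, then re-averages.
#'
#' @param segs Output of [pair_segments()].
#' @param post_spike_times Postsynaptic spike times (ms, global).
#' @param window Contamination window (ms relative to the trigger).
#' @return List with `avg` (decontaminated average or `NULL` when every
#'   segment was removed), `removed` (count), `fraction`, `n_kept`.
#' @export
decontaminate <- function(segs, post_spike_times, window = c(-15, 50)) {
  trig <- segs$triggers
  contaminated <- vapply(trig, function(t) {
    any(post_spike_times >= t + window[1] & post_spike_times <= t + window[2])
  }, logical(1))
  kept <- segs$segments[!contaminated, , drop = FALSE]
  list(avg = if (nrow(kept)) colMeans(kept) else NULL,
       removed = sum(contaminated),
       fraction = if (length(trig)) sum(contaminated) / length(trig) else 0,
       n_kept = nrow(kept))
}

#' EPSP kinetics from an averaged trace
#'
#' Amplitude above the pre-trigger baseline, single-exponential decay time
#' constant fitted from the peak over the following 40 ms (grid/golden
#' search over tau with the gain and offset profiled out), and the
#' half-width at half amplitude (linear interpolation on both flanks).
#'
#' @param avg AP%-normalised average trace.
#' @param window Trace window (ms).
#' @return List with `amplitude`, `onset`, `peak_t`, `decay_tau`,
#'   `half_width`, `r_squared` of the decay fit.
#' @export
epsp_kinetics <- function(avg, window = c(-45, 50)) {
  offs <- window[1]:window[2]
  base_idx <- which(offs <= -5)
  b0 <- mean(avg[base_idx])
  post_idx <- which(offs >= 0 & offs <= 30)
  rel <- avg[post_idx] - b0
  pk <- which.max(rel)
  amp <- rel[pk]
  peak_t <- offs[post_idx][pk]

  # decay fit: y(t) = b + A exp(-(t - t_peak)/tau) on [peak, peak + 40]
  dec_idx <- which(offs >= peak_t & offs <= peak_t + 40)
  t <- offs[dec_idx] - peak_t
  y <- avg[dec_idx]
  sse_tau <- function(tau) {
    e <- exp(-t / tau)
    fit <- stats::lm.fit(cbind(1, e), y)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(sse_tau, interval = c(1, 100))
  tau <- opt$minimum
  e <- exp(-t / tau)
  fit <- stats::lm.fit(cbind(1, e), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)

  # half-width at half amplitude, interpolated
  half <- b0 + amp / 2
  rise_region <- which(offs <= peak_t)
  fall_region <- which(offs >= peak_t)
  t_rise <- interp_crossing(offs[rise_region], avg[rise_region], half,
                            rising = TRUE)
  t_fall <- interp_crossing(offs[fall_region], avg[fall_region], half,
                            rising = FALSE)
  hw <- if (is.na(t_rise) || is.na(t_fall)) NA_real_ else t_fall - t_rise

  list(amplitude = amp, peak_t = peak_t, decay_tau = tau,
       half_width = hw, r_squared = r2)
}

# last upward (rising) or first downward (falling) crossing of `level`
interp_crossing <- function(t, y, level, rising = TRUE) {
  above <- y >= level
  if (rising) {
    k <- which(!above[-length(above)] & above[-1])
    if (!length(k)) return(NA_real_)
    k <- max(k)
  } else {
    k <- which(above[-length(above)] & !above[-1])
    if (!length(k)) return(NA_real_)
    k <- min(k)
  }
  t[k] + (level - y[k]) / (y[k + 1] - y[k]) * (t[k + 1] - t[k])
}

#' Presentation-only smoothing (Savitzky-Golay)
#'
#' 5-point first-order Savitzky-Golay filter used for figures only; no
#' analysis operation consumes smoothed traces.
#'
#' @param values Numeric trace.
#' @return Smoothed trace.
#' @export
smooth_presentation <- function(values) {
  as.numeric(signal::sgolayfilt(values, p = 1, n = 5))
}
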