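#' @keywords internal
#' Unit-peak biexponential kernel sampled at 1 ms
#'
#' `k(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / peak`, zero before `t = 0`.
biexp_kernel <- function(tau_rise, tau_decay, length_ms = NULL) {
  if (is.null(length_ms)) length_ms <- ceiling(6 * tau_decay)
  t <- seq(0, length_ms)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

# Optical AP waveform of one cell: fast biexponential spike plus an
# afterdepolarisation component whose mean over 15-40 ms post-peak equals
# adp_frac of the peak. Interneurons get a narrower spike and an AHP.
ap_waveform <- function(type = "PC", adp_frac = 0, length_ms = 80) {
  if (type == "PC") {
    spike <- biexp_kernel(1.0, 2.2, length_ms)
  } else {
    spike <- biexp_kernel(0.4, 1.1, length_ms)
  }
  peak_at <- which.max(spike)
  w <- spike
  if (adp_frac != 0) {
    t <- seq_along(spike) - peak_at
    adp <- ifelse(t > 0, (1 - exp(-t / 4)) * exp(-t / 30), 0)
    sel <- t >= 15 & t <= 40
    adp <- adp / mean(adp[sel]) * adp_frac
    w <- spike + adp
  }
  list(values = w / max(w), peak_at = peak_at)
}

# Per-cell fractional fluorescence drop time series (positive = darker),
# i.e. the noiseless -dF/F signal of that cell.
cell_drop_signal <- function(gt, cfg, cell_idx, total_ms) {
  cell <- gt$cells[cell_idx, ]
  sig <- numeric(total_ms)
  wf <- ap_waveform(cell$type, cell$adp_frac)
  spikes <- gt$spikes[[cell$cell_id]]
  sig <- add_kernel(sig, spikes - (wf$peak_at - 1), wf$values * cell$ap_peak_dff)
  inc <- gt$edges[gt$edges$post == cell$cell_id, , drop = FALSE]
  if (nrow(inc)) {
    for (e in seq_len(nrow(inc))) {
      pre_s <- gt$spikes[[inc$pre[e]]]
      if (!length(pre_s)) next
      ek <- biexp_kernel(cfg$epsp_rise_tau, inc$tau_decay[e])
      amp_dff <- inc$amp_ap_pct[e] / 100 * cell$ap_peak_dff
      sig <- add_kernel(sig, pre_s + cfg$synaptic_delay, ek * amp_dff)
    }
  }
  sig
}

# Add `kernel` starting at each (0-based ms) onset time; clips at both ends.
add_kernel <- function(sig, onsets, kernel) {
  n <- length(sig); kl <- length(kernel)
  for (t0 in onsets) {
    i0 <- floor(t0) + 1L
    if (i0 > n) next
    j0 <- 1L
    if (i0 < 1L) { j0 <- 2L - i0; i0 <- 1L }
    i1 <- min(n, i0 + (kl - j0))
    j1 <- j0 + (i1 - i0)
    sig[i0:i1] <- sig[i0:i1] + kernel[j0:j1]
  }
  sig
}

bleach_curve <- function(cfg) {
  u <- (seq_len(cfg$frames_per_trial) - 1) / (cfg$frames_per_trial - 1)
  c3 <- cfg$bleach_coeffs
  1 + c3[1] * u + c3[2] * u^2 + c3[3] * u^3
}

crosstalk_matrix <- function(gt, cfg) {
  n <- nrow(gt$cells)
  ct <- matrix(0, n, n)
  if (cfg$crosstalk_frac > 0) {
    d <- as.matrix(stats::dist(gt$cells[, c("y_um", "x_um")]))
    ct[d < cfg$crosstalk_radius] <- cfg$crosstalk_frac
    diag(ct) <- 0
  }
  ct
}

#' Render per-cell fluorescence traces
#'
#' Produces the ROI-mean raw fluorescence trace of every cell under the
#' same optical model as [render_movie()] (baseline x per-trial bleach
#' polynomial x (1 - summed AP/EPSP kernel drops) + Gaussian noise), but
#' without rasterising pixels. The trace noise SD equals
#' `ap_peak_dff / ap_snr` in fractional-fluorescence units, i.e. what the
#' ROI average of the pixel movie would show. This is the generator
#' backend used for large simulated experiments that enter the analysis
#' pipeline at the trace stage.
#'
#' @param gt Ground truth with spikes ([generate_spikes()]).
#' @param cfg Configuration (defaults to `gt$cfg`).
#' @param noise_sd Override for the trace noise SD (fractional
#'   fluorescence); `NULL` uses `ap_peak_dff / ap_snr` per cell.
#' @return List with `traces` (frames x cells matrix of raw fluorescence,
#'   arbitrary units), `frames_per_trial`, and `f0` (per-cell baseline).
#' @export
render_traces <- function(gt, cfg = gt$cfg, noise_sd = NULL) {
  stopifnot(!is.null(gt$spikes))
  set.seed(cfg$seed + 2L)
  total_ms <- cfg$n_trials * cfg$frames_per_trial
  n <- nrow(gt$cells)
  bleach <- rep(bleach_curve(cfg), cfg$n_trials)
  f0 <- 1000 * stats::rlnorm(n, 0, 0.1)
  ct <- crosstalk_matrix(gt, cfg)

  drops <- matrix(0, total_ms, n)
  for (i in seq_len(n)) drops[, i] <- cell_drop_signal(gt, cfg, i, total_ms)
  if (any(ct > 0)) drops <- drops + drops %*% t(ct)

  traces <- matrix(0, total_ms, n)
  for (i in seq_len(n)) {
    sd_i <- if (is.null(noise_sd)) {
      gt$cells$ap_peak_dff[i] / cfg$ap_snr
    } else noise_sd
    eps <- if (sd_i > 0) stats::rnorm(total_ms, 0, sd_i * f0[i]) else 0
    traces[, i] <- f0[i] * bleach * (1 - drops[, i]) + eps
  }
  colnames(traces) <- gt$cells$cell_id
  list(traces = traces, frames_per_trial = cfg$frames_per_trial, f0 = f0)
}

#' Render a synthetic voltage-imaging movie
#'
#' Per-pixel fluorescence is `baseline_map x bleach(t) x (1 - drop(t)) +
#' noise`, where `drop` sums the negative-going AP transient (scaled to the
#' cell's `ap_peak_dff`) and incoming EPSP kernels (scaled in AP% of the
#' cell's AP) over the cell's ROI, with optional cross-talk bleed between
#' nearby cells. Pixel noise is scaled so that the ROI-mean trace has the
#' configured `ap_snr`.
#'
#' @inheritParams render_traces
#' @param noise Logical; `FALSE` renders the noiseless movie.
#' @return A [movie_stack()] object.
#' @export
render_movie <- function(gt, cfg = gt$cfg, noise = TRUE) {
  stopifnot(!is.null(gt$spikes))
  set.seed(cfg$seed + 3L)
  total_ms <- cfg$n_trials * cfg$frames_per_trial
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  n <- nrow(gt$cells)

  background <- 300
  roi_level <- 1000
  base_map <- matrix(background, nr, nc)
  for (i in seq_len(n)) {
    px <- gt$rois[[i]]
    base_map[px] <- roi_level
  }

  bleach <- rep(bleach_curve(cfg), cfg$n_trials)
  ct <- crosstalk_matrix(gt, cfg)
  drops <- matrix(0, total_ms, n)
  for (i in seq_len(n)) drops[, i] <- cell_drop_signal(gt, cfg, i, total_ms)
  if (any(ct > 0)) drops <- drops + drops %*% t(ct)

  # baseline x bleach everywhere, then carve the cell signals into the ROIs
  data <- outer(bleach, base_map)
  for (i in seq_len(n)) {
    px <- gt$rois[[i]]
    for (k in seq_len(nrow(px))) {
      data[, px[k, 1], px[k, 2]] <- data[, px[k, 1], px[k, 2]] *
        (1 - drops[, i])
    }
  }
  if (noise) {
    for (i in seq_len(n)) {
      px <- gt$rois[[i]]
      sd_px <- gt$cells$ap_peak_dff[i] * roi_level *
        sqrt(nrow(px)) / cfg$ap_snr
      for (k in seq_len(nrow(px))) {
        data[, px[k, 1], px[k, 2]] <- data[, px[k, 1], px[k, 2]] +
          stats::rnorm(total_ms, 0, sd_px)
      }
    }
    bg_sd <- 0.003 * background
    data <- data + array(stats::rnorm(length(data), 0, bg_sd), dim = dim(data))
  }
  movie_stack(data, frames_per_trial = cfg$frames_per_trial,
              pixel_size = cfg$pixel_size, dark_subtracted = TRUE)
}

#' Write a synthetic dataset to disk
#'
#' One 16-bit multi-page TIFF per trial, a JSON ground-truth sidecar
#' (spikes, edges, ROI pixels, AP amplitudes) and a YAML echo of the
#' configuration.
#'
#' @param movie A [movie_stack()].
#' @param gt Ground truth.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(movie, gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiffs <- write_movie_tiff(movie, dir)
  sidecar <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(spikes = gt$spikes,
         edges = gt$edges,
         rois = lapply(gt$rois, function(p) as.data.frame(p)),
         ap_peak_dff = stats::setNames(as.list(gt$cells$ap_peak_dff),
                                       gt$cells$cell_id)),
    sidecar, digits = NA, auto_unbox = TRUE)
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- gt$cfg
  cfg$block_rates <- NULL
  yaml::write_yaml(unclass(cfg), cfg_path)
  invisible(c(tiffs, sidecar, cfg_path))
}
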