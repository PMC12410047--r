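#' Configuration for the synthetic voltage-imaging generator
#'
#' Bundles every parameter of the synthetic experiment: the trial structure
#' of the recording, the imaged field, the cell population, baseline firing
#' rates, the directed connection graph, unitary EPSP kinetics, the
#' spike-transmission model, and the optical model (AP signal-to-noise,
#' photobleaching, cross-talk). The defaults describe the experimental
#' regime the analysis is designed for: 2,200-frame trials at 1 kHz,
#' pyramidal cells firing spontaneously at 1.31 Hz, a 5.3 % directed
#' connection probability, EPSPs of 0.2-15 % of the postsynaptic AP peak
#' with 3 ms rise and 8-22 ms decay, and excess postsynaptic firing in a
#' 4-19 ms window after each presynaptic spike.
#'
#' @param n_trials Number of repeated trials (image sequences).
#' @param frames_per_trial Frames per trial; 1 frame is 1 ms.
#' @param frame_rate Acquisition rate in Hz. Fixed at 1000.
#' @param field_shape Imaged field as `c(rows, cols)` in pixels.
#' @param pixel_size Pixel edge in micrometres.
#' @param n_pcs,n_ins Number of pyramidal cells and interneurons.
#' @param pc_rate,in_rate Baseline firing rates (Hz).
#' @param connection_prob Directed PC to PC connection probability.
#' @param pc_in_prob Directed PC to IN connection probability.
#' @param epsp_amp_range Allowed unitary EPSP amplitudes, in percent of the
#'   postsynaptic AP peak (AP%).
#' @param epsp_amp_median,epsp_amp_sdlog Median and log-SD of the lognormal
#'   amplitude draw (truncated to `epsp_amp_range`).
#' @param epsp_amp_mean Population mean amplitude (AP%) used to scale the
#'   per-edge transmission gain.
#' @param epsp_rise_tau EPSP rise time constant (ms).
#' @param epsp_tau_range Per-edge decay time constants drawn uniformly from
#'   this range (ms).
#' @param transmission_window Window after the presynaptic AP peak in which
#'   postsynaptic firing is elevated (ms).
#' @param transmission_rate_gain Added postsynaptic rate (Hz) inside the
#'   transmission window for an edge of mean amplitude.
#' @param synaptic_delay Delay from presynaptic AP peak to EPSP onset
#'   (ms); default mid-way in the 2-3 frame post-AP range where the
#'   constrained fit is observed to be optimal.
#' @param refractory_ms Absolute refractory period of generated trains.
#' @param burst_prob Probability that a spike of an aAP-class cell is
#'   followed by a doublet partner 8-20 ms later.
#' @param adp_mix Proportions `c(aAP = ..., rAP = ...)` of the two
#'   afterdepolarisation classes among PCs.
#' @param ap_snr Peak-to-noise ratio of a single optical AP on the ROI-mean
#'   trace.
#' @param ap_peak_dff Mean optical AP peak amplitude (fractional
#'   fluorescence drop).
#' @param bleach_coeffs Polynomial coefficients `c(c1, c2, c3)` of the
#'   per-trial multiplicative photobleaching curve
#'   `1 + c1*u + c2*u^2 + c3*u^3`, `u` in `[0, 1]` across the trial.
#' @param crosstalk_radius Distance (micrometres) under which optical
#'   cross-talk between cells can occur.
#' @param crosstalk_frac Fraction of a cell's optical signal bled onto
#'   neighbours within `crosstalk_radius` (0 disables cross-talk).
#' @param min_separation Minimum centroid separation between somata
#'   (micrometres).
#' @param block_rates Optional square matrix of group-specific connection
#'   probabilities (rows = presynaptic group, columns = postsynaptic group)
#'   keyed by ADP class (`"aAP"`, `"rAP"`); overrides `connection_prob`
#'   for PC pairs whose groups are both named in it.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the generated experiment.
#'
#' @return A `voltcon_config` list.
#' @export
gen_config <- function(n_trials = 100,
                       frames_per_trial = 2200,
                       frame_rate = 1000,
                       field_shape = c(128, 96),
                       pixel_size = 1.87,
                       n_pcs = 10,
                       n_ins = 2,
                       pc_rate = 1.31,
                       in_rate = 4.0,
                       connection_prob = 0.053,
                       pc_in_prob = 0.0718,
                       epsp_amp_range = c(0.2, 15),
                       epsp_amp_median = 2.3,
                       epsp_amp_sdlog = 0.8,
                       epsp_amp_mean = 2.69,
                       epsp_rise_tau = 3,
                       epsp_tau_range = c(8, 22),
                       transmission_window = c(4, 19),
                       transmission_rate_gain = 3.5 - 1.31,
                       synaptic_delay = 2.5,
                       refractory_ms = 5,
                       burst_prob = 0,
                       adp_mix = c(aAP = 0.4, rAP = 0.6),
                       ap_snr = 15,
                       ap_peak_dff = 0.04,
                       bleach_coeffs = c(-0.05, 0.02, -0.005),
                       crosstalk_radius = 50,
                       crosstalk_frac = 0,
                       min_separation = 25,
                       block_rates = NULL,
                       seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    frames_per_trial = as.integer(frames_per_trial),
    frame_rate = frame_rate,
    field_shape = as.integer(field_shape),
    pixel_size = pixel_size,
    n_pcs = as.integer(n_pcs),
    n_ins = as.integer(n_ins),
    pc_rate = pc_rate,
    in_rate = in_rate,
    connection_prob = connection_prob,
    pc_in_prob = pc_in_prob,
    epsp_amp_range = epsp_amp_range,
    epsp_amp_median = epsp_amp_median,
    epsp_amp_sdlog = epsp_amp_sdlog,
    epsp_amp_mean = epsp_amp_mean,
    epsp_rise_tau = epsp_rise_tau,
    epsp_tau_range = epsp_tau_range,
    transmission_window = transmission_window,
    transmission_rate_gain = transmission_rate_gain,
    synaptic_delay = synaptic_delay,
    refractory_ms = refractory_ms,
    burst_prob = burst_prob,
    adp_mix = adp_mix,
    ap_snr = ap_snr,
    ap_peak_dff = ap_peak_dff,
    bleach_coeffs = bleach_coeffs,
    crosstalk_radius = crosstalk_radius,
    crosstalk_frac = crosstalk_frac,
    min_separation = min_separation,
    block_rates = block_rates,
    seed = as.integer(seed)
  )
  class(cfg) <- "voltcon_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "voltcon_config"))
  if (cfg$frame_rate != 1000) {
    stop("frame_rate is fixed at 1000 Hz (1 frame = 1 ms)", call. = FALSE)
  }
  if (cfg$frames_per_trial < 100) {
    stop("frames_per_trial must be at least 100", call. = FALSE)
  }
  if (cfg$n_trials < 1) stop("n_trials must be positive", call. = FALSE)
  rates <- c(cfg$pc_rate, cfg$in_rate, cfg$transmission_rate_gain)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (cfg$connection_prob < 0 || cfg$connection_prob > 1) {
    stop("connection_prob must be a probability", call. = FALSE)
  }
  if (cfg$epsp_amp_range[1] < 0 || cfg$epsp_amp_range[2] > 100 ||
      diff(cfg$epsp_amp_range) <= 0) {
    stop("epsp_amp_range must be an increasing interval within [0, 100]",
         call. = FALSE)
  }
  if (diff(cfg$transmission_window) <= 0) {
    stop("transmission_window must be an increasing ms pair", call. = FALSE)
  }
  if (cfg$ap_snr <= 0) stop("ap_snr must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.voltcon_config <- function(x, ...) {
  cat("<voltcon_config>\n")
  cat(sprintf("  trials: %d x %d frames @ %g Hz\n",
              x$n_trials, x$frames_per_trial, x$frame_rate))
  cat(sprintf("  field: %d x %d px (%.2f um/px)\n",
              x$field_shape[1], x$field_shape[2], x$pixel_size))
  cat(sprintf("  cells: %d PCs @ %.2f Hz, %d INs @ %.2f Hz\n",
              x$n_pcs, x$pc_rate, x$n_ins, x$in_rate))
  cat(sprintf("  connectivity: p = %.3f; EPSP %.1f-%.1f AP%%, decay %g-%g ms\n",
              x$connection_prob, x$epsp_amp_range[1], x$epsp_amp_range[2],
              x$epsp_tau_range[1], x$epsp_tau_range[2]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
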