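#' Afterdepolarisation ratio of an AP template
#'
#' Mean template value 15-40 ms after the AP peak divided by the peak
#' amplitude (AP-up convention, so an afterhyperpolarisation yields a
#' negative ratio). Computed for every spiking cell, including
#' interneurons with an AHP.
#'
#' @param template Numeric AP-up template.
#' @param time Time axis in ms relative to the AP peak (0 at the peak);
#'   default assumes a -45..+50 ms template.
#' @return ADP ratio (fraction of the peak).
#' @export
adp_ratio <- function(template, time = seq_along(template) - 46) {
  peak_idx <- which(time == 0)
  if (!length(peak_idx)) peak_idx <- which.max(template)
  win <- time >= 15 & time <= 40
  mean(template[win]) / template[peak_idx]
}

#' Classify a cell by its ADP ratio
#'
#' aAP cells carry a significant afterdepolarisation (7-20 % of the
#' peak); rAP cells repolarise regularly (0-4 %). Ratios in the 4-7 % gap
#' or out of range are left unclassified rather than force-assigned.
#'
#' @param ratio ADP ratio from [adp_ratio()].
#' @return `"aAP"`, `"rAP"` or `"unclassified"`.
#' @export
classify_adp <- function(ratio) {
  if (is.na(ratio)) return("unclassified")
  if (ratio >= 0.07 && ratio <= 0.20) return("aAP")
  if (ratio >= 0.00 && ratio <= 0.04) return("rAP")
  "unclassified"
}

#' Detect bursting from a spike train
#'
#' A cell bursts when at least 10 % of its APs are preceded by another AP
#' within 25 ms.
#'
#' @param spike_times Sorted spike times (ms).
#' @param isi_ms Predecessor window (25 ms).
#' @param min_fraction Burst threshold (0.10).
#' @return List with `bursting` (logical) and `fraction`.
#' @export
detect_bursting <- function(spike_times, isi_ms = 25, min_fraction = 0.10) {
  n <- length(spike_times)
  if (n < 2) return(list(bursting = FALSE, fraction = 0))
  preceded <- sum(diff(spike_times) <= isi_ms)
  frac <- preceded / n
  list(bursting = frac >= min_fraction, fraction = frac)
}

#' Pyramidal-layer annotation
#'
#' The two edges of the stratum pyramidale as polylines in micrometres.
#' The orientation convention is that depth 0 lies on the deep edge and
#' depth 1 on the superficial edge.
#'
#' @param deep_edge,superficial_edge Data frames (or matrices) with
#'   columns `x`, `y` in micrometres, ordered along the layer.
#' @return A `voltcon_layers` object.
#' @export
layer_annotation <- function(deep_edge, superficial_edge) {
  deep_edge <- as.data.frame(deep_edge)
  superficial_edge <- as.data.frame(superficial_edge)
  stopifnot(all(c("x", "y") %in% names(deep_edge)),
            all(c("x", "y") %in% names(superficial_edge)))
  xs <- sort(unique(c(deep_edge$x, superficial_edge$x)))
  dy <- stats::approx(deep_edge$x, deep_edge$y, xout = xs, rule = 2)$y
  sy <- stats::approx(superficial_edge$x, superficial_edge$y, xout = xs,
                      rule = 2)$y
  gap <- sy - dy
  if (any(gap > 0) && any(gap < 0)) {
    stop("layer boundaries cross", call. = FALSE)
  }
  structure(list(deep = deep_edge, superficial = superficial_edge),
            class = "voltcon_layers")
}

#' Read a layer annotation from a JSON of polyline vertices
#'
#' @param path JSON file with objects `deep` and `superficial`, each a
#'   list of `x`/`y` vertices in micrometres.
#' @return A [layer_annotation()].
#' @export
read_layer_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  layer_annotation(j$deep, j$superficial)
}

#' Assign a soma to a sublayer of the pyramidal layer
#'
#' The normalised depth `d` of the soma between the deep (0) and
#' superficial (1) boundary (evaluated at the soma's x position) is
#' trisected with half-open bins: `[0, 1/3)` deep, `[1/3, 2/3)` middle,
#' `[2/3, 1]` superficial; somata outside the layer are flagged.
#'
#' @param soma_xy Numeric `c(x, y)` in micrometres (or the normalised
#'   depth itself when `layers` is `NULL`).
#' @param layers A [layer_annotation()] or `NULL`.
#' @return `"deep"`, `"middle"`, `"superficial"` or `"outside"`.
#' @export
assign_sublayer <- function(soma_xy, layers = NULL) {
  d <- if (is.null(layers)) {
    soma_xy[1]
  } else {
    y_deep <- stats::approx(layers$deep$x, layers$deep$y, xout = soma_xy[1],
                            rule = 2)$y
    y_sup <- stats::approx(layers$superficial$x, layers$superficial$y,
                           xout = soma_xy[1], rule = 2)$y
    (soma_xy[2] - y_deep) / (y_sup - y_deep)
  }
  if (is.na(d) || d < 0 || d > 1) return("outside")
  if (d < 1 / 3) "deep" else if (d < 2 / 3) "middle" else "superficial"
}

#' Template full width at half maximum
#'
#' @param template AP-up template.
#' @param time Time axis (ms).
#' @return FWHM in ms (interpolated).
#' @export
template_fwhm <- function(template, time = seq_along(template) - 46) {
  pk <- which.max(template)
  half <- template[pk] / 2
  t_rise <- interp_crossing(time[seq_len(pk)], template[seq_len(pk)], half,
                            rising = TRUE)
  t_fall <- interp_crossing(time[pk:length(time)],
                            template[pk:length(template)], half,
                            rising = FALSE)
  if (is.na(t_rise) || is.na(t_fall)) return(NA_real_)
  t_fall - t_rise
}

#' Heuristic pyramidal-cell / interneuron classification
#'
#' Pyramidal cells have wider optical APs, sit in the cell layer, and
#' fire fewer spikes per experiment than interneurons. The rule: wide
#' template and (low spike count or in-layer soma) gives PC; narrow
#' template and (high spike count or out-of-layer soma) gives IN;
#' everything else is unknown and excluded from PC-PC rates. A
#' ground-truth or post hoc anatomy label overrides the heuristic when
#' supplied.
#'
#' @param template AP-up template (or `NULL` when `fwhm` is given).
#' @param n_spikes Spike count over the experiment.
#' @param in_layer Logical: soma inside the pyramidal layer.
#' @param fwhm Template FWHM (ms), computed from `template` if missing.
#' @param width_thresh FWHM boundary (ms); calibrated on synthetic
#'   templates, not claimed to reproduce anatomy-assisted assignments.
#' @param count_thresh Spike-count boundary.
#' @param override Optional known label (`"PC"`/`"IN"`).
#' @return `"PC"`, `"IN"` or `"unknown"`.
#' @export
classify_pc_in <- function(template = NULL, n_spikes, in_layer = NA,
                           fwhm = NULL, width_thresh = 2.0,
                           count_thresh = 300, override = NULL) {
  if (!is.null(override) && !is.na(override)) return(override)
  if (is.null(fwhm)) fwhm <- template_fwhm(template)
  if (is.na(fwhm)) return("unknown")
  wide <- fwhm >= width_thresh
  low_count <- n_spikes < count_thresh
  if (wide && (low_count || isTRUE(in_layer))) return("PC")
  if (!wide && (!low_count || identical(in_layer, FALSE))) return("IN")
  "unknown"
}
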