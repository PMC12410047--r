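#' Generate the ground-truth cell population and connection graph
#'
#' Places somata in the imaged field (pyramidal cells inside a horizontal
#' band standing in for the cell layer, interneurons anywhere), draws
#' non-overlapping elliptical ROIs, assigns per-cell optical AP amplitudes
#' and firing-property classes, and wires a directed Erdos-Renyi graph over
#' the pyramidal cells at the configured connection probability (optionally
#' block-structured by ADP class). Each edge carries a lognormal EPSP
#' amplitude (AP%) truncated to the configured range and a uniform decay
#' time constant.
#'
#' @param cfg A [gen_config()] object.
#' @return A `voltcon_ground_truth` list with elements `cfg`, `cells`
#'   (data frame), `rois` (list of pixel matrices), `edges` (data frame
#'   with `pre`, `post`, `amp_ap_pct`, `tau_decay`) and `spikes`
#'   (`NULL` until [generate_spikes()] is called).
#' @export
generate_network <- function(cfg) {
  validate_config(cfg)
  if (cfg$n_pcs < 2) stop("need at least 2 pyramidal cells", call. = FALSE)
  set.seed(cfg$seed)

  n <- cfg$n_pcs + cfg$n_ins
  field_um <- cfg$field_shape * cfg$pixel_size # rows (y), cols (x)

  # the pyramidal layer occupies a central horizontal band of the field;
  # depth 0 = deep edge, 1 = superficial edge of that band
  band <- c(0.30, 0.70) * field_um[1]
  pos <- place_somata(n, cfg$n_pcs, field_um, band, cfg$min_separation)

  type <- c(rep("PC", cfg$n_pcs), rep("IN", cfg$n_ins))
  depth <- ifelse(type == "PC",
                  (pos[, 1] - band[1]) / diff(band), NA_real_)

  adp_class <- rep(NA_character_, n)
  adp_frac <- rep(0, n)
  is_pc <- type == "PC"
  n_aap <- round(cfg$adp_mix[["aAP"]] * cfg$n_pcs)
  aap_idx <- sample(which(is_pc), n_aap)
  adp_class[is_pc] <- "rAP"
  adp_class[aap_idx] <- "aAP"
  adp_frac[is_pc] <- stats::runif(cfg$n_pcs, 0.00, 0.04)
  adp_frac[aap_idx] <- stats::runif(n_aap, 0.07, 0.20)

  cells <- data.frame(
    cell_id = sprintf("c%02d", seq_len(n)),
    type = type,
    y_um = pos[, 1],
    x_um = pos[, 2],
    depth = depth,
    adp_class = adp_class,
    adp_frac = adp_frac,
    burst_prob = ifelse(!is.na(adp_class) & adp_class == "aAP",
                        cfg$burst_prob, 0),
    rate_hz = ifelse(type == "PC", cfg$pc_rate, cfg$in_rate),
    # cell-to-cell variability of the optical AP peak (fluorescence units)
    ap_peak_dff = cfg$ap_peak_dff * stats::rlnorm(n, 0, 0.15),
    diameter_um = stats::runif(n, 10, 20),
    stringsAsFactors = FALSE
  )

  rois <- lapply(seq_len(n), function(i) {
    ellipse_roi(pos[i, ], cells$diameter_um[i], cfg$field_shape,
                cfg$pixel_size)
  })
  names(rois) <- cells$cell_id
  overlap <- check_roi_overlap(rois)
  if (overlap) stop("generated ROIs overlap; increase min_separation",
                    call. = FALSE)

  edges <- draw_edges(cells, cfg)

  gt <- list(cfg = cfg, cells = cells, rois = rois, edges = edges,
             layer_band_um = band, spikes = NULL)
  class(gt) <- "voltcon_ground_truth"
  gt
}

place_somata <- function(n, n_pcs, field_um, band, min_sep) {
  pos <- matrix(NA_real_, n, 2)
  margin <- 12 # keep ROIs inside the field
  for (i in seq_len(n)) {
    for (try in seq_len(5000)) {
      if (i <= n_pcs) {
        y <- stats::runif(1, band[1], band[2])
      } else {
        y <- stats::runif(1, margin, field_um[1] - margin)
      }
      x <- stats::runif(1, margin, field_um[2] - margin)
      if (i == 1) { pos[i, ] <- c(y, x); break }
      d <- sqrt((pos[seq_len(i - 1), 1] - y)^2 +
                  (pos[seq_len(i - 1), 2] - x)^2)
      if (all(d >= min_sep, na.rm = TRUE)) { pos[i, ] <- c(y, x); break }
    }
    if (is.na(pos[i, 1])) {
      stop("could not place ", n, " somata at min_separation = ", min_sep,
           " um in a ", round(field_um[1]), " x ", round(field_um[2]),
           " um field", call. = FALSE)
    }
  }
  pos
}

ellipse_roi <- function(centre_um, diameter_um, field_shape, pixel_size) {
  a <- diameter_um / 2            # semi-axis along rows
  b <- diameter_um / 2 * 0.8      # slightly elongated soma
  cy <- centre_um[1] / pixel_size
  cx <- centre_um[2] / pixel_size
  ry <- ceiling(a / pixel_size)
  rx <- ceiling(b / pixel_size)
  rows <- max(1, floor(cy - ry)):min(field_shape[1], ceiling(cy + ry))
  cols <- max(1, floor(cx - rx)):min(field_shape[2], ceiling(cx + rx))
  grid <- expand.grid(row = rows, col = cols)
  inside <- ((grid$row - cy) * pixel_size / a)^2 +
    ((grid$col - cx) * pixel_size / b)^2 <= 1
  px <- as.matrix(grid[inside, , drop = FALSE])
  if (nrow(px) == 0) px <- matrix(c(round(cy), round(cx)), 1, 2,
                                  dimnames = list(NULL, c("row", "col")))
  px
}

check_roi_overlap <- function(rois) {
  keys <- unlist(lapply(rois, function(p) p[, 1] * 1e5 + p[, 2]))
  any(duplicated(keys))
}

draw_edges <- function(cells, cfg) {
  pre <- character(0); post <- character(0)
  pcs <- which(cells$type == "PC")
  ins <- which(cells$type == "IN")
  for (i in pcs) {
    for (j in pcs) {
      if (i == j) next
      p <- cfg$connection_prob
      if (!is.null(cfg$block_rates)) {
        gi <- cells$adp_class[i]; gj <- cells$adp_class[j]
        if (gi %in% rownames(cfg$block_rates) &&
            gj %in% colnames(cfg$block_rates)) {
          p <- cfg$block_rates[gi, gj]
        }
      }
      if (stats::runif(1) < p) {
        pre <- c(pre, cells$cell_id[i]); post <- c(post, cells$cell_id[j])
      }
    }
    for (j in ins) {
      if (stats::runif(1) < cfg$pc_in_prob) {
        pre <- c(pre, cells$cell_id[i]); post <- c(post, cells$cell_id[j])
      }
    }
  }
  k <- length(pre)
  amp <- numeric(k)
  for (e in seq_len(k)) {
    repeat {
      a <- stats::rlnorm(1, log(cfg$epsp_amp_median), cfg$epsp_amp_sdlog)
      if (a >= cfg$epsp_amp_range[1] && a <= cfg$epsp_amp_range[2]) break
    }
    amp[e] <- a
  }
  data.frame(pre = pre, post = post, amp_ap_pct = amp,
             tau_decay = stats::runif(k, cfg$epsp_tau_range[1],
                                      cfg$epsp_tau_range[2]),
             stringsAsFactors = FALSE)
}

#' Generate ground-truth spike trains
#'
#' Baseline firing is homogeneous Poisson per cell at its configured rate,
#' restricted to the trial windows. For every presynaptic spike on an edge,
#' the postsynaptic cell's instantaneous rate is raised by
#' `transmission_rate_gain * amp / epsp_amp_mean` inside the transmission
#' window (4-19 ms after the presynaptic peak by default); the excess
#' spikes are drawn by Poisson thinning and must fall inside the same
#' trial. aAP-class cells may fire doublets. A 5 ms absolute refractory
#' period is enforced on the merged train.
#'
#' @param gt Output of [generate_network()].
#' @param cfg The same configuration (defaults to `gt$cfg`).
#' @return `gt` with `spikes`: a named list of strictly increasing global
#'   spike times in ms (global time = trial_index * frames_per_trial +
#'   frame; 1 frame = 1 ms).
#' @export
generate_spikes <- function(gt, cfg = gt$cfg) {
  stopifnot(inherits(gt, "voltcon_ground_truth"))
  set.seed(cfg$seed + 1L)
  fpt <- cfg$frames_per_trial
  total_ms <- cfg$n_trials * fpt

  base <- lapply(seq_len(nrow(gt$cells)), function(i) {
    r <- gt$cells$rate_hz[i]
    if (r <= 0) return(numeric(0))
    k <- stats::rpois(1, r * total_ms / 1000)
    sort(stats::runif(k, 0, total_ms))
  })
  names(base) <- gt$cells$cell_id

  # doublet mechanism for bursting cells
  for (i in seq_len(nrow(gt$cells))) {
    bp <- gt$cells$burst_prob[i]
    if (bp > 0 && length(base[[i]]) > 0) {
      s <- base[[i]]
      doublet <- s[stats::runif(length(s)) < bp]
      if (length(doublet)) {
        base[[i]] <- sort(c(s, doublet + stats::runif(length(doublet), 8, 20)))
      }
    }
  }

  # synaptic transmission by thinning: excess Poisson mass in the window
  if (nrow(gt$edges) > 0) {
    win <- cfg$transmission_window
    w_s <- diff(win) / 1000
    for (e in seq_len(nrow(gt$edges))) {
      pre_s <- base[[gt$edges$pre[e]]]
      if (!length(pre_s)) next
      gain <- cfg$transmission_rate_gain *
        gt$edges$amp_ap_pct[e] / cfg$epsp_amp_mean
      k <- stats::rpois(length(pre_s), gain * w_s)
      if (!sum(k)) next
      src <- rep(pre_s, k)
      ext <- src + stats::runif(sum(k), win[1], win[2])
      same_trial <- floor(src / fpt) == floor(ext / fpt)
      ext <- ext[same_trial & ext < total_ms]
      j <- gt$edges$post[e]
      base[[j]] <- sort(c(base[[j]], ext))
    }
  }

  gt$spikes <- lapply(base, enforce_refractory, refractory = cfg$refractory_ms)
  gt
}

enforce_refractory <- function(times, refractory) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' @export
print.voltcon_ground_truth <- function(x, ...) {
  cat("<voltcon_ground_truth>\n")
  cat(sprintf("  %d cells (%d PC, %d IN), %d directed edges\n",
              nrow(x$cells), sum(x$cells$type == "PC"),
              sum(x$cells$type == "IN"), nrow(x$edges)))
  if (!is.null(x$spikes)) {
    cat(sprintf("  spikes: median %g per cell\n",
                stats::median(lengths(x$spikes))))
  }
  invisible(x)
}
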