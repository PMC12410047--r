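#' Simulate one synthetic experiment
#'
#' Network, spikes and ROI-mean fluorescence traces for one pseudo-slice.
#'
#' @param cfg A [gen_config()].
#' @return List with `raw` (frames x cells fluorescence matrix), `gt`
#'   (ground truth with spikes) and `cfg`.
#' @export
simulate_experiment <- function(cfg) {
  gt <- generate_network(cfg)
  gt <- generate_spikes(gt)
  rt <- render_traces(gt)
  list(raw = rt$traces, gt = gt, cfg = cfg)
}

#' Default analysis parameters
#'
#' Every tunable of the trace-level analysis pipeline in one place.
#'
#' @param thresh_factor Spike threshold in RMS multiples.
#' @param min_spikes QC minimum AP count.
#' @param cv_thresh QC peak-amplitude CV limit.
#' @param crosstalk_radius Adjacent-pair exclusion radius (um).
#' @param amp_range Candidate amplitude range (AP%).
#' @param baseline_sd_max Unstable-baseline limit (AP%).
#' @param contamination_max Maximum fraction of trigger segments removed
#'   by decontamination before the direction is excluded.
#' @param min_triggers Minimum decontaminated trigger count per pair.
#' @param k_sd RMSE-drop acceptance factor of the shift-window fit.
#' @return Named list.
#' @export
analysis_params <- function(thresh_factor = 5, min_spikes = 10,
                            cv_thresh = 0.5, crosstalk_radius = 50,
                            amp_range = c(0.2, 15), baseline_sd_max = 1.5,
                            contamination_max = 0.5, min_triggers = 10,
                            k_sd = 2) {
  list(thresh_factor = thresh_factor, min_spikes = min_spikes,
       cv_thresh = cv_thresh, crosstalk_radius = crosstalk_radius,
       amp_range = amp_range, baseline_sd_max = baseline_sd_max,
       contamination_max = contamination_max, min_triggers = min_triggers,
       k_sd = k_sd)
}

#' Analyse an experiment from per-cell traces
#'
#' The full trace-level pipeline: fractional-change conversion and bleach
#' correction, zero-phase 100 Hz filtering, iterative threshold spike
#' detection, QC, AP templates and AP-peak normalisation, firing-property
#' classification, cross-correlograms with cross-detection flags,
#' trigger-aligned pair averages with silent-cell baseline subtraction and
#' postsynaptic-spike decontamination, the candidate screen, and the
#' constrained shifting-window EPSP fit. Produces a cell table, a pair
#' table and a [connectivity_experiment()].
#'
#' @param raw Frames x cells matrix of raw ROI-mean fluorescence (column
#'   names are cell ids).
#' @param frames_per_trial Trial length in frames.
#' @param positions Optional data frame `cell_id`, `x_um`, `y_um` for the
#'   cross-talk distance exclusion.
#' @param depth Optional named numeric: normalised soma depth within the
#'   pyramidal layer (for sublayer labels).
#' @param type_override Optional named character of known cell types.
#' @param params [analysis_params()].
#' @param experiment_id Identifier.
#' @return List with `cells`, `pairs` (data frames), `spikes`, `traces`,
#'   `templates`, and `experiment`.
#' @export
analyze_traces <- function(raw, frames_per_trial, positions = NULL,
                           depth = NULL, type_override = NULL,
                           params = analysis_params(),
                           experiment_id = "exp1") {
  ids <- colnames(raw)
  traces <- traces_from_raw(raw, frames_per_trial)

  ## spike detection + QC
  spikes <- list(); amps <- list(); qc <- list()
  for (id in ids) {
    f <- lowpass_100hz(traces[[id]])
    det <- detect_spikes(f, thresh_factor = params$thresh_factor)
    spikes[[id]] <- det$spike_times
    amps[[id]] <- spike_peak_amplitudes(traces[[id]], det$spike_times)
    qc[[id]] <- qc_cell(det$spike_times, amps[[id]],
                        min_spikes = params$min_spikes,
                        cv_thresh = params$cv_thresh)
  }
  active <- ids[!vapply(qc, `[[`, logical(1), "excluded")]

  ## templates, AP peaks, classes
  templates <- list(); cells <- list()
  for (id in active) {
    tpl <- ap_template(traces[[id]], spikes[[id]])
    templates[[id]] <- tpl
    ratio <- adp_ratio(tpl$template, tpl$time)
    d <- if (!is.null(depth)) unname(depth[id]) else NA_real_
    in_layer <- if (is.na(d)) NA else (d >= 0 && d <= 1)
    type <- classify_pc_in(tpl$template, n_spikes = length(spikes[[id]]),
                           in_layer = in_layer,
                           override = type_override[[id]])
    burst <- detect_bursting(spikes[[id]])
    cells[[id]] <- data.frame(
      cell_id = id, type = type, n_spikes = length(spikes[[id]]),
      ap_peak = tpl$peak, adp_ratio = ratio,
      adp_class = classify_adp(ratio),
      bursting = burst$bursting, burst_fraction = burst$fraction,
      sublayer = if (is.na(d)) NA_character_ else assign_sublayer(d),
      depth = d, stringsAsFactors = FALSE)
  }
  cell_tab <- do.call(rbind, cells)
  rownames(cell_tab) <- NULL

  ## pairwise distances
  dist_um <- NULL
  if (!is.null(positions)) {
    m <- as.matrix(positions[, c("x_um", "y_um")])
    rownames(m) <- positions$cell_id
    dist_um <- as.matrix(stats::dist(m))
  }

  ## cross-detection screen over all ordered active pairs
  cross_flagged <- matrix(FALSE, length(active), length(active),
                          dimnames = list(active, active))
  for (a in active) for (b in active) {
    if (a == b) next
    cc <- crosscorr(spikes[[a]], spikes[[b]])
    cross_flagged[a, b] <- flag_cross_detection(cc)
  }

  ## pair testing: presynaptic cell must be a pyramidal cell
  pres <- cell_tab$cell_id[cell_tab$type == "PC"]
  n_act <- length(active)
  tested <- matrix(FALSE, n_act, n_act, dimnames = list(active, active))
  connected <- tested
  pair_rows <- list()
  win <- c(-45, 50)
  for (pre in pres) {
    pre_spk <- spikes[[pre]]
    segs_all <- list(); clean_avg <- list(); contaminated <- list()
    for (other in setdiff(active, pre)) {
      segs <- pair_segments(traces[[other]]$values, pre_spk,
                            frames_per_trial, window = win)
      segs_all[[other]] <- segs
      dec <- decontaminate(segs, spikes[[other]], window = win)
      clean_avg[[other]] <- dec$avg
      contaminated[[other]] <- dec$n_kept < 0.3 * nrow(segs$segments)
    }
    for (post in setdiff(active, pre)) {
      segs <- segs_all[[post]]
      dec <- decontaminate(segs, spikes[[post]])
      row <- list(pre = pre, post = post, status = "tested",
                  reason = NA_character_, n_triggers = nrow(segs$segments),
                  removed = dec$removed, removed_fraction = dec$fraction,
                  amp_ap_pct = NA_real_, tau_decay = NA_real_,
                  half_width = NA_real_, best_shift = NA_integer_)
      exclude <- function(reason) {
        row$status <<- "excluded"; row$reason <<- reason
      }
      if (cross_flagged[pre, post] || cross_flagged[post, pre]) {
        exclude("cross_detection")
      } else if (is.null(dec$avg) ||
                 dec$fraction > params$contamination_max ||
                 dec$n_kept < params$min_triggers) {
        exclude("ap_contaminated")
      } else {
        corr <- silent_cell_baseline(clean_avg, contaminated,
                                     exclude = c(pre, post), window = win)
        adj <- dec$avg - corr$correction
        ap_pct <- normalize_ap_percent(
          adj, cell_tab$ap_peak[cell_tab$cell_id == post])
        d_um <- if (!is.null(dist_um)) dist_um[pre, post] else NA
        scr <- candidate_screen(ap_pct, window = win, distance_um = d_um,
                                crosstalk_radius = params$crosstalk_radius,
                                amp_range = params$amp_range,
                                baseline_sd_max = params$baseline_sd_max)
        if (scr$status == "excluded") {
          exclude(scr$reason)
        } else if (scr$status == "candidate") {
          fit <- shift_window_fit(ap_pct, window = win, k_sd = params$k_sd)
          row$best_shift <- fit$best_shift
          if (fit$accepted) {
            kin <- epsp_kinetics(ap_pct, window = win)
            row$status <- "connected"
            row$amp_ap_pct <- fit$amp
            row$tau_decay <- fit$tau_decay
            row$half_width <- kin$half_width
          }
        }
      }
      if (row$status != "excluded") {
        tested[pre, post] <- TRUE
        connected[pre, post] <- row$status == "connected"
      }
      pair_rows[[paste(pre, post)]] <- as.data.frame(row,
                                                    stringsAsFactors = FALSE)
    }
  }
  pair_tab <- do.call(rbind, pair_rows)
  rownames(pair_tab) <- NULL

  exp <- connectivity_experiment(tested, connected, cell_ids = active,
                                 labels = cell_tab,
                                 experiment_id = experiment_id)
  list(cells = cell_tab, pairs = pair_tab, spikes = spikes,
       traces = traces, templates = templates, experiment = exp,
       qc = qc)
}

#' Compare a pipeline result against ground truth
#'
#' Joins detected spikes and accepted connections with the generator's
#' ground truth: spike recall/precision (tolerance +-1 ms), connection
#' recall over tested planted edges, false-positive rate over tested null
#' directions, and recovered-vs-planted amplitudes.
#'
#' @param result Output of [analyze_traces()].
#' @param gt The matching ground truth.
#' @param tol_ms Spike matching tolerance.
#' @return List of metrics.
#' @export
evaluate_against_truth <- function(result, gt, tol_ms = 1) {
  ids <- intersect(names(result$spikes), names(gt$spikes))
  tp <- 0; n_det <- 0; n_true <- 0; terr <- c()
  for (id in ids) {
    det <- result$spikes[[id]]; tru <- gt$spikes[[id]]
    n_det <- n_det + length(det); n_true <- n_true + length(tru)
    if (length(det) && length(tru)) {
      for (t in det) {
        d <- min(abs(tru - t))
        if (d <= tol_ms) { tp <- tp + 1; terr <- c(terr, d) }
      }
    }
  }
  pair_tab <- result$pairs
  tested <- pair_tab[pair_tab$status != "excluded", , drop = FALSE]
  edge_key <- paste(gt$edges$pre, gt$edges$post)
  tested_key <- paste(tested$pre, tested$post)
  planted <- tested_key %in% edge_key
  accepted <- tested$status == "connected"
  amp_pairs <- NULL
  if (any(planted & accepted)) {
    m <- match(tested_key[planted & accepted], edge_key)
    amp_pairs <- data.frame(planted = gt$edges$amp_ap_pct[m],
                            recovered = tested$amp_ap_pct[planted & accepted])
  }
  list(spike_recall = if (n_true) tp / n_true else NA,
       spike_precision = if (n_det) tp / n_det else NA,
       mean_timing_error_ms = if (length(terr)) mean(terr) else NA,
       n_tested = nrow(tested),
       n_planted_tested = sum(planted),
       connection_recall = if (sum(planted)) {
         sum(planted & accepted) / sum(planted)
       } else NA,
       false_positive_rate = if (sum(!planted)) {
         sum(!planted & accepted) / sum(!planted)
       } else NA,
       amp_pairs = amp_pairs)
}

#' Run the multi-slice parameter-recovery study
#'
#' Simulates a cohort of pseudo-slices at the configured connectivity and
#' amplitude regime, runs the full trace-level pipeline on each, pools
#' the results, and reports the recovered connectivity rate, spike
#' detection metrics, false-positive rate on null directions, and the
#' regression slope of recovered on planted EPSP amplitudes.
#'
#' @param n_slices Number of pseudo-slices.
#' @param seed Root seed; per-slice seeds are derived from it.
#' @param n_trials Trials per slice.
#' @param connection_prob Planted connection probability.
#' @param amp_range Planted amplitude range (AP%).
#' @param n_pcs_range Pyramidal cells per slice (cycled).
#' @param params [analysis_params()].
#' @param progress Print per-slice progress.
#' @return List with pooled metrics, the per-slice experiments and
#'   evaluation details.
#' @export
run_recovery_study <- function(n_slices = 26, seed = 1, n_trials = 40,
                               connection_prob = 0.053,
                               amp_range = c(2, 10),
                               n_pcs_range = 9:12,
                               params = analysis_params(),
                               progress = FALSE) {
  results <- list(); evals <- list(); exps <- list()
  planted_k <- 0; planted_n <- 0
  for (s in seq_len(n_slices)) {
    cfg <- gen_config(
      n_trials = n_trials,
      field_shape = c(320, 512), # full-size field for soma placement
      n_pcs = n_pcs_range[((s - 1) %% length(n_pcs_range)) + 1],
      n_ins = 0,
      connection_prob = connection_prob,
      epsp_amp_range = amp_range,
      seed = seed * 1000L + s)
    sim <- simulate_experiment(cfg)
    res <- analyze_traces(
      sim$raw, cfg$frames_per_trial,
      positions = data.frame(cell_id = sim$gt$cells$cell_id,
                             x_um = sim$gt$cells$x_um,
                             y_um = sim$gt$cells$y_um),
      depth = stats::setNames(sim$gt$cells$depth, sim$gt$cells$cell_id),
      type_override = stats::setNames(as.list(sim$gt$cells$type),
                                      sim$gt$cells$cell_id),
      params = params,
      experiment_id = sprintf("slice%02d", s))
    ev <- evaluate_against_truth(res, sim$gt)
    results[[s]] <- res; evals[[s]] <- ev
    exps[[s]] <- res$experiment
    planted_k <- planted_k + ev$n_planted_tested
    planted_n <- planted_n + ev$n_tested
    if (progress) {
      message(sprintf("slice %02d: tested %d, planted %d, recall %.2f",
                      s, ev$n_tested, ev$n_planted_tested,
                      ev$connection_recall))
    }
  }
  rate <- connectivity_rate(exps, pre_filter = list(type = "PC"),
                            post_filter = list(type = "PC"))
  amp_all <- do.call(rbind, lapply(evals, `[[`, "amp_pairs"))
  slope <- if (!is.null(amp_all) && nrow(amp_all) >= 3) {
    unname(stats::coef(stats::lm(recovered ~ 0 + planted, amp_all)))
  } else NA_real_
  wmean <- function(field, wfield) {
    v <- vapply(evals, `[[`, numeric(1), field)
    w <- vapply(evals, `[[`, numeric(1), wfield)
    ok <- !is.na(v) & !is.na(w) & w > 0
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  fp <- do.call(rbind, lapply(evals, function(e) {
    c(fp = e$false_positive_rate * (e$n_tested - e$n_planted_tested),
      n = e$n_tested - e$n_planted_tested)
  }))
  rec <- do.call(rbind, lapply(evals, function(e) {
    c(tp = if (is.na(e$connection_recall)) 0 else
      e$connection_recall * e$n_planted_tested,
      n = e$n_planted_tested)
  }))
  sp <- vapply(evals, `[[`, numeric(1), "spike_recall")
  pp <- vapply(evals, `[[`, numeric(1), "spike_precision")
  list(recovered_rate_pct = rate$rate_pct,
       planted_rate_pct = 100 * planted_k / planted_n,
       configured_rate_pct = 100 * connection_prob,
       n_tested = rate$n, n_connected = rate$k,
       false_positive_rate = sum(fp[, "fp"]) / sum(fp[, "n"]),
       connection_recall = sum(rec[, "tp"]) / sum(rec[, "n"]),
       amplitude_slope = slope,
       spike_recall = mean(sp, na.rm = TRUE),
       spike_precision = mean(pp, na.rm = TRUE),
       amp_pairs = amp_all,
       experiments = exps, evals = evals)
}

#' Run the whole pipeline on one simulated experiment
#'
#' Convenience wrapper: simulate, analyse, summarise, optionally write
#' every intermediate (cell table, pair table, spike files, report) to a
#' directory.
#'
#' @param cfg A [gen_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param params [analysis_params()].
#' @return List with `sim`, `result`, `eval`, `report`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, params = analysis_params()) {
  sim <- simulate_experiment(cfg)
  result <- analyze_traces(
    sim$raw, cfg$frames_per_trial,
    positions = data.frame(cell_id = sim$gt$cells$cell_id,
                           x_um = sim$gt$cells$x_um,
                           y_um = sim$gt$cells$y_um),
    depth = stats::setNames(sim$gt$cells$depth, sim$gt$cells$cell_id),
    type_override = stats::setNames(as.list(sim$gt$cells$type),
                                    sim$gt$cells$cell_id),
    params = params)
  ev <- evaluate_against_truth(result, sim$gt)
  rep <- write_report(result, path = if (is.null(out_dir)) NULL else
    file.path(out_dir, "report.txt"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(result$cells, file.path(out_dir, "cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(result$pairs, file.path(out_dir, "pairs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_spike_files(result$spikes, file.path(out_dir, "spikes"))
  }
  list(sim = sim, result = result, eval = ev, report = rep)
}

#' Summarise an analysis as report tables
#'
#' Connectivity rates overall and per class, the motif census, the
#' sublayer and ADP-class connection matrices, and per-stage counts.
#'
#' @param result Output of [analyze_traces()].
#' @param path Optional file to write the formatted report to.
#' @return List of report tables (invisibly writes `path` when given).
#' @export
write_report <- function(result, path = NULL) {
  exp <- result$experiment
  overall <- connectivity_rate(exp, pre_filter = list(type = "PC"),
                               post_filter = list(type = "PC"))
  census <- motif_census(exp$connected)
  class_matrix <- function(field, classes) {
    m <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
    k <- m
    for (a in classes) for (b in classes) {
      r <- connectivity_rate(exp,
                             pre_filter = stats::setNames(list(a), field),
                             post_filter = stats::setNames(list(b), field))
      m[a, b] <- r$rate_pct; k[a, b] <- r$n
    }
    list(rate_pct = m, tested = k)
  }
  sub_m <- class_matrix("sublayer", c("superficial", "middle", "deep"))
  adp_m <- class_matrix("adp_class", c("aAP", "rAP"))
  counts <- table(result$pairs$status)
  rep <- list(overall = overall, motifs = census, sublayer = sub_m,
              adp = adp_m, pair_status_counts = counts)
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("overall PC-PC: %d/%d = %.2f%%", overall$k,
                       overall$n, overall$rate_pct), con)
    writeLines("motif census:", con)
    writeLines(utils::capture.output(print(census)), con)
    writeLines("sublayer rates (%):", con)
    writeLines(utils::capture.output(print(round(sub_m$rate_pct, 2))), con)
    writeLines("ADP-class rates (%):", con)
    writeLines(utils::capture.output(print(round(adp_m$rate_pct, 2))), con)
    writeLines("pair status:", con)
    writeLines(utils::capture.output(print(counts)), con)
  }
  rep
}
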