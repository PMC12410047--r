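test_that("configuration invariants are enforced", {
  expect_error(gen_config(frame_rate = 500), "1000")
  expect_error(gen_config(frames_per_trial = 50), "at least 100")
  expect_error(gen_config(pc_rate = -1), "non-negative")
  expect_error(gen_config(connection_prob = 1.5), "probability")
  expect_error(gen_config(epsp_amp_range = c(5, 2)), "increasing")
  expect_error(generate_network(gen_config(n_pcs = 1)), "at least 2")
})

test_that("zero connection probability yields an edgeless graph", {
  gt <- generate_network(tiny_cfg(n_pcs = 6, connection_prob = 0))
  expect_identical(nrow(gt$edges), 0L)
})

test_that("edge counts follow the binomial closed form across seeds", {
  # n_pcs = 50 at p = 0.053: mean directed edges = 50*49*0.053 = 129.85
  counts <- vapply(1:10, function(s) {
    cfg <- gen_config(n_pcs = 50, n_ins = 0, connection_prob = 0.053,
                      field_shape = c(320, 512), min_separation = 20,
                      seed = s)
    nrow(generate_network(cfg)$edges)
  }, numeric(1))
  n_dir <- 50 * 49
  mu <- n_dir * 0.053
  se <- sqrt(n_dir * 0.053 * (1 - 0.053) / 10)
  expect_gt(mean(counts), mu - 1.96 * se)
  expect_lt(mean(counts), mu + 1.96 * se)
})

test_that("block-structured rates reproduce the configured ordering", {
  rates <- matrix(c(0.25, 0.02, 0.02, 0.10), 2, 2, byrow = TRUE,
                  dimnames = list(c("aAP", "rAP"), c("aAP", "rAP")))
  hits <- matrix(0, 2, 2, dimnames = dimnames(rates))
  poss <- matrix(0, 2, 2, dimnames = dimnames(rates))
  for (s in 1:20) {
    cfg <- gen_config(n_pcs = 20, n_ins = 0, block_rates = rates,
                      field_shape = c(320, 512), min_separation = 20,
                      seed = s)
    gt <- generate_network(cfg)
    cls <- stats::setNames(gt$cells$adp_class, gt$cells$cell_id)
    for (a in c("aAP", "rAP")) for (b in c("aAP", "rAP")) {
      na <- sum(cls == a); nb <- sum(cls == b)
      poss[a, b] <- poss[a, b] + if (a == b) na * (na - 1) else na * nb
      sel <- cls[gt$edges$pre] == a & cls[gt$edges$post] == b
      hits[a, b] <- hits[a, b] + sum(sel)
    }
  }
  realized <- hits / poss
  expect_gt(realized["aAP", "aAP"], realized["aAP", "rAP"])
  expect_gt(realized["aAP", "aAP"], realized["rAP", "aAP"])
  expect_gt(realized["rAP", "rAP"], realized["rAP", "aAP"])
})

test_that("edge amplitudes and decay constants respect configured ranges", {
  cfg <- gen_config(n_pcs = 30, n_ins = 0, connection_prob = 0.2,
                    field_shape = c(320, 512), min_separation = 20,
                    seed = 3)
  gt <- generate_network(cfg)
  expect_true(all(gt$edges$amp_ap_pct >= cfg$epsp_amp_range[1]))
  expect_true(all(gt$edges$amp_ap_pct <= cfg$epsp_amp_range[2]))
  expect_true(all(gt$edges$tau_decay >= 8 & gt$edges$tau_decay <= 22))
  expect_true(all(gt$edges$pre %in% gt$cells$cell_id))
  expect_true(all(gt$edges$post %in% gt$cells$cell_id))
})

test_that("zero firing rate produces empty spike trains", {
  gt <- generate_spikes(generate_network(tiny_cfg(pc_rate = 0)))
  expect_true(all(lengths(gt$spikes) == 0))
})

test_that("baseline spike counts sit inside the Poisson 99% band", {
  # 100 trials x 2.2 s at 1.31 Hz: expected 288.2 spikes per cell
  cfg <- gen_config(n_trials = 100, n_pcs = 8, n_ins = 0,
                    connection_prob = 0, field_shape = c(320, 512),
                    seed = 4)
  gt <- generate_spikes(generate_network(cfg))
  lambda <- 1.31 * 100 * 2.2
  total <- sum(lengths(gt$spikes))
  # refractoriness trims ~lambda * rate * 5ms of draws; allow for it below
  expect_gt(total, qpois(0.005, lambda * 8) * 0.98)
  expect_lt(total, qpois(0.995, lambda * 8))
  expect_true(all(vapply(gt$spikes, function(s) all(diff(s) > 0),
                         logical(1))))
})

test_that("generated trains respect the absolute refractory period", {
  cfg <- tiny_cfg(pc_rate = 30, n_trials = 5, seed = 8)
  gt <- generate_spikes(generate_network(cfg))
  isis <- unlist(lapply(gt$spikes, diff))
  expect_true(all(isis >= cfg$refractory_ms))
})

test_that("synaptic transmission raises the post-window rate by the gain", {
  # strong edge: rate in the 4-19 ms window ~ baseline + configured gain
  cfg <- gen_config(n_trials = 60, n_pcs = 2, n_ins = 0,
                    field_shape = c(320, 512), pc_rate = 2,
                    connection_prob = 1, epsp_amp_range = c(2.6, 2.8),
                    epsp_amp_median = 2.7, epsp_amp_mean = 2.69,
                    seed = 5)
  gt <- generate_spikes(generate_network(cfg))
  e <- gt$edges[1, ]
  pr <- peri_ap_rate(gt$spikes[[e$pre]], gt$spikes[[e$post]])
  gain <- cfg$transmission_rate_gain * e$amp_ap_pct / cfg$epsp_amp_mean
  # sampling error: ~200+ triggers x 15 ms windows
  n_pre <- length(gt$spikes[[e$pre]])
  se <- sqrt((pr$baseline_hz + gain) / (n_pre * 0.015))
  expect_gt(pr$response_hz - pr$baseline_hz, gain - 3 * se)
  expect_lt(pr$response_hz - pr$baseline_hz, gain + 3 * se)
})

test_that("doublet mechanism produces bursting trains", {
  cfg <- tiny_cfg(n_pcs = 4, burst_prob = 0.5, adp_mix = c(aAP = 1, rAP = 0),
                  pc_rate = 2, n_trials = 10, seed = 9)
  gt <- generate_spikes(generate_network(cfg))
  fracs <- vapply(gt$spikes[gt$cells$cell_id[gt$cells$adp_class == "aAP"]],
                  function(s) detect_bursting(s)$fraction, numeric(1))
  expect_gt(mean(fracs), 0.10)
})

test_that("identical seed and config give bit-identical output", {
  cfg <- tiny_cfg(connection_prob = 0.3, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$gt$edges, b$gt$edges)
  expect_identical(a$gt$spikes, b$gt$spikes)
  expect_identical(a$raw, b$raw)
  m1 <- render_movie(a$gt)
  m2 <- render_movie(b$gt)
  expect_identical(m1$data, m2$data)
})

test_that("noiseless movie equals baseline times bleach exactly", {
  cfg <- tiny_cfg(pc_rate = 0, n_trials = 2, frames_per_trial = 400)
  gt <- generate_spikes(generate_network(cfg))
  mov <- render_movie(gt, noise = FALSE)
  bleach <- rep(voltcon:::bleach_curve(cfg), cfg$n_trials)
  base <- mov$data[1, , ] / bleach[1]
  expected <- outer(bleach, base)
  expect_equal(mov$data, expected, tolerance = 1e-12)
})

test_that("rendered AP trough matches ap_peak_dff in noiseless movies", {
  cfg <- tiny_cfg(n_pcs = 2, n_trials = 1, frames_per_trial = 600,
                  pc_rate = 1, bleach_coeffs = c(0, 0, 0), seed = 12)
  gt <- generate_spikes(generate_network(cfg))
  # plant exactly one spike for the first cell, none elsewhere
  gt$spikes <- lapply(gt$spikes, function(x) numeric(0))
  gt$spikes[[1]] <- 300
  mov <- render_movie(gt, noise = FALSE)
  dff <- compute_dff(mov)
  tr <- extract_trace(dff, roi(gt$rois[[1]]), correct_bleach = FALSE)
  # measure from the trace baseline: the trial-mean F0 includes the dip
  # itself, shifting the whole trace by a known small offset
  trough <- max(tr$values) - stats::median(tr$values)
  expect_equal(trough, gt$cells$ap_peak_dff[1], tolerance = 0.01)
})

test_that("movie and trace datasets round-trip through disk", {
  cfg <- tiny_cfg(n_pcs = 2, n_trials = 2, frames_per_trial = 300,
                  field_shape = c(32, 32), seed = 13)
  gt <- generate_spikes(generate_network(cfg))
  mov <- render_movie(gt)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(mov, gt, dir)
  expect_true(file.exists(file.path(dir, "trial_001.tif")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_movie_tiff(dir)
  expect_equal(dim(back$data), dim(mov$data))
  # 16-bit quantisation bound
  expect_lt(max(abs(back$data - mov$data)) / max(mov$data), 1 / 65000)
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  expect_equal(sort(names(side$spikes)), sort(gt$cells$cell_id))
})
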