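#!/usr/bin/env Rscript
# Stage 1: simulate a cohort of synthetic voltage-imaging pseudo-slices.
#
# Eight slices at the study regime: 1 kHz, 40 trials x 2,200 frames,
# 9-12 spontaneously firing pyramidal cells per slice in a full-size
# field, directed connectivity planted at 5.3 % with amplitudes 2-10 AP%.
# Raw ROI-mean traces and the ground truth are cached for the later
# stages; one slice is also written out as spike-time text files.

library(voltcon)

out <- "results"
dir.create(out, showWarnings = FALSE)
n_slices <- 8
seed <- 1

sims <- list()
for (s in seq_len(n_slices)) {
  cfg <- gen_config(n_trials = 40, field_shape = c(320, 512),
                    n_pcs = 9 + ((s - 1) %% 4), n_ins = 0,
                    connection_prob = 0.053, epsp_amp_range = c(2, 10),
                    seed = seed * 1000L + s)
  sims[[s]] <- simulate_experiment(cfg)
  message(sprintf("slice %d: %d cells, %d planted connections, %d spikes",
                  s, nrow(sims[[s]]$gt$cells), nrow(sims[[s]]$gt$edges),
                  sum(lengths(sims[[s]]$gt$spikes))))
}
saveRDS(sims, file.path(out, "simulated_slices.rds"))

write_spike_files(sims[[1]]$gt$spikes, file.path(out, "slice1_spikes"))
message("cached ", n_slices, " slices under ", out)
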