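# Shared fixtures: small configurations, ideal traces, brute-force oracles.

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_trials = 3, frames_per_trial = 1100,
                   field_shape = c(64, 64), n_pcs = 3, n_ins = 0,
                   pc_rate = 2, connection_prob = 0, min_separation = 22,
                   seed = 1)
  do.call(gen_config, utils::modifyList(defaults, args))
}

# ideal AP%-normalised average trace over -45..+50 with a biexponential
# EPSP (rise tau 3) planted at `onset`
ideal_epsp_trace <- function(amp, tau, onset = 2, window = c(-45, 50),
                             rise_tau = 3) {
  offs <- window[1]:window[2]
  g <- ifelse(offs >= onset,
              exp(-(offs - onset) / tau) - exp(-(offs - onset) / rise_tau),
              0)
  amp * g / max(g)
}

# exhaustive motif count over all distinct-node tuples (oracle for graphs
# with few nodes); independent of the package's census implementation
brute_force_census <- function(adj) {
  n <- nrow(adj)
  reciprocal <- 0; divergent <- 0; convergent <- 0
  three_chain <- 0; four_chain <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b && adj[a, b] && adj[b, a]) reciprocal <- reciprocal + 1
  }
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (a == b || a == cc || b == cc) next
    if (b < cc && adj[a, b] && adj[a, cc]) divergent <- divergent + 1
    if (a < b && adj[a, cc] && adj[b, cc]) convergent <- convergent + 1
    if (adj[a, b] && adj[b, cc]) three_chain <- three_chain + 1
  }
  if (n >= 4) {
    for (a in seq_len(n)) for (b in seq_len(n)) {
      for (cc in seq_len(n)) for (d in seq_len(n)) {
        if (length(unique(c(a, b, cc, d))) < 4) next
        if (adj[a, b] && adj[b, cc] && adj[cc, d]) {
          four_chain <- four_chain + 1
        }
      }
    }
  }
  c(reciprocal = reciprocal, divergent = divergent,
    convergent = convergent, three_chain = three_chain,
    four_chain = four_chain)
}

# full-enumeration two-sided Fisher exact p for a 2x2 table given margins
# (sum of probabilities of all tables no more probable than the observed)
enum_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0, m - n2); hi <- min(m, n1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(n1, x) + lchoose(n2, m - x) - lchoose(n1 + n2, m))
  }, numeric(1))
  p_obs <- probs[k1 - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# simulate + analyse one small trace-level slice
run_small_slice <- function(seed, n_trials = 40, n_pcs = 8,
                            connection_prob = 0.1,
                            amp_range = c(2, 10), ...) {
  cfg <- gen_config(n_trials = n_trials, field_shape = c(320, 512),
                    n_pcs = n_pcs, n_ins = 0,
                    connection_prob = connection_prob,
                    epsp_amp_range = amp_range, seed = seed, ...)
  sim <- simulate_experiment(cfg)
  res <- analyze_traces(
    sim$raw, cfg$frames_per_trial,
    positions = data.frame(cell_id = sim$gt$cells$cell_id,
                           x_um = sim$gt$cells$x_um,
                           y_um = sim$gt$cells$y_um),
    depth = stats::setNames(sim$gt$cells$depth, sim$gt$cells$cell_id),
    type_override = stats::setNames(as.list(sim$gt$cells$type),
                                    sim$gt$cells$cell_id))
  list(cfg = cfg, sim = sim, res = res,
       eval = evaluate_against_truth(res, sim$gt))
}
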