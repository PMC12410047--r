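#' A partially observed directed connectivity experiment
#'
#' One slice experiment: the set of spiking cells, the ordered-pair mask
#' of directions that survived the exclusion rules ("tested"), and the
#' mask of detected connections. Connected implies tested; the diagonal is
#' never tested.
#'
#' @param tested,connected Square logical matrices (row = presynaptic,
#'   column = postsynaptic).
#' @param cell_ids Optional ids (dimnames used otherwise).
#' @param labels Optional data frame of per-cell labels (`cell_id`,
#'   `type`, `sublayer`, `adp_class`, ...).
#' @param experiment_id Identifier.
#' @return A `voltcon_experiment` object.
#' @export
connectivity_experiment <- function(tested, connected, cell_ids = NULL,
                                    labels = NULL,
                                    experiment_id = NA_character_) {
  tested <- as.matrix(tested); connected <- as.matrix(connected)
  stopifnot(nrow(tested) == ncol(tested),
            identical(dim(tested), dim(connected)))
  diag(tested) <- FALSE; diag(connected) <- FALSE
  if (any(connected & !tested)) {
    stop("connected directions must be tested", call. = FALSE)
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(tested)
    if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_len(nrow(tested)))
  }
  dimnames(tested) <- dimnames(connected) <- list(cell_ids, cell_ids)
  structure(list(tested = tested, connected = connected,
                 cell_ids = cell_ids, labels = labels,
                 experiment_id = experiment_id),
            class = "voltcon_experiment")
}

#' @export
print.voltcon_experiment <- function(x, ...) {
  cat(sprintf("<voltcon_experiment %s> %d cells, %d/%d connected/tested\n",
              x$experiment_id, length(x$cell_ids),
              sum(x$connected), sum(x$tested)))
  invisible(x)
}

#' Connectivity rate
#'
#' `rate = 100 k / n` with `k` connected and `n` tested directions. Can be
#' called with plain counts, with one experiment, or with a list of
#' experiments (pooled); label filters select presynaptic/postsynaptic
#' subsets.
#'
#' @param x Connected count, a `voltcon_experiment`, or a list of them.
#' @param n Tested count (counts form only).
#' @param pre_filter,post_filter Optional functions `labels-row -> logical`
#'   (or a named list like `list(type = "PC")`) selecting cells.
#' @return List with `k`, `n`, `rate_pct`.
#' @export
connectivity_rate <- function(x, n = NULL, pre_filter = NULL,
                              post_filter = NULL) {
  if (is.numeric(x)) {
    stopifnot(!is.null(n), x >= 0, n >= 0, x <= n)
    return(list(k = x, n = n, rate_pct = if (n > 0) 100 * x / n else 0))
  }
  exps <- if (inherits(x, "voltcon_experiment")) list(x) else x
  k <- 0L; nn <- 0L
  for (e in exps) {
    sel_pre <- label_select(e, pre_filter)
    sel_post <- label_select(e, post_filter)
    keep <- outer(sel_pre, sel_post, "&")
    k <- k + sum(e$connected & keep)
    nn <- nn + sum(e$tested & keep)
  }
  list(k = k, n = nn, rate_pct = if (nn > 0) 100 * k / nn else 0)
}

label_select <- function(e, filter) {
  if (is.null(filter)) return(rep(TRUE, length(e$cell_ids)))
  if (is.function(filter)) {
    return(vapply(seq_along(e$cell_ids), function(i) {
      isTRUE(filter(e$labels[i, , drop = FALSE]))
    }, logical(1)))
  }
  sel <- rep(TRUE, length(e$cell_ids))
  for (nm in names(filter)) {
    sel <- sel & (e$labels[[nm]] %in% filter[[nm]])
  }
  sel & !is.na(sel)
}

#' Two-sided Fisher exact test on a 2x2 connectivity table
#'
#' Exact hypergeometric two-sided p for `k1/n1` vs `k2/n2` connected /
#' tested directions.
#'
#' @param k1,n1,k2,n2 Connected and tested counts of the two groups.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(k1, n1, k2, n2) {
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                            byrow = TRUE))$p.value
}

#' Motif census of a directed graph
#'
#' Non-induced pattern counts over distinct-node tuples:
#' reciprocal = unordered pairs connected in both directions;
#' divergent = `(A, {B, C})` with `A -> B` and `A -> C`;
#' convergent = `({A, B}, C)` with `A -> C` and `B -> C`;
#' three-chain = ordered distinct `(A, B, C)` with `A -> B -> C`;
#' four-chain = ordered distinct `(A, B, C, D)` with `A -> B -> C -> D`.
#' Chains exclude repeated nodes but extra edges do not disqualify a
#' tuple, and a reciprocal pair is not additionally counted as a chain
#' `A -> B -> A`.
#'
#' @param adj Square logical adjacency matrix (row = presynaptic).
#' @return Named integer vector
#'   `c(reciprocal, divergent, convergent, three_chain, four_chain)`.
#' @export
motif_census <- function(adj) {
  A <- as.matrix(adj) != 0
  diag(A) <- FALSE
  outd <- rowSums(A); ind <- colSums(A)
  recip_m <- A & t(A)
  reciprocal <- sum(recip_m) / 2
  divergent <- sum(choose(outd, 2))
  convergent <- sum(choose(ind, 2))
  three_chain <- sum(ind * outd) - sum(recip_m) # drop A -> B -> A
  four_chain <- 0
  edges <- which(A, arr.ind = TRUE)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      b <- edges[k, 1]; cc <- edges[k, 2]
      in_b <- ind[b] - A[cc, b]          # predecessors of b other than c
      out_c <- outd[cc] - A[cc, b]       # successors of c other than b
      overlap <- sum(A[, b] & A[cc, ])   # x -> b and c -> x (x != b, c)
      four_chain <- four_chain + in_b * out_c - overlap
    }
  }
  c(reciprocal = unname(reciprocal), divergent = unname(divergent),
    convergent = unname(convergent), three_chain = unname(three_chain),
    four_chain = unname(four_chain))
}

#' Skeleton-preserving bootstrap null for motif counts
#'
#' For every iteration and every experiment, the observed number of
#' connections is re-assigned uniformly without replacement among that
#' experiment's tested directions (the "skeleton": excluded directions can
#' never receive a connection); the motif census is summed across
#' experiments. Only experiments with at least `min_cells` pyramidal
#' cells are included.
#'
#' @param exps List of [connectivity_experiment()] objects.
#' @param n_iter Bootstrap iterations (10,000).
#' @param seed Integer seed.
#' @param min_cells Minimum cells per experiment (9).
#' @return A `voltcon_bootstrap` list with `observed`, `samples`
#'   (n_iter x 5), per-motif `median`, `iqr_lo`, `iqr_hi`, `mean`, and
#'   empirical two-sided `p`.
#' @export
bootstrap_motifs <- function(exps, n_iter = 10000, seed = 1,
                             min_cells = 9) {
  if (inherits(exps, "voltcon_experiment")) exps <- list(exps)
  keep <- vapply(exps, function(e) length(e$cell_ids) >= min_cells,
                 logical(1))
  exps <- exps[keep]
  if (!length(exps)) stop("no experiment with >= ", min_cells, " cells",
                          call. = FALSE)
  set.seed(seed)
  skel <- lapply(exps, function(e) {
    list(n = length(e$cell_ids), tested_idx = which(e$tested),
         k = sum(e$connected))
  })
  observed <- Reduce(`+`, lapply(exps, function(e) motif_census(e$connected)))
  motifs <- names(observed)
  samples <- matrix(0, n_iter, length(motifs),
                    dimnames = list(NULL, motifs))
  for (it in seq_len(n_iter)) {
    tot <- numeric(length(motifs))
    for (s in skel) {
      idx <- if (s$k > 0) sample(s$tested_idx, s$k) else integer(0)
      adj <- matrix(FALSE, s$n, s$n)
      adj[idx] <- TRUE
      tot <- tot + motif_census(adj)
    }
    samples[it, ] <- tot
  }
  qs <- apply(samples, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  p <- vapply(seq_along(motifs), function(j) {
    lo <- (sum(samples[, j] <= observed[j]) + 1) / (n_iter + 1)
    hi <- (sum(samples[, j] >= observed[j]) + 1) / (n_iter + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  structure(list(observed = observed, samples = samples,
                 median = qs[2, ], iqr_lo = qs[1, ], iqr_hi = qs[3, ],
                 mean = colMeans(samples),
                 p = stats::setNames(p, motifs), n_iter = n_iter),
            class = "voltcon_bootstrap")
}

#' @export
print.voltcon_bootstrap <- function(x, ...) {
  df <- data.frame(observed = x$observed, median = x$median,
                   iqr_lo = x$iqr_lo, iqr_hi = x$iqr_hi, p = x$p)
  print(df)
  invisible(x)
}

#' Overall chi-square test of the motif profile
#'
#' `X^2 = sum (O - E)^2 / E` over the five motif categories against the
#' bootstrap expectations, df = 4.
#'
#' @param observed,expected Length-5 numeric vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
motif_overall_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(expected > 0))
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-cell connection probabilities and power-law fit
#'
#' For every cell of every included experiment (at least `min_cells`
#' pyramidal cells), computes the input and output connection
#' probabilities (connections / tested directions in that orientation),
#' tabulates the number of cells at each distinct probability value, and
#' fits a least-squares line on the log-log occurrence plot (zero
#' probabilities dropped; the fit is flagged undefined with fewer than 3
#' distinct occupied values).
#'
#' @param exps List of [connectivity_experiment()] objects.
#' @param min_cells Inclusion threshold (9).
#' @return List with `cells` (data frame: `experiment`, `cell_id`,
#'   `p_in`, `p_out`, `tested_in`, `tested_out`) and `fit_in` / `fit_out`
#'   (each `slope`, `intercept`, `r_squared`, `defined`).
#' @export
degree_distribution <- function(exps, min_cells = 9) {
  if (inherits(exps, "voltcon_experiment")) exps <- list(exps)
  keep <- vapply(exps, function(e) length(e$cell_ids) >= min_cells,
                 logical(1))
  exps <- exps[keep]
  rows <- lapply(exps, function(e) {
    data.frame(experiment = e$experiment_id, cell_id = e$cell_ids,
               tested_in = colSums(e$tested), in_k = colSums(e$connected),
               tested_out = rowSums(e$tested), out_k = rowSums(e$connected),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  cells$p_in <- ifelse(cells$tested_in > 0, cells$in_k / cells$tested_in, NA)
  cells$p_out <- ifelse(cells$tested_out > 0, cells$out_k / cells$tested_out,
                        NA)
  list(cells = cells,
       fit_in = loglog_fit(cells$p_in),
       fit_out = loglog_fit(cells$p_out))
}

loglog_fit <- function(p) {
  p <- p[!is.na(p) & p > 0]
  occ <- table(signif(p, 6))
  x <- log10(as.numeric(names(occ)))
  y <- log10(as.numeric(occ))
  if (length(x) < 3) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, defined = FALSE))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, defined = TRUE)
}

#' Detect hub cells
#'
#' A cell is a hub when both its input and its output connection
#' probability exceed twice the overall connectivity rate. The expected
#' hub count under independence is
#' `N * P(p_in > thr) * P(p_out > thr)`.
#'
#' @param cells The `cells` data frame from [degree_distribution()].
#' @param overall_rate_pct Overall connectivity rate in percent.
#' @return List with `hubs` (subset of `cells`), `n_hubs`,
#'   `expected_hubs`, `threshold` (as a probability).
#' @export
hub_detect <- function(cells, overall_rate_pct) {
  thr <- 2 * overall_rate_pct / 100
  ok <- !is.na(cells$p_in) & !is.na(cells$p_out)
  cells <- cells[ok, , drop = FALSE]
  hi_in <- cells$p_in > thr
  hi_out <- cells$p_out > thr
  hubs <- cells[hi_in & hi_out, , drop = FALSE]
  list(hubs = hubs, n_hubs = nrow(hubs),
       expected_hubs = nrow(cells) * mean(hi_in) * mean(hi_out),
       threshold = thr)
}
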