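#!/usr/bin/env Rscript
# Stage 5: firing-property cell classes and class-resolved connectivity.
#
# ADP-based aAP/rAP assignment, bursting, sublayer trisection, and the
# sublayer and ADP-class connection matrices of the recovered graphs.

library(voltcon)

out <- "results"
results <- readRDS(file.path(out, "analysis_results.rds"))

cells <- do.call(rbind, lapply(seq_along(results), function(s) {
  cbind(slice = s, results[[s]]$res$cells)
}))
message("class counts:")
print(table(cells$adp_class))
print(table(cells$sublayer))
message(sprintf("bursting cells: %d of %d", sum(cells$bursting),
                nrow(cells)))
write.table(cells, file.path(out, "all_cells_classified.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

exps <- lapply(results, function(x) x$res$experiment)
class_matrix <- function(field, classes) {
  m <- matrix(NA_real_, length(classes), length(classes),
              dimnames = list(pre = classes, post = classes))
  n <- m
  for (a in classes) for (b in classes) {
    r <- connectivity_rate(exps,
                           pre_filter = stats::setNames(list(a), field),
                           post_filter = stats::setNames(list(b), field))
    m[a, b] <- r$rate_pct; n[a, b] <- r$n
  }
  list(rate_pct = m, tested = n)
}

sub_m <- class_matrix("sublayer", c("superficial", "middle", "deep"))
adp_m <- class_matrix("adp_class", c("aAP", "rAP"))
message("sublayer connection rates (%):")
print(round(sub_m$rate_pct, 2))
message("ADP-class connection rates (%):")
print(round(adp_m$rate_pct, 2))

write.table(round(sub_m$rate_pct, 3),
            file.path(out, "sublayer_rate_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write.table(round(adp_m$rate_pct, 3),
            file.path(out, "adp_rate_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
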