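#!/usr/bin/env Rscript
# Stage 2: voxelwise T2 fitting and distribution biomarkers.
#
# For every simulated animal: load the echo stack and muscle mask, fit the
# monoexponential decay voxelwise (nonlinear least squares), trim the T2
# sample's 1% tails, and compute the biomarkers (IDR, KDE mode, Pearson mode
# skew, D'Agostino K2). Writes results/cohort_metrics.csv and a histogram
# panel (per-animal T2 histogram with the mean/sd Gaussian overlaid, which
# visibly fails for diseased animals) for four representative severities.

library(musclet2)

rec <- read.csv("results/cohort_records.csv", stringsAsFactors = FALSE)

rows <- lapply(seq_len(nrow(rec)), function(i) {
  id <- rec$animal_id[i]
  stack <- read_stack(file.path("scratch/cohort", paste0(id, ".nii")))
  mask <- read_mask(file.path("scratch/cohort", paste0(id, "_mask.nii")))
  map <- fit_map(stack, mask, method = "nls")
  d <- suppressWarnings(summarize_t2(map))
  metrics_row(d, animal_id = id, genotype = rec$genotype[i])
})
met <- do.call(rbind, rows)
out <- merge(rec, met[, c("animal_id", "n_retained", "mean_ms", "sd_ms",
                          "mode_ms", "idr_ms", "pearson_skew",
                          "normality_stat", "normality_p")],
             by = "animal_id")
write.csv(out, "results/cohort_metrics.csv", row.names = FALSE)

np <- out$normality_p[out$sd_ms > 0]
cat(sprintf("Fitted %d animals; all %d non-degenerate T2 distributions non-normal at p < 0.001: %s\n",
            nrow(out), length(np), all(np < 0.001)))
cat(sprintf("IDR range %.2f-%.2f ms; skew range %.3f-%.3f\n",
            min(out$idr_ms), max(out$idr_ms),
            min(out$pearson_skew, na.rm = TRUE),
            max(out$pearson_skew, na.rm = TRUE)))

# Histogram panel (mildest WT, mild/severe mdxB10, mdxD2)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  b10 <- out[out$genotype == "mdxB10", ]
  picks <- c(out$animal_id[out$genotype == "WT"][1],
             b10$animal_id[which.min(b10$severity_true)],
             b10$animal_id[which.max(b10$severity_true)],
             out$animal_id[out$genotype == "mdxD2"][1])
  dfs <- do.call(rbind, lapply(picks, function(id) {
    stack <- read_stack(file.path("scratch/cohort", paste0(id, ".nii")))
    mask <- read_mask(file.path("scratch/cohort", paste0(id, "_mask.nii")))
    d <- suppressWarnings(summarize_t2(fit_map(stack, mask)))
    data.frame(animal_id = id, t2 = d$values_ms,
               mean = d$mean_ms, sd = d$sd_ms)
  }))
  dir.create("results/figures", showWarnings = FALSE)
  p <- ggplot(dfs, aes(t2)) +
    geom_histogram(aes(y = after_stat(density)), bins = 60,
                   fill = "grey70", colour = "grey40", linewidth = 0.1) +
    stat_function(data = NULL, fun = function(x) x, geom = "blank") +
    facet_wrap(~animal_id, scales = "free_y") +
    labs(x = expression(T[2] ~ "(ms)"), y = "density",
         title = "Muscle T2 distributions with mean/sd Gaussian overlay") +
    theme_minimal()
  # per-facet Gaussian overlay
  gauss <- do.call(rbind, lapply(picks, function(id) {
    r <- dfs[dfs$animal_id == id, ][1, ]
    x <- seq(min(dfs$t2), max(dfs$t2), length.out = 300)
    data.frame(animal_id = id, x = x, y = dnorm(x, r$mean, max(r$sd, 1e-6)))
  }))
  p <- p + geom_line(data = gauss, aes(x, y), colour = "red",
                     linetype = "dashed")
  ggsave("results/figures/t2_histograms.pdf", p, width = 8, height = 6)
  cat("Wrote results/figures/t2_histograms.pdf\n")
}
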