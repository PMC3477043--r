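#!/usr/bin/env Rscript
# Validation on synthetic alignments with planted substitution modes: can
# the PCA recover a two-position co-varying mode and an independent
# one-position mode, and does the quadrant partition recover the planted
# four-way membership?

suppressMessages(library(pocketpca))
dir.create("results", showWarnings = FALSE)

two_mode_spec <- function(n, noise, seed) {
  synthetic_alignment_spec(
    n, "EVDDHASFTSRRGL",
    modes = list(list(positions = c(2L, 3L), letters = c("T", "G"),
                      prob = 0.5),
                 list(positions = 10L, letters = "A", prob = 0.5)),
    noise = noise, seed = seed)
}

rows <- list()
for (noise in c(0, 0.02)) {
  for (seed in 1:5) {
    spec <- two_mode_spec(200L, noise, seed)
    g <- generate_alignment(spec)
    model <- fit_pca(onehot_encode(g$records))
    cosines <- sapply(1:2, function(m) {
      contrast <- mode_contrast(spec, m)
      max(abs(c(sum(contrast * model$vectors[, 1]),
                sum(contrast * model$vectors[, 2]))))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      n = 200L, noise = noise, seed = seed,
      cos_mode1 = round(cosines[1], 4), cos_mode2 = round(cosines[2], 4),
      n_nonzero_eigenvalues = sum(model$values > 1e-10))
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/synthetic_mode_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Mode recovery (|cosine| of planted contrast with best top-2 PC):\n")
print(tab, row.names = FALSE)
cat(sprintf("Minimum |cosine| at 2%% noise across seeds: %.4f\n",
            min(tab$cos_mode1[tab$noise > 0], tab$cos_mode2[tab$noise > 0])))

spec0 <- two_mode_spec(200L, 0, 17L)
g0 <- generate_alignment(spec0)
enc0 <- onehot_encode(g0$records)
model0 <- orient_axes(fit_pca(enc0), g0$records,
                      features = list(
                        pc1 = list(list(column = 2L, letters = "T")),
                        pc2 = list(list(column = 10L, letters = "S"))))
asg <- assign_quadrant(project(model0, enc0))
truth <- ifelse(g0$modes[, 1], ifelse(g0$modes[, 2], "B", "A"),
                ifelse(g0$modes[, 2], "D", "C"))
cat(sprintf("\nNoise-free 4-way partition accuracy vs planted truth: %.1f%% (n = 200)\n",
            100 * mean(asg$group == truth)))
cat("Wrote results/synthetic_mode_recovery.tsv\n")
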