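# Variance decomposition: broad-sense heritability per trait within each
# experiment and across the combined experiments, plus the replicate-level
# G x E ANOVA counts. Expectation from the generator: within-experiment
# medians near 0.5, combined-scope median near 0.25 (G x E and experiment
# variance leave Vg but stay in Vp).

source("analysis/00_config.R")

traits <- read_trait_table(file.path(OUT, "traits.csv"))

h2 <- heritability_table(traits)
write.csv(h2, file.path(OUT, "heritability.csv"), row.names = FALSE)

for (s in c("exp1", "exp2", "combined")) {
  cat(sprintf("median H2 (%s): %.3f\n", s, median(h2$H2[h2$scope == s])))
}

# replicate-level ANOVA: how many traits show line / experiment / G x E
# effects at p < 0.05
counts <- c(line = 0, experiment = 0, gxe = 0)
for (t in unique(traits$trait)) {
  a <- fit_gxe_anova(traits[traits$trait == t, ])
  counts["line"] <- counts["line"] + (a$p[a$term == "line"] < 0.05)
  counts["experiment"] <- counts["experiment"] +
    (a$p[a$term == "experiment"] < 0.05)
  counts["gxe"] <- counts["gxe"] +
    isTRUE(a$p[a$term == "line:experiment"] < 0.05)
}
cat(sprintf("traits with significant line / experiment / GxE effects: %d / %d / %d (of %d)\n",
            counts["line"], counts["experiment"], counts["gxe"],
            length(unique(traits$trait))))
write.csv(data.frame(term = names(counts), n_significant = counts),
          file.path(OUT, "anova_counts.csv"), row.names = FALSE)
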