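# QTL hotspots: 10 cM sliding-window counts per dataset, permutation count
# thresholds (peaks re-placed uniformly over marker positions), merging of
# significant peaks across the three datasets, validation against all
# traits with the multi-marker linear model, and the marker x experiment
# partitioning of each validated hotspot.

source("analysis/00_config.R")

gm <- read_genotype_map(file.path(OUT, "map.csv"),
                        file.path(OUT, "genotypes.csv"))
traits <- read_trait_table(file.path(OUT, "traits.csv"))
qtl <- read.csv(file.path(OUT, "qtl.csv"),
                colClasses = c(chromosome = "character"))
grid <- build_scan_grid(gm$map, STEP)

peaks <- list()
for (ds in unique(qtl$dataset)) {
  sub <- qtl[qtl$dataset == ds, ]
  thr <- hotspot_permutation_threshold(nrow(sub), grid, WINDOW,
                                       n_perm = N_PERM_HOT, alpha = ALPHA,
                                       seed = SEED + 20)
  prof <- window_counts(sub, grid, WINDOW)
  peaks[[ds]] <- find_hotspots(prof, as.numeric(thr), gm$map, ds)
  cat(sprintf("%s: count threshold %d, %d hotspot peak(s)\n", ds,
              as.integer(thr), nrow(peaks[[ds]])))
}
all_peaks <- do.call(rbind, peaks)
write.csv(all_peaks, file.path(OUT, "hotspot_peaks.csv"), row.names = FALSE)

merged <- merge_hotspots(all_peaks, gm$map, radius = WINDOW)
cat(sprintf("merged across datasets: %d unique hotspot(s) at markers %s\n",
            nrow(merged), paste(merged$marker, collapse = ", ")))

v <- validate_hotspots_marker_model(traits, merged$marker, gm$genotypes,
                                    n_perm = N_PERM_VAL, alpha = ALPHA,
                                    seed = SEED + 21)
mx <- marker_by_experiment_model(traits, merged$marker, gm$genotypes)
hs <- cbind(merged, v[match(merged$marker, v$marker), -1],
            mx[match(merged$marker, mx$marker), -1])
write.csv(hs, file.path(OUT, "hotspots.csv"), row.names = FALSE)
cat(sprintf("validated: %d of %d; main-effect dominant: %d\n",
            sum(hs$validated), nrow(hs),
            sum(hs$validated & hs$main_dominant)))

# effect-table export for the top hotspot (network-drawing input)
top <- hs$marker[which.max(hs$n_significant)]
et <- hotspot_effect_table(traits, top, gm$genotypes)
write.csv(et, file.path(OUT, paste0("effects_", top, ".csv")),
          row.names = FALSE)
cat(sprintf("hotspot %s: %d traits Lemont-up, %d Teqing-up (q < 0.05)\n",
            top, sum(et$direction == "lemont_up"),
            sum(et$direction == "teqing_up")))
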