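# Shared settings for the analysis drivers. Each numbered script can be run
# in order from the repository root: Rscript analysis/01_simulate.R, ...
# All outputs land under results/analysis/.

library(ricemqtl)

SEED <- 2026
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

N_LINES <- 280      # the LT-RIL population size
N_TRAITS <- 150     # metabolite-like traits (paper scale ~500; see vignette)
STEP <- 1           # scan grid step, cM
N_PERM <- 1000      # permutations for LOD thresholds (the study's protocol)
N_PERM_HOT <- 1000  # permutations for hotspot count thresholds
N_PERM_VAL <- 200   # permutations for validation / enrichment nulls
ALPHA <- 0.05
WINDOW <- 10        # hotspot sliding window, cM
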