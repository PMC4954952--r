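# Build the synthetic study: the 175-marker / 12-chromosome RIL map, 280
# simulated lines, and a replicated 150-trait panel with polygenic additive
# effects, experiment and G x E effects (within-experiment H2 ~ 0.5,
# combined ~ 0.25), three shared hotspot loci (two with both effect signs,
# the C/N-partitioning-like pattern), one epistatic hotspot pair, and ten
# variance-QTL traits for the CV branch.

source("analysis/00_config.R")

map <- lt_ril_template()
genotypes <- simulate_ril_genotypes(map, N_LINES, seed = SEED)

hot1 <- c(chromosome = "3", marker = "c03m09")
hot2 <- c(chromosome = "7", marker = "c07m06")
hot3 <- c(chromosome = "11", marker = "c11m05")
pos_of <- function(mk) map$position_cM[map$marker == mk]

set.seed(SEED + 1)
background <- function(v_add, n_loci = 3) {
  pick <- sample(nrow(map), n_loci)
  data.frame(chromosome = map$chromosome[pick],
             position_cM = map$position_cM[pick],
             a = sample(c(-1, 1), n_loci, TRUE) * sqrt(v_add / n_loci))
}
mk_arch <- function(hotspots = NULL, hot_a = 0, epi_pair = NULL, w = 0,
                    var_qtl = NULL) {
  qtl <- background(max(0.75 - sum(hot_a^2), 0.15))
  for (i in seq_along(hotspots)) {
    qtl <- rbind(qtl, data.frame(
      chromosome = hotspots[[i]][["chromosome"]],
      position_cM = pos_of(hotspots[[i]][["marker"]]),
      a = rep_len(hot_a, length(hotspots))[i]))
  }
  epi <- if (!is.null(epi_pair)) {
    data.frame(chromosome1 = epi_pair[[1]][["chromosome"]],
               position1 = pos_of(epi_pair[[1]][["marker"]]),
               chromosome2 = epi_pair[[2]][["chromosome"]],
               position2 = pos_of(epi_pair[[2]][["marker"]]), w = w)
  } else NULL
  pick <- sample(nrow(map), 2)
  trait_architecture(
    qtl = qtl, epistasis = epi,
    exp_effect = rnorm(1, 0, 0.5),
    gxe = data.frame(chromosome = map$chromosome[pick],
                     position_cM = map$position_cM[pick],
                     effect = sqrt(0.25 / 2)),
    sigma = 1, mu = 10 * exp(rnorm(1, 0, 0.2)), var_qtl = var_qtl)
}

arch <- c(
  lapply(1:20, function(i) mk_arch(list(hot1), +0.45)),
  lapply(1:10, function(i) mk_arch(list(hot1), -0.45)),
  lapply(1:15, function(i) mk_arch(list(hot2), +0.45)),
  lapply(1:10, function(i) mk_arch(list(hot2), -0.45)),
  lapply(1:25, function(i) mk_arch(list(hot1, hot3), c(0.4, 0.4),
                                   epi_pair = list(hot1, hot3), w = 0.35)),
  lapply(1:10, function(i) mk_arch(
    var_qtl = list(chromosome = "8", position_cM = pos_of("c08m05"), k = 2))),
  lapply(1:60, function(i) mk_arch()))
names(arch) <- sprintf("T%03d", seq_along(arch))
traits <- simulate_trait_panel(genotypes, arch, seed = SEED + 2)

write_map(map, file.path(OUT, "map.csv"))
write_genotypes(genotypes, file.path(OUT, "genotypes.csv"))
write_traits(traits, file.path(OUT, "traits.csv"))

cat(sprintf("simulated %d lines x %d markers, %d traits x 4 replicates\n",
            nrow(genotypes), ncol(genotypes), length(arch)))
cat(sprintf("mean allele-A frequency %.3f; %.1f%% missing calls\n",
            mean(unclass(genotypes) == "A"), 0))
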