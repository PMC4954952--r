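#' Template genetic map emulating the Lemont x Teqing RIL design
#'
#' A deterministic 12-chromosome map with 175 markers, uneven spacing on a
#' rice-like scale (~1500 cM total), and one deliberately wide gap on each of
#' chromosomes 3 and 9 (mirroring the sparse regions of the real RFLP map).
#' Spacings come from a golden-ratio low-discrepancy sequence, so the map is
#' reproducible without touching the RNG.
#'
#' @return A `genetic_map` with 175 markers on chromosomes "1".."12".
#' @export
lt_ril_template <- function() {
  n_mark <- c(20L, 18L, 17L, 16L, 15L, 15L, 14L, 13L, 12L, 12L, 12L, 11L)
  chr_len <- c(181, 157, 166, 129, 122, 124, 118, 121, 93, 83, 117, 109)
  phi <- (sqrt(5) - 1) / 2
  idx <- 0L
  rows <- vector("list", 12L)
  for (c in 1:12) {
    k <- n_mark[c]
    # uneven positive spacings in (0.25, 1.75) x mean, summing to chr length
    u <- ((idx + seq_len(k - 1L)) * phi) %% 1
    idx <- idx + k - 1L
    w <- 0.25 + 1.5 * u
    sp <- chr_len[c] * w / sum(w)
    if (c %in% c(3L, 9L)) {
      # widen the central interval into a map gap, shrink the rest
      g <- ceiling((k - 1L) / 2)
      gap <- 0.35 * chr_len[c]
      sp <- sp * (chr_len[c] - gap) / (sum(sp) - sp[g])
      sp[g] <- gap
    }
    pos <- round(c(0, cumsum(sp)), 2)
    rows[[c]] <- data.frame(
      marker = sprintf("c%02dm%02d", c, seq_len(k)),
      chromosome = as.character(c), position_cM = pos,
      stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  genetic_map(m$marker, m$chromosome, m$position_cM)
}

#' Simulate selfed-RIL genotypes along a genetic map
#'
#' Each line is an independent two-state Markov chain per chromosome: the
#' first marker is "A" or "B" with probability 1/2 and each subsequent marker
#' switches class with probability `ril_recfrac_cm(d)` for the inter-marker
#' distance d.
#'
#' @param map a `genetic_map`.
#' @param n_lines number of lines (>= 2).
#' @param seed integer seed; fixes the whole matrix.
#' @param missing_rate fraction of calls set missing at random (default 0).
#' @param map_function map function passed to [ril_recfrac_cm()].
#' @return A `genotype_matrix`.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed, missing_rate = 0,
                                   map_function = "haldane") {
  stopifnot(inherits(map, "genetic_map"), n_lines >= 2)
  set.seed(as.integer(seed))
  calls <- matrix(NA_character_, n_lines, nrow(map),
                  dimnames = list(sprintf("RIL%03d", seq_len(n_lines)),
                                  map$marker))
  for (chr in unique(map$chromosome)) {
    mi <- which(map$chromosome == chr)
    d <- diff(map$position_cM[mi])
    sw <- ril_recfrac_cm(d, map_function)
    x <- matrix(0L, n_lines, length(mi))
    x[, 1] <- as.integer(stats::runif(n_lines) < 0.5)
    if (length(mi) > 1L) {
      flips <- matrix(stats::runif(n_lines * length(d)), n_lines) <
        matrix(sw, n_lines, length(d), byrow = TRUE)
      for (j in seq_along(d)) {
        x[, j + 1L] <- ifelse(flips[, j], 1L - x[, j], x[, j])
      }
    }
    calls[, mi] <- ifelse(x == 1L, "A", "B")
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(calls)) < missing_rate
    calls[drop] <- NA_character_
  }
  genotype_matrix(calls, map)
}

#' Define the genetic architecture of one simulated trait
#'
#' Loci must sit at marker positions of the map used downstream. Genotypes
#' are coded x = +1 (A, Lemont) / -1 (B, Teqing), so an additive effect `a`
#' is half the A-vs-B class difference.
#'
#' @param qtl data.frame with `chromosome`, `position_cM`, `a` (additive
#'   effect per +/-1 coding); may be empty.
#' @param epistasis data.frame with `chromosome1`, `position1`, `chromosome2`,
#'   `position2`, `w` (product-coded interaction effect); may be empty.
#' @param exp_effect additive shift applied to experiment 2 observations.
#' @param gxe data.frame with `chromosome`, `position_cM`, `effect`: extra
#'   locus effect expressed only in experiment 2 (genotype-by-experiment).
#' @param sigma residual standard deviation (> 0).
#' @param mu baseline trait mean (kept well above 0 so CV is defined).
#' @param var_qtl optional list(chromosome, position_cM, k): lines carrying
#'   "B" at this locus have residual sd `sigma * k` (a variance QTL, k > 0).
#' @return A `trait_architecture` list.
#' @export
trait_architecture <- function(qtl = NULL, epistasis = NULL, exp_effect = 0,
                               gxe = NULL, sigma = 1, mu = 10, var_qtl = NULL) {
  stopifnot(sigma > 0)
  if (!is.null(var_qtl)) stopifnot(var_qtl$k > 0)
  structure(list(qtl = qtl, epistasis = epistasis, exp_effect = exp_effect,
                 gxe = gxe, sigma = sigma, mu = mu, var_qtl = var_qtl),
            class = "trait_architecture")
}

# +/-1 coding of the marker at (chromosome, position); errors if off-map
.locus_code <- function(genotypes, chromosome, position_cM) {
  map <- attr(genotypes, "map")
  hit <- which(map$chromosome == as.character(chromosome) &
                 abs(map$position_cM - position_cM) < 1e-6)
  if (length(hit) == 0L) {
    stop(sprintf("architecture locus chr %s @ %.2f cM is not a map marker",
                 chromosome, position_cM))
  }
  x <- unclass(genotypes)[, hit[1]]
  out <- ifelse(is.na(x), 0, ifelse(x == "A", 1, -1))
  out
}

#' Simulate a replicated multi-trait panel over a study design
#'
#' Generates y(line, experiment, block, trait) = mu + sum(a_i x_i) +
#' sum(w_ij x_i x_j) + e 1[exp = 2] + s sum(h_i x_i) + eps, where s = +1 in
#' experiment 1 and -1 in experiment 2 (so G x E effects cancel in the
#' combined line means but contribute within-experiment genetic variance),
#' and eps ~ N(0, sigma^2 k^(2 1[B at variance QTL])). The default design is
#' the study's: two experiments, two complete blocks each, four replicates
#' per line.
#'
#' @param genotypes a `genotype_matrix`.
#' @param architectures named list of `trait_architecture` objects (names
#'   become trait ids; unnamed lists get "T001", ...).
#' @param seed integer seed.
#' @param n_experiments,n_blocks replicate structure (defaults 2 and 2).
#' @return A `trait_table`: long data.frame `line`, `experiment`, `block`,
#'   `trait`, `value`.
#' @export
simulate_trait_panel <- function(genotypes, architectures, seed,
                                 n_experiments = 2, n_blocks = 2) {
  stopifnot(length(architectures) > 0)
  if (is.null(names(architectures)) || any(names(architectures) == "")) {
    names(architectures) <- sprintf("T%03d", seq_along(architectures))
  }
  set.seed(as.integer(seed))
  lines <- rownames(genotypes)
  n <- length(lines)
  reps <- expand.grid(block = seq_len(n_blocks),
                      experiment = seq_len(n_experiments))
  out <- vector("list", length(architectures))
  for (t in seq_along(architectures)) {
    arch <- architectures[[t]]
    base <- rep(arch$mu, n)
    if (!is.null(arch$qtl) && nrow(arch$qtl)) {
      for (q in seq_len(nrow(arch$qtl))) {
        base <- base + arch$qtl$a[q] *
          .locus_code(genotypes, arch$qtl$chromosome[q], arch$qtl$position_cM[q])
      }
    }
    if (!is.null(arch$epistasis) && nrow(arch$epistasis)) {
      for (q in seq_len(nrow(arch$epistasis))) {
        x1 <- .locus_code(genotypes, arch$epistasis$chromosome1[q],
                          arch$epistasis$position1[q])
        x2 <- .locus_code(genotypes, arch$epistasis$chromosome2[q],
                          arch$epistasis$position2[q])
        base <- base + arch$epistasis$w[q] * x1 * x2
      }
    }
    gxe_shift <- rep(0, n)
    if (!is.null(arch$gxe) && nrow(arch$gxe)) {
      for (q in seq_len(nrow(arch$gxe))) {
        gxe_shift <- gxe_shift + arch$gxe$effect[q] *
          .locus_code(genotypes, arch$gxe$chromosome[q], arch$gxe$position_cM[q])
      }
    }
    sd_line <- rep(arch$sigma, n)
    if (!is.null(arch$var_qtl)) {
      xb <- .locus_code(genotypes, arch$var_qtl$chromosome,
                        arch$var_qtl$position_cM)
      sd_line[xb == -1] <- arch$sigma * arch$var_qtl$k
    }
    blk <- vector("list", nrow(reps))
    for (r in seq_len(nrow(reps))) {
      e2 <- as.integer(reps$experiment[r] == 2L)
      s <- 1 - 2 * e2
      y <- base + e2 * arch$exp_effect + s * gxe_shift +
        stats::rnorm(n, 0, sd_line)
      blk[[r]] <- data.frame(line = lines, experiment = reps$experiment[r],
                             block = reps$block[r],
                             trait = names(architectures)[t], value = y,
                             stringsAsFactors = FALSE)
    }
    out[[t]] <- do.call(rbind, blk)
  }
  tt <- do.call(rbind, out)
  rownames(tt) <- NULL
  class(tt) <- c("trait_table", "data.frame")
  tt
}

#' Sample a panel of trait architectures
#'
#' Draws per-trait polygenic architectures the way the study's metabolome
#' behaves: a Poisson number of additive QTLs at random marker positions,
#' optional pairwise epistasis, experiment main effects and G x E drawn from
#' normal distributions, and log-normal-like positive baselines.
#'
#' @param map a `genetic_map`.
#' @param n_traits number of traits.
#' @param seed integer seed.
#' @param mean_qtl mean number of additive QTLs per trait (Poisson).
#' @param a_sd sd of additive effects.
#' @param p_epistasis probability a trait carries one epistatic pair.
#' @param w_sd sd of interaction effects.
#' @param exp_sd sd of the experiment main effect across traits.
#' @param gxe_sd sd of per-locus G x E effects (0 disables).
#' @param sigma residual sd.
#' @param mu baseline mean.
#' @return Named list of `trait_architecture`.
#' @export
sample_architectures <- function(map, n_traits, seed, mean_qtl = 2,
                                 a_sd = 0.5, p_epistasis = 0.2, w_sd = 0.4,
                                 exp_sd = 0.5, gxe_sd = 0.25, sigma = 1,
                                 mu = 10) {
  set.seed(as.integer(seed))
  arch <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    nq <- stats::rpois(1, mean_qtl)
    qtl <- NULL
    if (nq > 0) {
      pick <- sample(nrow(map), min(nq, nrow(map)))
      qtl <- data.frame(chromosome = map$chromosome[pick],
                        position_cM = map$position_cM[pick],
                        a = stats::rnorm(length(pick), 0, a_sd))
    }
    epi <- NULL
    if (stats::runif(1) < p_epistasis) {
      pick <- sample(nrow(map), 2)
      epi <- data.frame(chromosome1 = map$chromosome[pick[1]],
                        position1 = map$position_cM[pick[1]],
                        chromosome2 = map$chromosome[pick[2]],
                        position2 = map$position_cM[pick[2]],
                        w = stats::rnorm(1, 0, w_sd))
    }
    gxe <- NULL
    if (gxe_sd > 0 && !is.null(qtl) && nrow(qtl)) {
      gxe <- data.frame(chromosome = qtl$chromosome,
                        position_cM = qtl$position_cM,
                        effect = stats::rnorm(nrow(qtl), 0, gxe_sd))
    }
    arch[[t]] <- trait_architecture(
      qtl = qtl, epistasis = epi,
      exp_effect = stats::rnorm(1, 0, exp_sd), gxe = gxe,
      sigma = sigma, mu = mu * exp(stats::rnorm(1, 0, 0.2)))
  }
  names(arch) <- sprintf("T%03d", seq_len(n_traits))
  arch
}
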