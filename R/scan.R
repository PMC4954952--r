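# LOD cap: keeps noise-free fits finite while preserving ordering
.LOD_CAP <- 300

# simple-regression LOD of y on each column of P (complete y assumed)
# returns list(lod, b0, b1, rss, rss0)
.lod_columns <- function(P, y) {
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  xm <- colMeans(P)
  Sxy <- as.vector(crossprod(P, yc))            # centered y removes mean term
  Sxx <- colSums(P^2) - n * xm^2
  ok <- Sxx > 1e-12
  b1 <- ifelse(ok, Sxy / Sxx, 0)
  rss1 <- pmax(rss0 - ifelse(ok, Sxy^2 / Sxx, 0), 0)
  lod <- rep(0, ncol(P))
  if (rss0 > 0) {
    lod <- (n / 2) * log10(rss0 / pmax(rss1, rss0 * 10^(-2 * .LOD_CAP / n)))
    lod <- pmin(pmax(lod, 0), .LOD_CAP)
  }
  list(lod = lod, b0 = mean(y) - b1 * xm, b1 = b1, rss = rss1, rss0 = rss0)
}

#' Haley-Knott genome scan for one trait
#'
#' At every grid position, regresses per-line trait means on the conditional
#' probability of the "A" genotype class and converts the fit to a LOD score,
#' LOD = (n/2) log10(RSS0 / RSS1), against the intercept-only null. With
#' complete genotypes this reduces exactly to two-group marker regression at
#' marker positions.
#'
#' @param trait_means named numeric vector of per-line trait means (names =
#'   line ids; NAs dropped).
#' @param genotypes a `genotype_matrix`.
#' @param grid a `scan_grid`.
#' @param probs optional precomputed [genotype_probs()] matrix (lines x grid).
#' @return A `lod_profile`: list with `grid`, `lod`, `b0`, `b1` (fitted
#'   intercept/slope on P(A); class means are b0 + b1 and b0), `rss`, `n`.
#' @export
hk_scan <- function(trait_means, genotypes, grid, probs = NULL) {
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  keep <- !is.na(trait_means)
  y <- trait_means[keep]
  if (length(y) < 10) stop("need >= 10 lines with non-missing trait values")
  P <- probs[names(trait_means)[keep], , drop = FALSE]
  if (stats::var(y) == 0) {
    warning("zero-variance trait; returning all-zero LOD profile")
    fit <- list(lod = rep(0, nrow(grid)), b0 = rep(mean(y), nrow(grid)),
                b1 = rep(0, nrow(grid)), rss = rep(0, nrow(grid)), rss0 = 0)
  } else {
    fit <- .lod_columns(P, y)
  }
  structure(list(grid = grid, lod = fit$lod, b0 = fit$b0, b1 = fit$b1,
                 rss = fit$rss, rss0 = fit$rss0, n = length(y)),
            class = "lod_profile")
}

#' @export
print.lod_profile <- function(x, ...) {
  i <- which.max(x$lod)
  cat(sprintf("LOD profile over %d positions; peak %.2f at chr %s %.1f cM\n",
              length(x$lod), x$lod[i], x$grid$chromosome[i],
              x$grid$position_cM[i]))
  invisible(x)
}

# genome-wide max LOD for each column of a matrix of (permuted) traits
.max_lod_matrix <- function(P, Y) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  xm <- colMeans(P)
  Sxx <- colSums(P^2) - n * xm^2
  S <- crossprod(P, Yc)                       # positions x perms
  red <- S^2 / ifelse(Sxx > 1e-12, Sxx, Inf)
  rss1 <- sweep(-red, 2, rss0, "+")
  floorv <- rss0 * 10^(-2 * .LOD_CAP / n)
  rss1 <- pmax(rss1, rep(floorv, each = nrow(S)))
  lod <- (n / 2) * sweep(-log10(rss1), 2, log10(pmax(rss0, 1e-300)), "+")
  lod[, rss0 <= 0] <- 0
  apply(pmin(pmax(lod, 0), .LOD_CAP), 2, max)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes trait values across lines, rescans the genome each time, and
#' takes the ceil((1 - alpha) * n_perm)-th order statistic of the null
#' genome-wide maximum LOD (the 95th percentile at the study's alpha = 0.05,
#' 1000 repetitions).
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (must exceed 1/alpha).
#' @param alpha genome-wide type-I error rate.
#' @param seed integer seed.
#' @return Scalar LOD threshold, with the null maxima as attribute
#'   `"null_max"`.
#' @export
permutation_threshold <- function(trait_means, genotypes, grid, n_perm = 1000,
                                  alpha = 0.05, seed = 1, probs = NULL) {
  if (n_perm * alpha < 1) stop("n_perm too small for alpha (need n_perm >= 1/alpha)")
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  keep <- !is.na(trait_means)
  y <- trait_means[keep]
  P <- probs[names(trait_means)[keep], , drop = FALSE]
  set.seed(as.integer(seed))
  Y <- matrix(0, length(y), n_perm)
  for (j in seq_len(n_perm)) Y[, j] <- y[sample.int(length(y))]
  mx <- .max_lod_matrix(P, Y)
  thr <- sort(mx)[ceiling((1 - alpha) * n_perm)]
  attr(thr, "null_max") <- mx
  thr
}

#' 1.5-LOD support interval around a scan peak
#'
#' The contiguous region around the peak where the LOD stays within `drop`
#' of the peak value, extended outward by one grid position on each side
#' (the first position falling below the cutoff), clipped at chromosome
#' ends. Flanking marker names are the nearest mapped markers at or outside
#' the interval ends.
#'
#' @param profile a `lod_profile`.
#' @param chromosome chromosome of the peak; defaults to the global peak's.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return data.frame with `chromosome`, `peak_cM`, `peak_lod`, `low_cM`,
#'   `high_cM`, `low_marker`, `high_marker`.
#' @export
lod_support_interval <- function(profile, chromosome = NULL, drop = 1.5) {
  g <- profile$grid
  if (is.null(chromosome)) chromosome <- g$chromosome[which.max(profile$lod)]
  ci <- which(g$chromosome == chromosome)
  lod <- profile$lod[ci]
  pos <- g$position_cM[ci]
  ipk <- which.max(lod)
  cut <- lod[ipk] - drop
  lo <- ipk
  while (lo > 1L && lod[lo - 1L] >= cut) lo <- lo - 1L
  hi <- ipk
  while (hi < length(lod) && lod[hi + 1L] >= cut) hi <- hi + 1L
  # expand to the flanking below-cutoff grid positions
  if (lo > 1L) lo <- lo - 1L
  if (hi < length(lod)) hi <- hi + 1L
  mk <- g$marker[ci]
  low_marker <- {
    cand <- which(!is.na(mk) & seq_along(mk) <= lo)
    if (length(cand)) mk[max(cand)] else mk[which(!is.na(mk))[1]]
  }
  high_marker <- {
    cand <- which(!is.na(mk) & seq_along(mk) >= hi)
    if (length(cand)) mk[min(cand)] else mk[rev(which(!is.na(mk)))[1]]
  }
  data.frame(chromosome = chromosome, peak_cM = pos[ipk],
             peak_lod = lod[ipk], low_cM = pos[lo], high_cM = pos[hi],
             low_marker = low_marker, high_marker = high_marker,
             stringsAsFactors = FALSE)
}

#' Standardized additive effect at a locus
#'
#' (mean of A-class lines - mean of B-class lines) / grand mean: the
#' dimensionless allelic-substitution effect, positive when the Lemont (A)
#' allele raises the trait.
#'
#' @param trait_means named per-line trait means.
#' @param genotype_at_peak character vector of "A"/"B" calls (NA dropped)
#'   aligned with `trait_means`.
#' @return list(effect, se, mean_A, mean_B, grand_mean); `se` is the pooled
#'   two-sample standard error on the same standardized scale.
#' @export
standardized_additive_effect <- function(trait_means, genotype_at_peak) {
  keep <- !is.na(trait_means) & !is.na(genotype_at_peak)
  y <- trait_means[keep]; gcl <- genotype_at_peak[keep]
  if (!all(c("A", "B") %in% gcl)) stop("both genotype classes must be present")
  gm <- mean(y)
  if (abs(gm) < 1e-12 * stats::sd(y)) stop("grand mean ~ 0: standardized effect undefined")
  ya <- y[gcl == "A"]; yb <- y[gcl == "B"]
  pool <- sqrt(((length(ya) - 1) * stats::var(ya) + (length(yb) - 1) * stats::var(yb)) /
                 (length(ya) + length(yb) - 2))
  se <- pool * sqrt(1 / length(ya) + 1 / length(yb)) / abs(gm)
  list(effect = (mean(ya) - mean(yb)) / gm, se = se,
       mean_A = mean(ya), mean_B = mean(yb), grand_mean = gm)
}
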