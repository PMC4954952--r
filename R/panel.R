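#' Per-line trait means for a dataset selector
#'
#' "combined" averages all available replicates (both experiments), "exp1"
#' and "exp2" the two replicates of that experiment only. Missing replicates
#' are tolerated (mean of what is available).
#'
#' @param traits a `trait_table` (long format).
#' @param dataset one of "combined", "exp1", "exp2".
#' @return Numeric matrix lines x traits of means.
#' @export
trait_means_matrix <- function(traits, dataset = c("combined", "exp1", "exp2")) {
  dataset <- match.arg(dataset)
  tt <- traits
  if (dataset == "exp1") tt <- tt[tt$experiment == 1, ]
  if (dataset == "exp2") tt <- tt[tt$experiment == 2, ]
  lines <- unique(traits$line)
  trs <- unique(traits$trait)
  m <- matrix(NA_real_, length(lines), length(trs),
              dimnames = list(lines, trs))
  agg <- tapply(tt$value, list(tt$line, tt$trait), mean, na.rm = TRUE)
  m[rownames(agg), colnames(agg)] <- agg
  m
}

#' Scan a whole trait panel for QTLs
#'
#' For every trait: per-line means for the chosen dataset, a Haley-Knott
#' genome scan, a genome-wide permutation threshold, stepwise multi-QTL
#' selection (penalties from the permutation nulls), drop-one refinement,
#' 1.5-LOD support intervals and standardized effects at the nearest marker.
#'
#' By default one permutation threshold and one interaction penalty are
#' estimated per panel (`share_threshold = TRUE`): the genotypes are common
#' to all traits, so the null genome-wide max-LOD distribution is too.
#' Per-trait permutation thresholds (the single-trait protocol) are used
#' when `share_threshold = FALSE`.
#'
#' @param traits a `trait_table`.
#' @param dataset "combined", "exp1" or "exp2".
#' @param genotypes a `genotype_matrix`.
#' @param grid a `scan_grid`.
#' @param n_perm permutations for the LOD threshold (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed for all permutation nulls.
#' @param penalty_int interaction penalty; estimated by
#'   [interaction_penalty()] when NULL.
#' @param max_qtl cap on QTLs per trait.
#' @param share_threshold share one permutation threshold across the panel.
#' @param probs optional precomputed [genotype_probs()].
#' @param pair_search allow the two-locus forward fallback (see
#'   [fit_multiqtl_stepwise()]); off by default at panel scale, where it
#'   would run a marker-pair scan for every trait whose forward search
#'   stalls.
#' @return A data.frame of QTL results: `trait`, `dataset`, `chromosome`,
#'   `position_cM`, `lod` (drop-one), `lod_scan` (marginal scan LOD at the
#'   peak), `threshold`, `effect`, `effect_se`, `pve`, `ci_low_cM`,
#'   `ci_high_cM`, `ci_low_marker`, `ci_high_marker`.
#' @export
scan_trait_panel <- function(traits, dataset, genotypes, grid, n_perm = 1000,
                             alpha = 0.05, seed = 1, penalty_int = NULL,
                             max_qtl = 10, share_threshold = TRUE,
                             probs = NULL, pair_search = FALSE) {
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  M <- trait_means_matrix(traits, dataset)
  M <- M[intersect(rownames(M), rownames(probs)), , drop = FALSE]
  map <- attr(genotypes, "map")
  shared_thr <- NULL
  if (share_threshold) {
    ref <- which(colSums(!is.na(M)) >= 10)[1]
    if (is.na(ref)) stop("no trait has >= 10 informative lines")
    shared_thr <- as.numeric(permutation_threshold(
      M[, ref], genotypes, grid, n_perm = n_perm, alpha = alpha,
      seed = seed, probs = probs))
    if (is.null(penalty_int)) {
      penalty_int <- interaction_penalty(
        M[, ref], genotypes, grid, n_perm = max(100, ceiling(1 / alpha)),
        alpha = alpha, seed = seed + 1L, probs = probs)
    }
  }
  out <- list()
  for (t in colnames(M)) {
    y <- M[, t]
    if (sum(!is.na(y)) < 10) {
      message("skipping trait ", t, ": fewer than 10 informative lines")
      next
    }
    profile <- hk_scan(y, genotypes, grid, probs = probs)
    thr <- shared_thr
    if (is.null(thr)) {
      thr <- as.numeric(permutation_threshold(
        y, genotypes, grid, n_perm = n_perm, alpha = alpha, seed = seed,
        probs = probs))
    }
    if (max(profile$lod) < thr) next
    pint <- if (is.null(penalty_int)) thr + 2 else penalty_int
    mod <- fit_multiqtl_stepwise(y, genotypes, grid, penalty_main = thr,
                                 penalty_int = pint, max_qtl = max_qtl,
                                 probs = probs, pair_search = pair_search)
    mod <- drop_one_refine(mod, y, genotypes, grid, threshold = thr,
                           probs = probs)
    if (!nrow(mod$loci)) next
    out[[t]] <- .qtl_table_for_model(t, dataset, y, mod, profile, thr,
                                     genotypes, map, grid, probs)
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_qtl_table()
  rownames(res) <- NULL
  res
}

.empty_qtl_table <- function() {
  data.frame(trait = character(0), dataset = character(0),
             chromosome = character(0), position_cM = numeric(0),
             lod = numeric(0), lod_scan = numeric(0), threshold = numeric(0),
             effect = numeric(0), effect_se = numeric(0), pve = numeric(0),
             ci_low_cM = numeric(0), ci_high_cM = numeric(0),
             ci_low_marker = character(0), ci_high_marker = character(0),
             stringsAsFactors = FALSE)
}

# QTLResult rows for a fitted model: intervals from covariate-adjusted
# chromosome profiles, effects from the nearest genotyped marker
.qtl_table_for_model <- function(trait, dataset, y, mod, profile, thr,
                                 genotypes, map, grid, probs) {
  keep <- !is.na(y)
  yy <- y[keep]
  P <- probs[names(y)[keep], , drop = FALSE]
  n <- length(yy)
  loci <- mod$loci$grid_idx
  ints <- if (nrow(mod$interactions)) {
    lapply(seq_len(nrow(mod$interactions)), function(r)
      loci[mod$interactions[r, ]])
  } else list()
  rows <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    other_ints <- Filter(function(p) !loci[k] %in% p, ints)
    Xo <- .mqm_design(P, loci[-k], other_ints)
    qo <- qr(Xo)
    ry <- qr.resid(qo, yy)
    rss_r <- sum(ry^2)
    ci <- which(grid$chromosome == grid$chromosome[loci[k]])
    RC <- qr.resid(qo, P[, ci, drop = FALSE])
    red <- as.vector(crossprod(RC, ry))^2 / pmax(colSums(RC^2), 1e-10)
    lodp <- (n / 2) * log10(rss_r / pmax(rss_r - red, rss_r * 1e-12))
    prof_k <- structure(list(grid = grid[ci, ], lod = lodp, n = n),
                        class = "lod_profile")
    iv <- lod_support_interval(prof_k, chromosome = grid$chromosome[loci[k]])
    # full-model PVE of this QTL (and its interactions) against total SS
    full <- .mqm_fit(yy, P, loci, ints)
    pve <- 100 * (sum(ry^2) - full$rss) / full$rss0
    # effect at the nearest genotyped marker
    mi <- which(map$chromosome == grid$chromosome[loci[k]])
    nearest <- mi[which.min(abs(map$position_cM[mi] -
                                  grid$position_cM[loci[k]]))]
    calls <- unclass(genotypes)[names(y)[keep], nearest]
    eff <- tryCatch(standardized_additive_effect(yy, calls),
                    error = function(e) list(effect = NA_real_, se = NA_real_))
    rows[[k]] <- data.frame(
      trait = trait, dataset = dataset,
      chromosome = grid$chromosome[loci[k]],
      position_cM = grid$position_cM[loci[k]],
      lod = mod$loci$drop_lod[k],
      lod_scan = profile$lod[loci[k]], threshold = thr,
      effect = eff$effect, effect_se = eff$se,
      pve = max(min(pve, 100), 0),
      ci_low_cM = iv$low_cM, ci_high_cM = iv$high_cM,
      ci_low_marker = iv$low_marker, ci_high_marker = iv$high_marker,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
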