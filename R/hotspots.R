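# per-chromosome sliding-window count machinery: for sorted peak positions,
# count peaks within +/- window/2 of each grid position
.window_count_chr <- function(grid_pos, peak_pos, window) {
  if (!length(peak_pos)) return(rep(0L, length(grid_pos)))
  sp <- sort(peak_pos)
  hi <- findInterval(grid_pos + window / 2 + 1e-9, sp)
  lo <- findInterval(grid_pos - window / 2 - 1e-9, sp)
  hi - lo
}

#' Sliding-window QTL counts along the genome
#'
#' For every grid position, the number of QTL peaks (across all traits) on
#' the same chromosome within half a window either side — the profile whose
#' exceedances define QTL hotspots (default window 10 cM).
#'
#' @param qtls data.frame of QTLs with `chromosome` and `position_cM`
#'   (e.g. from [scan_trait_panel()]); may be empty.
#' @param grid a `scan_grid`.
#' @param window full window width in cM (counts within +/- window/2).
#' @return data.frame `chromosome`, `position_cM`, `marker`, `count`.
#' @export
window_counts <- function(qtls, grid, window = 10) {
  stopifnot(window > 0)
  cnt <- integer(nrow(grid))
  for (chr in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == chr)
    cnt[gi] <- .window_count_chr(grid$position_cM[gi],
                                 qtls$position_cM[qtls$chromosome == chr],
                                 window)
  }
  out <- data.frame(chromosome = grid$chromosome,
                    position_cM = grid$position_cM, marker = grid$marker,
                    count = cnt, stringsAsFactors = FALSE)
  class(out) <- c("hotspot_profile", "data.frame")
  out
}

#' Permutation threshold for hotspot window counts
#'
#' Under the null, the observed QTLs have no positional clustering: each
#' permutation re-places every QTL peak uniformly at random over the genetic
#' map (preserving the total QTL count) and records the genome-wide maximum
#' window count. The threshold is the ceil((1-alpha) n_perm)-th order
#' statistic of those maxima. By default peaks are re-placed over the map's
#' marker positions, which is where interval mapping localizes peaks — a
#' uniform-in-cM null (`placement = "grid"`) under-counts clustering in
#' marker-dense regions and over-counts it inside map gaps.
#'
#' @param n_qtl total number of QTLs being placed.
#' @param grid a `scan_grid`.
#' @param window window width in cM.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param placement re-place peaks over `"marker"` positions (default) or
#'   uniformly over all `"grid"` positions.
#' @return Integer count threshold with the null maxima as attribute
#'   `"null_max"`.
#' @export
hotspot_permutation_threshold <- function(n_qtl, grid, window = 10,
                                          n_perm = 1000, alpha = 0.05,
                                          seed = 1,
                                          placement = c("marker", "grid")) {
  if (n_qtl < 1) stop("need at least one QTL")
  placement <- match.arg(placement)
  npos <- nrow(grid)
  cells <- if (placement == "marker") which(!is.na(grid$marker)) else
    seq_len(npos)
  # global cumulative-count bounds of each position's window (per chromosome)
  LO <- integer(npos); HI <- integer(npos)
  for (chr in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == chr)
    pos <- grid$position_cM[gi]
    off <- gi[1] - 1L
    HI[gi] <- off + findInterval(pos + window / 2 + 1e-9, pos)
    LO[gi] <- off + findInterval(pos - window / 2 - 1e-9, pos)
  }
  set.seed(as.integer(seed))
  mx <- integer(n_perm)
  for (k in seq_len(n_perm)) {
    cnt <- tabulate(cells[sample.int(length(cells), n_qtl, replace = TRUE)],
                    nbins = npos)
    cum <- cumsum(cnt)
    wc <- cum[HI] - ifelse(LO > 0L, cum[pmax(LO, 1L)], 0L)
    mx[k] <- max(wc)
  }
  thr <- sort(mx)[ceiling((1 - alpha) * n_perm)]
  attr(thr, "null_max") <- mx
  thr
}

#' Extract hotspot peaks from a window-count profile
#'
#' Contiguous runs of grid positions at or above the threshold are collapsed
#' to one peak each (maximum count, ties broken toward the lower cM), tagged
#' with the nearest mapped marker.
#'
#' @param profile a `hotspot_profile` from [window_counts()].
#' @param threshold count threshold (from
#'   [hotspot_permutation_threshold()]).
#' @param map the `genetic_map` (for nearest-marker naming).
#' @param dataset label carried through to the output.
#' @return data.frame `dataset`, `chromosome`, `peak_cM`, `nearest_marker`,
#'   `count`, `threshold`.
#' @export
find_hotspots <- function(profile, threshold, map, dataset = "combined") {
  rows <- list()
  for (chr in unique(profile$chromosome)) {
    sub <- profile[profile$chromosome == chr, ]
    sig <- sub$count >= threshold
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- sub[starts[r]:ends[r], ]
      pk <- seg[which.max(seg$count), ]
      mi <- which(map$chromosome == chr)
      nearest <- map$marker[mi][which.min(abs(map$position_cM[mi] -
                                                pk$position_cM))]
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = dataset, chromosome = chr, peak_cM = pk$position_cM,
        nearest_marker = nearest, count = pk$count, threshold = threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(dataset = character(0), chromosome = character(0),
                      peak_cM = numeric(0), nearest_marker = character(0),
                      count = integer(0), threshold = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Merge hotspot peaks across datasets
#'
#' Single-linkage clustering of significant peaks on each chromosome: peaks
#' within `radius` cM are chained into one cluster, represented by the
#' marker nearest its highest-count peak.
#'
#' @param peaks data.frame of hotspot peaks (from [find_hotspots()], any
#'   number of datasets concatenated).
#' @param map the `genetic_map`.
#' @param radius linkage radius in cM (default 10, one window).
#' @return data.frame `chromosome`, `peak_cM`, `marker`, `count`,
#'   `n_peaks` (peaks merged into the cluster).
#' @export
merge_hotspots <- function(peaks, map, radius = 10) {
  stopifnot(radius > 0)
  rows <- list()
  for (chr in unique(peaks$chromosome)) {
    sub <- peaks[peaks$chromosome == chr, ]
    sub <- sub[order(sub$peak_cM), ]
    cl <- cumsum(c(1, diff(sub$peak_cM) > radius))
    for (g in unique(cl)) {
      seg <- sub[cl == g, ]
      pk <- seg[which.max(seg$count), ]
      mi <- which(map$chromosome == chr)
      nearest <- map$marker[mi][which.min(abs(map$position_cM[mi] -
                                                pk$peak_cM))]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, peak_cM = pk$peak_cM, marker = nearest,
        count = pk$count, n_peaks = nrow(seg), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$chromosome, unique(map$chromosome)), out$peak_cM), ,
      drop = FALSE]
}

# design for the hotspot-marker models on line x experiment means
.hotspot_design <- function(traits, hotspot_markers, genotypes,
                            interaction = FALSE) {
  Y <- .line_exp_means(traits)
  lines <- sub("\r.*$", "", rownames(Y))
  expv <- sub("^.*\r", "", rownames(Y))
  keep <- lines %in% rownames(genotypes)
  Y <- Y[keep, , drop = FALSE]
  lines <- lines[keep]; expv <- expv[keep]
  Mx <- .marker_codes(genotypes, hotspot_markers)[lines, , drop = FALSE]
  e <- ifelse(expv == sort(unique(expv))[1], 1, -1)
  X <- cbind(`(Intercept)` = 1, Mx, experiment = e)
  if (interaction) {
    XI <- Mx * e
    colnames(XI) <- paste0(hotspot_markers, ":experiment")
    X <- cbind(X, XI)
  }
  list(X = X, Y = Y, lines = lines, e = e, markers = hotspot_markers)
}

# per-marker counts of traits whose term is BH-significant within its model
.count_significant <- function(p, term_rows, fdr = 0.05) {
  q <- apply(p, 2, function(pc) stats::p.adjust(pc, method = "BH"))
  if (is.null(dim(q))) q <- matrix(q, nrow = nrow(p), dimnames = dimnames(p))
  rowSums(q[term_rows, , drop = FALSE] < fdr, na.rm = TRUE)
}

#' Validate hotspots with a multi-marker linear model and permutation null
#'
#' Fits trait ~ sum(hotspot markers) + experiment to every trait's line x
#' experiment means, counts per marker how many traits are FDR-significant
#' (BH within each trait's model, q < `fdr`), and compares each marker's
#' count against a null built by permuting the line labels of the genotype
#' rows. A hotspot is validated when its observed count exceeds the
#' (1-alpha) null quantile.
#'
#' @param traits a `trait_table`.
#' @param hotspot_markers character vector of marker names (hotspot peaks).
#' @param genotypes a `genotype_matrix`.
#' @param n_perm permutations for the null (default 200).
#' @param alpha significance level for validation.
#' @param fdr within-model BH threshold (default 0.05).
#' @param seed integer seed.
#' @return data.frame `marker`, `n_significant`, `null_threshold`,
#'   `validated`.
#' @export
validate_hotspots_marker_model <- function(traits, hotspot_markers, genotypes,
                                           n_perm = 200, alpha = 0.05,
                                           fdr = 0.05, seed = 1) {
  d <- .hotspot_design(traits, hotspot_markers, genotypes)
  count_for <- function(X) {
    f <- .mtlm(X, d$Y, warn_alias = FALSE)
    tr <- match(hotspot_markers, f$terms)
    nc <- rep(NA_integer_, length(hotspot_markers))
    nc[!is.na(tr)] <- .count_significant(f$p, tr[!is.na(tr)], fdr)
    nc
  }
  obs <- count_for(d$X)
  set.seed(as.integer(seed))
  ulines <- unique(d$lines)
  codes <- .marker_codes(genotypes, hotspot_markers)
  null_counts <- matrix(NA_integer_, length(hotspot_markers), n_perm)
  for (k in seq_len(n_perm)) {
    perm <- stats::setNames(sample(ulines), ulines)
    # permuted line-to-genotype assignment, same within both experiments
    Xp <- d$X
    Xp[, hotspot_markers] <- codes[perm[d$lines], , drop = FALSE]
    null_counts[, k] <- count_for(Xp)
  }
  thr <- apply(null_counts, 1, function(v)
    sort(v)[ceiling((1 - alpha) * sum(!is.na(v)))])
  data.frame(marker = hotspot_markers, n_significant = obs,
             null_threshold = thr, validated = obs > thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker main-effect vs marker x experiment partitioning
#'
#' Extends the hotspot-marker model with marker x experiment interactions:
#' trait ~ sum(markers) + experiment + sum(marker x experiment). Per marker,
#' counts the traits FDR-significant for the main term and for the
#' interaction term (BH within each trait's model), the partitioning used to
#' ask whether a hotspot acts across experiments or conditionally on one.
#'
#' @inheritParams validate_hotspots_marker_model
#' @return data.frame `marker`, `n_main`, `n_gxe`, `main_dominant`.
#' @export
marker_by_experiment_model <- function(traits, hotspot_markers, genotypes,
                                       fdr = 0.05) {
  d <- .hotspot_design(traits, hotspot_markers, genotypes, interaction = TRUE)
  if (length(unique(d$e)) < 2) stop("need two experiments")
  fit <- .mtlm(d$X, d$Y)
  main_rows <- match(hotspot_markers, fit$terms)
  int_rows <- match(paste0(hotspot_markers, ":experiment"), fit$terms)
  n_main <- .count_significant(fit$p, main_rows, fdr)
  n_gxe <- .count_significant(fit$p, int_rows, fdr)
  data.frame(marker = hotspot_markers, n_main = as.integer(n_main),
             n_gxe = as.integer(n_gxe), main_dominant = n_main > n_gxe,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-trait standardized allelic effects at a hotspot marker
#'
#' The export behind network views of a hotspot: for every trait, the
#' standardized additive effect at the marker ((mean_A - mean_B) / grand
#' mean, positive when the Lemont allele raises the trait — equivalently the
#' Teqing allele lowers it), its BH q-value across traits, and the direction
#' label.
#'
#' @param traits a `trait_table`.
#' @param hotspot_marker one marker name.
#' @param genotypes a `genotype_matrix`.
#' @param fdr BH threshold for the `significant` flag.
#' @return data.frame `trait`, `marker`, `effect`, `qvalue`, `direction`
#'   ("lemont_up", "teqing_up" or "ns"), `significant`.
#' @export
hotspot_effect_table <- function(traits, hotspot_marker, genotypes,
                                 fdr = 0.05) {
  M <- trait_means_matrix(traits, "combined")
  M <- M[intersect(rownames(M), rownames(genotypes)), , drop = FALSE]
  calls <- unclass(genotypes)[rownames(M),
                              match(hotspot_marker,
                                    attr(genotypes, "map")$marker)]
  eff <- vapply(colnames(M), function(t) {
    out <- tryCatch(standardized_additive_effect(M[, t], calls),
                    error = function(e) list(effect = NA_real_, se = NA_real_))
    c(out$effect, out$se)
  }, numeric(2))
  tstat <- eff[1, ] / eff[2, ]
  ncl <- sum(!is.na(calls))
  p <- 2 * stats::pt(abs(tstat), ncl - 2, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(q) & q < fdr
  data.frame(trait = colnames(M), marker = hotspot_marker,
             effect = eff[1, ], qvalue = q,
             direction = ifelse(!sig, "ns",
                                ifelse(eff[1, ] > 0, "lemont_up", "teqing_up")),
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}
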