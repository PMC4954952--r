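# joint design for the hotspot epistasis model on line x experiment means:
# intercept + all marker mains + all pairwise products + experiment +
# (optionally) pair x experiment three-way terms; +/-1 sum-to-zero coding
.epistasis_design <- function(traits, markers, genotypes, three_way = TRUE) {
  d <- .hotspot_design(traits, markers, genotypes)
  m <- length(markers)
  if (m < 2) stop("need >= 2 hotspot markers")
  Mx <- d$X[, markers, drop = FALSE]
  pi_ <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  pj_ <- unlist(lapply(2:m, function(i) i:m))
  PR <- Mx[, pi_, drop = FALSE] * Mx[, pj_, drop = FALSE]
  pair_names <- paste0(markers[pi_], ":", markers[pj_])
  colnames(PR) <- pair_names
  X <- cbind(d$X[, c("(Intercept)", markers), drop = FALSE], PR,
             experiment = d$e)
  term_type <- c("intercept", rep("main", m), rep("pair", length(pair_names)),
                 "experiment")
  if (three_way) {
    TW <- PR * d$e
    colnames(TW) <- paste0(pair_names, ":experiment")
    X <- cbind(X, TW)
    term_type <- c(term_type, rep("pair_exp", length(pair_names)))
  }
  list(X = X, Y = d$Y, term_type = term_type, pairs = cbind(pi_, pj_),
       pair_names = pair_names, markers = markers)
}

#' Pairwise epistasis ANOVA for one trait at the hotspot markers
#'
#' Fits the full joint model trait ~ sum(M_m) + sum(M_m x M_n) + experiment
#' (+ sum(M_m x M_n x experiment)) on the line x experiment means with
#' sum-to-zero +/-1 coding, and returns per-term Type III sums of squares,
#' F, p and within-model BH q-values. Every term is a single-df contrast, so
#' the Type III SS is the squared t statistic times the residual variance.
#' Missing genotype calls are imputed from conditional genotype
#' probabilities so the joint design stays complete; aliased (perfectly
#' correlated) terms are dropped with a warning.
#'
#' @param trait data.frame with `line`, `experiment`, `block`, `value` for
#'   one trait (a `trait_table` slice).
#' @param hotspot_markers character vector (>= 2) of marker names.
#' @param genotypes a `genotype_matrix`.
#' @param three_way include pair x experiment three-way terms (default TRUE).
#' @return An `anova_record` data.frame: `term`, `type`, `ss`, `df`, `F`,
#'   `p`, `q`, with a residual row at the bottom.
#' @export
pairwise_epistasis_anova <- function(trait, hotspot_markers, genotypes,
                                     three_way = TRUE) {
  trait$trait <- "y"
  des <- .epistasis_design(trait, hotspot_markers, genotypes, three_way)
  fit <- .mtlm(des$X, des$Y[, 1, drop = FALSE])
  keep <- fit$terms != "(Intercept)"
  terms <- fit$terms[keep]
  type <- des$term_type[match(terms, colnames(des$X))]
  p <- fit$p[keep, 1]
  rec <- data.frame(term = terms, type = type, ss = fit$ss[keep, 1], df = 1L,
                    F = fit$t[keep, 1]^2, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rec <- rbind(rec, data.frame(term = "Residuals", type = "residual",
                               ss = fit$rss[1], df = fit$df_res,
                               F = NA_real_, p = NA_real_, q = NA_real_,
                               stringsAsFactors = FALSE))
  rownames(rec) <- NULL
  class(rec) <- c("anova_record", "data.frame")
  rec
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with monotonicity enforcement (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in [0, 1]; may be empty.
#' @return q-values, same length.
#' @export
fdr_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# per-pair counts of FDR-significant pair (and three-way) terms over a panel
.pair_counts <- function(traits, markers, genotypes, fdr = 0.05,
                         three_way = TRUE, design = NULL) {
  des <- if (is.null(design)) {
    .epistasis_design(traits, markers, genotypes, three_way)
  } else design
  fit <- .mtlm(des$X, des$Y, warn_alias = FALSE)
  keep <- fit$terms != "(Intercept)"
  q <- apply(fit$p[keep, , drop = FALSE], 2,
             function(pc) stats::p.adjust(pc, method = "BH"))
  if (is.null(dim(q))) q <- matrix(q, ncol = ncol(des$Y))
  rownames(q) <- fit$terms[keep]
  cnt <- function(rows) {
    out <- rep(NA_integer_, length(des$pair_names))
    hit <- match(rows, rownames(q))
    out[!is.na(hit)] <- rowSums(q[hit[!is.na(hit)], , drop = FALSE] < fdr,
                                na.rm = TRUE)
    out
  }
  n_pair <- cnt(des$pair_names)
  n_gxe <- if (three_way) cnt(paste0(des$pair_names, ":experiment")) else
    rep(NA_integer_, length(des$pair_names))
  list(n_pair = n_pair, n_gxe = n_gxe, des = des, fit = fit)
}

#' Permutation enrichment of epistatic interaction counts
#'
#' For every hotspot-marker pair, counts the traits whose pairwise
#' interaction term is FDR-significant in the joint epistasis model, then
#' builds a per-pair null by permuting the line labels of the genotype rows
#' against the (intact) trait matrix — preserving trait-trait correlation —
#' and retains the pairs whose observed count exceeds the (1-alpha) null
#' quantile. The pair x experiment three-way counts get the same treatment
#' and define the experiment-dependence flag.
#'
#' @param traits a `trait_table`.
#' @param hotspot_markers character vector (>= 2) of marker names.
#' @param genotypes a `genotype_matrix`.
#' @param n_perm permutations (default 200).
#' @param alpha enrichment significance level.
#' @param fdr within-model BH threshold.
#' @param seed integer seed.
#' @param three_way include and test three-way terms.
#' @return data.frame of epistasis edges: `marker1`, `marker2`,
#'   `n_significant_traits`, `null_threshold`, `enrichment_p`, `retained`,
#'   `n_gxe_traits`, `experiment_dependent`.
#' @export
epistasis_enrichment <- function(traits, hotspot_markers, genotypes,
                                 n_perm = 200, alpha = 0.05, fdr = 0.05,
                                 seed = 1, three_way = TRUE) {
  obs <- .pair_counts(traits, hotspot_markers, genotypes, fdr, three_way)
  des <- obs$des
  lines <- sub("\r.*$", "", rownames(des$Y))
  ulines <- unique(lines)
  codes <- .marker_codes(genotypes, hotspot_markers)
  m <- length(hotspot_markers)
  set.seed(as.integer(seed))
  np <- length(des$pair_names)
  null_pair <- matrix(NA_integer_, np, n_perm)
  null_gxe <- matrix(NA_integer_, np, n_perm)
  for (k in seq_len(n_perm)) {
    perm <- stats::setNames(sample(ulines), ulines)
    Mx <- codes[perm[lines], , drop = FALSE]
    PR <- Mx[, des$pairs[, 1], drop = FALSE] * Mx[, des$pairs[, 2], drop = FALSE]
    Xp <- des$X
    Xp[, hotspot_markers] <- Mx
    Xp[, des$pair_names] <- PR
    if (three_way) {
      Xp[, paste0(des$pair_names, ":experiment")] <- PR * Xp[, "experiment"]
    }
    pk <- .pair_counts(traits, hotspot_markers, genotypes, fdr, three_way,
                       design = list(X = Xp, Y = des$Y,
                                     term_type = des$term_type,
                                     pairs = des$pairs,
                                     pair_names = des$pair_names,
                                     markers = hotspot_markers))
    null_pair[, k] <- pk$n_pair
    null_gxe[, k] <- pk$n_gxe
  }
  qthr <- function(M) apply(M, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    sort(v)[ceiling((1 - alpha) * length(v))]
  })
  thr <- qthr(null_pair)
  enr_p <- vapply(seq_len(np), function(i) {
    v <- null_pair[i, !is.na(null_pair[i, ])]
    (1 + sum(v >= obs$n_pair[i])) / (1 + length(v))
  }, numeric(1))
  thr3 <- if (three_way) qthr(null_gxe) else rep(NA_integer_, np)
  data.frame(marker1 = hotspot_markers[des$pairs[, 1]],
             marker2 = hotspot_markers[des$pairs[, 2]],
             n_significant_traits = obs$n_pair,
             null_threshold = thr, enrichment_p = enr_p,
             retained = obs$n_pair > thr,
             n_gxe_traits = obs$n_gxe,
             experiment_dependent = if (three_way) obs$n_gxe > thr3 else NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of model variance explained by epistatic interactions
#'
#' 100 x (sum of pairwise-interaction Type III SS) / (sum of all model-term
#' Type III SS, residual excluded) for one fitted `anova_record`.
#'
#' @param anova an `anova_record` from [pairwise_epistasis_anova()].
#' @return Percentage in [0, 100].
#' @export
epistatic_variance_fraction <- function(anova) {
  model <- anova$type != "residual"
  tot <- sum(anova$ss[model], na.rm = TRUE)
  if (tot <= 0) {
    warning("zero model SS; epistatic fraction set to 0")
    return(0)
  }
  100 * sum(anova$ss[model & anova$type == "pair"], na.rm = TRUE) / tot
}

#' Compare epistatic variance fractions between two trait groups
#'
#' Welch two-sample t-test on per-trait epistatic variance fractions (the
#' growth-vs-metabolite style comparison), reporting group means with
#' standard errors.
#'
#' @param groupA,groupB numeric vectors of variance fractions (percent),
#'   each of length >= 2.
#' @return list `mean_A`, `se_A`, `mean_B`, `se_B`, `t`, `df`, `p`.
#' @export
compare_variance_fractions <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2) stop("groups need >= 2 values")
  tt <- stats::t.test(groupA, groupB)
  list(mean_A = mean(groupA), se_A = stats::sd(groupA) / sqrt(length(groupA)),
       mean_B = mean(groupB), se_B = stats::sd(groupB) / sqrt(length(groupB)),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Export an epistasis network as SIF plus edge attributes
#'
#' Writes the retained edges as a simple-interaction-format file
#' ("marker1 epistasis marker2") and a tab-separated edge-attribute table
#' (trait counts, enrichment p, experiment dependence — the solid/dashed
#' distinction of network viewers) for import into graph tools.
#'
#' @param edges data.frame from [epistasis_enrichment()] (typically filtered
#'   to `retained`).
#' @param sif_path output SIF path.
#' @param attr_path output TSV path (default: SIF path with .tsv).
#' @return Invisibly, the SIF path.
#' @export
export_network <- function(edges, sif_path,
                           attr_path = sub("\\.sif$", ".edges.tsv", sif_path)) {
  lines <- if (nrow(edges)) {
    paste(edges$marker1, "epistasis", edges$marker2)
  } else character(0)
  writeLines(lines, sif_path)
  utils::write.table(
    data.frame(marker1 = edges$marker1, marker2 = edges$marker2,
               n_traits = edges$n_significant_traits,
               enrichment_p = edges$enrichment_p,
               experiment_dependent = edges$experiment_dependent,
               line_style = ifelse(edges$experiment_dependent %in% TRUE,
                                   "dashed", "solid")),
    attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sif_path)
}

#' Read a SIF network file back
#'
#' @param sif_path path written by [export_network()].
#' @return data.frame `marker1`, `interaction`, `marker2` (0 rows for an
#'   empty network).
#' @export
read_network <- function(sif_path) {
  ln <- readLines(sif_path)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) {
    return(data.frame(marker1 = character(0), interaction = character(0),
                      marker2 = character(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(ln, "[ \t]+"))
  data.frame(marker1 = parts[, 1], interaction = parts[, 2],
             marker2 = parts[, 3], stringsAsFactors = FALSE)
}
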