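# design matrix for a multi-QTL model: intercept + P(A) columns + products
.mqm_design <- function(probs, loci_idx, int_pairs) {
  X <- cbind(`(Intercept)` = rep(1, nrow(probs)))
  if (length(loci_idx)) X <- cbind(X, probs[, loci_idx, drop = FALSE])
  if (length(int_pairs)) {
    for (p in int_pairs) X <- cbind(X, probs[, p[1]] * probs[, p[2]])
  }
  X
}

.mqm_fit <- function(y, probs, loci_idx, int_pairs) {
  X <- .mqm_design(probs, loci_idx, int_pairs)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  n <- length(y)
  lod <- if (rss0 > 0) {
    min((n / 2) * log10(rss0 / max(rss, rss0 * 10^(-2 * .LOD_CAP / n))), .LOD_CAP)
  } else 0
  list(rss = rss, rss0 = rss0, lod = lod, qr = fit$qr, n = n)
}

# RSS reduction from adding each column of C to the model whose QR is qrX
.add_gain <- function(qrX, ry, C) {
  RC <- qr.resid(qrX, C)
  num <- as.vector(crossprod(RC, ry))^2
  den <- colSums(RC^2)
  ifelse(den > 1e-10, num / den, 0)
}

# vectorized projection gain onto span of three residualized columns with
# Gram [[a,d,e],[d,b,f],[e,f,c]] and inner products u = (u1,u2,u3) with y
.red3 <- function(a, b, c, d, e, f, u1, u2, u3) {
  det3 <- a * (b * c - f^2) - d * (d * c - e * f) + e * (d * f - e * b)
  A11 <- b * c - f^2; A22 <- a * c - e^2; A33 <- a * b - d^2
  A12 <- e * f - d * c; A13 <- d * f - e * b; A23 <- d * e - a * f
  r3 <- (u1^2 * A11 + u2^2 * A22 + u3^2 * A33 +
           2 * (u1 * u2 * A12 + u1 * u3 * A13 + u2 * u3 * A23)) / det3
  det2 <- a * b - d^2
  r2 <- (u1^2 * b + u2^2 * a - 2 * u1 * u2 * d) / det2
  r1 <- pmax(ifelse(a > 1e-10, u1^2 / a, 0), ifelse(b > 1e-10, u2^2 / b, 0))
  r2 <- ifelse(is.finite(r2) & det2 > 1e-8 * pmax(a * b, 1e-300), r2, r1)
  ifelse(is.finite(r3) & det3 > 1e-10 * pmax(a * b * c, 1e-300), pmax(r3, r2), r2)
}

# additive-only gain of a pair (first two columns of the same Gram)
.red2 <- function(a, b, d, u1, u2) {
  det2 <- a * b - d^2
  r2 <- (u1^2 * b + u2^2 * a - 2 * u1 * u2 * d) / det2
  r1 <- pmax(ifelse(a > 1e-10, u1^2 / a, 0), ifelse(b > 1e-10, u2^2 / b, 0))
  ifelse(is.finite(r2) & det2 > 1e-8 * pmax(a * b, 1e-300), r2, r1)
}

# all i<j marker-pair indices for a grid (marker positions only)
.marker_grid_idx <- function(grid) which(!is.na(grid$marker))

#' Penalty for interaction terms from a pairwise permutation null
#'
#' Permutes the trait across lines and, for each permutation, scans all
#' marker pairs for the largest interaction LOD (full two-locus model vs the
#' additive two-locus model). The penalty is the ceil((1-alpha) n_perm)-th
#' order statistic of those maxima, playing the same role for interaction
#' terms that the genome-wide permutation threshold plays for main effects.
#'
#' @inheritParams permutation_threshold
#' @return Scalar interaction penalty (LOD units).
#' @export
interaction_penalty <- function(trait_means, genotypes, grid, n_perm = 100,
                                alpha = 0.05, seed = 1, probs = NULL) {
  if (n_perm * alpha < 1) stop("n_perm too small for alpha")
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  keep <- !is.na(trait_means)
  y <- trait_means[keep]
  n <- length(y)
  M <- probs[names(trait_means)[keep], .marker_grid_idx(grid), drop = FALSE]
  m <- ncol(M)
  Mc <- sweep(M, 2, colMeans(M))
  pairs_i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  pairs_j <- unlist(lapply(2:m, function(i) i:m))
  PR <- M[, pairs_i, drop = FALSE] * M[, pairs_j, drop = FALSE]
  PRc <- sweep(PR, 2, colMeans(PR))
  gmm <- crossprod(Mc)
  a <- diag(gmm)[pairs_i]; b <- diag(gmm)[pairs_j]; d <- gmm[cbind(pairs_i, pairs_j)]
  cc <- colSums(PRc^2)
  e <- colSums(PRc * Mc[, pairs_i])
  f <- colSums(PRc * Mc[, pairs_j])
  set.seed(as.integer(seed))
  Y <- matrix(0, n, n_perm)
  for (k in seq_len(n_perm)) Y[, k] <- y[sample.int(n)]
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  Um <- crossprod(Mc, Yc)          # m x n_perm
  Up <- crossprod(PRc, Yc)         # npairs x n_perm
  mx <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    u1 <- Um[pairs_i, k]; u2 <- Um[pairs_j, k]; u3 <- Up[, k]
    radd <- .red2(a, b, d, u1, u2)
    rfull <- .red3(a, b, cc, d, e, f, u1, u2, u3)
    rss_add <- pmax(rss0[k] - radd, rss0[k] * 1e-12)
    rss_full <- pmax(rss0[k] - rfull, rss0[k] * 1e-12)
    mx[k] <- max((n / 2) * log10(rss_add / rss_full))
  }
  sort(mx)[ceiling((1 - alpha) * n_perm)]
}

# scan all marker pairs for the best (pair + interaction) joint addition to
# the current model; returns list(i, j, lod_gain) with i, j grid indices
.pair_scan <- function(y, probs, grid, qrX, rss_cur, n) {
  ry <- qr.resid(qrX, y)
  midx <- .marker_grid_idx(grid)
  M <- probs[, midx, drop = FALSE]
  m <- ncol(M)
  if (m < 2L) return(NULL)
  RM <- qr.resid(qrX, M)
  pairs_i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  pairs_j <- unlist(lapply(2:m, function(i) i:m))
  RP <- qr.resid(qrX, M[, pairs_i, drop = FALSE] * M[, pairs_j, drop = FALSE])
  gmm <- crossprod(RM)
  a <- diag(gmm)[pairs_i]; b <- diag(gmm)[pairs_j]; d <- gmm[cbind(pairs_i, pairs_j)]
  cc <- colSums(RP^2)
  e <- colSums(RP * RM[, pairs_i])
  f <- colSums(RP * RM[, pairs_j])
  u1 <- as.vector(crossprod(RM, ry))[pairs_i]
  u2 <- as.vector(crossprod(RM, ry))[pairs_j]
  u3 <- as.vector(crossprod(RP, ry))
  red <- .red3(a, b, cc, d, e, f, u1, u2, u3)
  rss_new <- pmax(rss_cur - red, rss_cur * 1e-12)
  gain <- (n / 2) * log10(rss_cur / rss_new)
  best <- which.max(gain)
  list(i = midx[pairs_i[best]], j = midx[pairs_j[best]], lod_gain = gain[best])
}

.plod <- function(lod, n_loci, n_int, pm, pi) lod - pm * n_loci - pi * n_int

#' Stepwise multi-QTL model selection
#'
#' Forward selection over the scan grid followed by backward elimination,
#' scored by the penalized LOD: model LOD minus `penalty_main` per QTL and
#' `penalty_int` per interaction (penalties from the genome-wide and pairwise
#' permutation nulls). Forward moves are (i) add the best single locus,
#' (ii) add the best interaction between selected loci, or, when neither
#' passes its penalty, (iii) a two-locus marker scan proposing a locus pair
#' plus its interaction (charged two main penalties plus one interaction
#' penalty) so purely epistatic architectures can enter.
#'
#' @inheritParams hk_scan
#' @param penalty_main penalty per additive QTL (typically the permutation
#'   LOD threshold).
#' @param penalty_int penalty per interaction term, see
#'   [interaction_penalty()].
#' @param max_qtl maximum number of QTLs (default 10).
#' @param pair_search whether the two-locus fallback scan is allowed.
#' @return A `multiqtl_model`: list with `loci` (data.frame chromosome,
#'   position_cM, grid_idx), `interactions` (two-column matrix of rows of
#'   `loci`), `lod`, `plod`, `n`.
#' @export
fit_multiqtl_stepwise <- function(trait_means, genotypes, grid, penalty_main,
                                  penalty_int = penalty_main + 2,
                                  max_qtl = 10, probs = NULL,
                                  pair_search = TRUE) {
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  keep <- !is.na(trait_means)
  y <- trait_means[keep]
  P <- probs[names(trait_means)[keep], , drop = FALSE]
  n <- length(y)
  loci <- integer(0)
  ints <- list()
  pair_used <- FALSE
  repeat {
    if (length(loci) >= max_qtl) break
    fit <- .mqm_fit(y, P, loci, ints)
    ry <- qr.resid(fit$qr, y)
    gains <- .add_gain(fit$qr, ry, P)
    rss_new <- pmax(fit$rss - gains, fit$rss * 1e-12)
    lod_gain <- (n / 2) * log10(fit$rss / rss_new)
    best_main <- which.max(lod_gain)
    main_score <- lod_gain[best_main] - penalty_main
    int_score <- -Inf; best_int <- NULL
    if (length(loci) >= 2L) {
      cand <- utils::combn(seq_along(loci), 2, simplify = FALSE)
      cand <- Filter(function(p) !any(vapply(ints, function(q)
        setequal(q, loci[p]), logical(1))), cand)
      if (length(cand)) {
        C <- vapply(cand, function(p) P[, loci[p[1]]] * P[, loci[p[2]]],
                    numeric(n))
        g2 <- .add_gain(fit$qr, ry, C)
        lg2 <- (n / 2) * log10(fit$rss / pmax(fit$rss - g2, fit$rss * 1e-12))
        bi <- which.max(lg2)
        int_score <- lg2[bi] - penalty_int
        best_int <- loci[cand[[bi]]]
      }
    }
    if (main_score > 0 && main_score >= int_score) {
      loci <- c(loci, best_main)
    } else if (int_score > 0) {
      ints <- c(ints, list(best_int))
    } else if (pair_search && !pair_used && length(loci) + 2L <= max_qtl) {
      pair_used <- TRUE
      ps <- .pair_scan(y, P, grid, fit$qr, fit$rss, n)
      if (!is.null(ps) &&
          ps$lod_gain - (2 * penalty_main + penalty_int) > 0) {
        loci <- c(loci, ps$i, ps$j)
        ints <- c(ints, list(c(ps$i, ps$j)))
      } else break
    } else break
  }
  # backward elimination on the penalized score
  repeat {
    fit <- .mqm_fit(y, P, loci, ints)
    cur <- .plod(fit$lod, length(loci), length(ints), penalty_main, penalty_int)
    best_gain <- 0; best_drop <- NULL
    for (k in seq_along(ints)) {
      f2 <- .mqm_fit(y, P, loci, ints[-k])
      g <- .plod(f2$lod, length(loci), length(ints) - 1L,
                 penalty_main, penalty_int) - cur
      if (g > best_gain) { best_gain <- g; best_drop <- list(type = "int", k = k) }
    }
    for (k in seq_along(loci)) {
      keep_ints <- Filter(function(p) !loci[k] %in% p, ints)
      f2 <- .mqm_fit(y, P, loci[-k], keep_ints)
      g <- .plod(f2$lod, length(loci) - 1L, length(keep_ints),
                 penalty_main, penalty_int) - cur
      if (g > best_gain) { best_gain <- g; best_drop <- list(type = "locus", k = k) }
    }
    if (is.null(best_drop)) break
    if (best_drop$type == "int") {
      ints <- ints[-best_drop$k]
    } else {
      ints <- Filter(function(p) !loci[best_drop$k] %in% p, ints)
      loci <- loci[-best_drop$k]
    }
  }
  fit <- .mqm_fit(y, P, loci, ints)
  loci_df <- data.frame(chromosome = grid$chromosome[loci],
                        position_cM = grid$position_cM[loci],
                        grid_idx = loci, stringsAsFactors = FALSE)
  imat <- if (length(ints)) {
    t(vapply(ints, function(p) c(match(p[1], loci), match(p[2], loci)),
             integer(2)))
  } else matrix(integer(0), 0, 2)
  structure(list(loci = loci_df, interactions = imat, lod = fit$lod,
                 plod = .plod(fit$lod, length(loci), length(ints),
                              penalty_main, penalty_int),
                 penalty_main = penalty_main, penalty_int = penalty_int,
                 n = n),
            class = "multiqtl_model")
}

#' @export
print.multiqtl_model <- function(x, ...) {
  cat(sprintf("multi-QTL model: %d loci, %d interactions, LOD %.2f (pLOD %.2f)\n",
              nrow(x$loci), nrow(x$interactions), x$lod, x$plod))
  invisible(x)
}

#' Drop-one refinement of a multi-QTL model
#'
#' Refits the model with each QTL removed in turn (its interactions removed
#' with it); the per-QTL LOD is the loss in model LOD. QTLs whose drop-one
#' LOD falls below `threshold` are pruned, and the procedure repeats until
#' stable. Interaction terms get the analogous single-term drop LOD.
#'
#' @param model a `multiqtl_model` from [fit_multiqtl_stepwise()].
#' @inheritParams fit_multiqtl_stepwise
#' @param threshold pruning threshold on the drop-one LOD (default: the
#'   model's main-effect penalty).
#' @return The refined `multiqtl_model` with `drop_lod` on `loci` and an
#'   `int_drop_lod` vector.
#' @export
drop_one_refine <- function(model, trait_means, genotypes, grid,
                            threshold = model$penalty_main, probs = NULL) {
  if (is.null(probs)) probs <- genotype_probs(genotypes, grid)
  keep <- !is.na(trait_means)
  y <- trait_means[keep]
  P <- probs[names(trait_means)[keep], , drop = FALSE]
  loci <- model$loci$grid_idx
  ints <- if (nrow(model$interactions)) {
    lapply(seq_len(nrow(model$interactions)), function(r)
      loci[model$interactions[r, ]])
  } else list()
  repeat {
    if (!length(loci)) break
    fit <- .mqm_fit(y, P, loci, ints)
    drop_lod <- vapply(seq_along(loci), function(k) {
      keep_ints <- Filter(function(p) !loci[k] %in% p, ints)
      fit$lod - .mqm_fit(y, P, loci[-k], keep_ints)$lod
    }, numeric(1))
    worst <- which.min(drop_lod)
    if (drop_lod[worst] < threshold) {
      ints <- Filter(function(p) !loci[worst] %in% p, ints)
      loci <- loci[-worst]
    } else break
  }
  fit <- .mqm_fit(y, P, loci, ints)
  int_drop <- vapply(seq_along(ints), function(k)
    fit$lod - .mqm_fit(y, P, loci, ints[-k])$lod, numeric(1))
  drop_lod <- vapply(seq_along(loci), function(k) {
    keep_ints <- Filter(function(p) !loci[k] %in% p, ints)
    fit$lod - .mqm_fit(y, P, loci[-k], keep_ints)$lod
  }, numeric(1))
  loci_df <- data.frame(chromosome = grid$chromosome[loci],
                        position_cM = grid$position_cM[loci],
                        grid_idx = loci, drop_lod = drop_lod,
                        stringsAsFactors = FALSE)
  imat <- if (length(ints)) {
    t(vapply(ints, function(p) c(match(p[1], loci), match(p[2], loci)),
             integer(2)))
  } else matrix(integer(0), 0, 2)
  structure(list(loci = loci_df, interactions = imat,
                 int_drop_lod = int_drop, lod = fit$lod,
                 plod = .plod(fit$lod, length(loci), length(ints),
                              model$penalty_main, model$penalty_int),
                 penalty_main = model$penalty_main,
                 penalty_int = model$penalty_int, n = fit$n),
            class = "multiqtl_model")
}
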