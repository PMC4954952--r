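# Multi-trait linear model with 1-df terms.
#
# All genetic model terms here are single-df contrasts (two RIL classes, two
# experiments, sum-to-zero +/-1 coding), so each term's Type III SS equals
# t^2 * sigma^2 for its coefficient t statistic: the term adjusted for all
# others. Fitting one QR per design and sweeping all traits through it at
# once is what makes panel-level ANOVA and its permutation nulls cheap.
#
# X: n x p design (first column intercept), Y: n x T trait matrix.
# Returns coef, se, t, p, ss (p x T), rss (T), df_res, kept columns.
.mtlm <- function(X, Y, warn_alias = TRUE) {
  qx <- qr(X)
  kept <- qx$pivot[seq_len(qx$rank)]
  if (qx$rank < ncol(X)) {
    if (warn_alias) {
      warning("aliased design column(s) dropped: ",
              paste(colnames(X)[setdiff(seq_len(ncol(X)), kept)],
                    collapse = ", "))
    }
    X <- X[, sort(kept), drop = FALSE]
    qx <- qr(X)
  }
  n <- nrow(X); p <- ncol(X)
  coef <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  rss <- colSums(res^2)
  df_res <- n - p
  if (df_res <= 0) stop("no residual degrees of freedom")
  sigma2 <- rss / df_res
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE]))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tt <- coef / se
  pp <- 2 * stats::pt(abs(tt), df_res, lower.tail = FALSE)
  ss <- coef^2 / xtx_inv_diag
  rownames(coef) <- rownames(se) <- rownames(tt) <- rownames(pp) <-
    rownames(ss) <- colnames(X)
  list(coef = coef, se = se, t = tt, p = pp, ss = ss, rss = rss,
       df_res = df_res, terms = colnames(X))
}

# line x experiment trait means as a matrix with rows "line\rexp"
.line_exp_means <- function(traits) {
  key <- paste(traits$line, traits$experiment, sep = "\r")
  agg <- tapply(traits$value, list(key, traits$trait), mean, na.rm = TRUE)
  agg
}

# +/-1 marker codes for given markers; missing calls imputed from the
# conditional genotype probability at the marker (2 P(A) - 1)
.marker_codes <- function(genotypes, markers) {
  map <- attr(genotypes, "map")
  idx <- match(markers, map$marker)
  if (anyNA(idx)) stop("marker(s) not on map: ",
                       paste(markers[is.na(idx)], collapse = ", "))
  calls <- unclass(genotypes)[, idx, drop = FALSE]
  X <- matrix(0, nrow(calls), length(markers),
              dimnames = list(rownames(calls), markers))
  X[calls == "A"] <- 1; X[calls == "B"] <- -1
  if (anyNA(calls)) {
    g <- data.frame(chromosome = map$chromosome[idx],
                    position_cM = map$position_cM[idx],
                    marker = markers, stringsAsFactors = FALSE)
    class(g) <- c("scan_grid", "data.frame")
    P <- genotype_probs(genotypes, g)
    X[is.na(calls)] <- (2 * P - 1)[is.na(calls)]
  }
  X
}
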