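#' Genotype x experiment ANOVA for one trait
#'
#' Fits value ~ line + experiment + line:experiment on the replicated
#' observations with sum-to-zero contrasts and returns Type III sums of
#' squares, F and p per term. With a fully confounded design (every line
#' observed in only one experiment) the interaction is dropped with a
#' warning.
#'
#' @param trait data.frame with columns `line`, `experiment`, `value`
#'   (replicated observations of one trait).
#' @return data.frame with `term`, `ss`, `df`, `F`, `p`.
#' @export
fit_gxe_anova <- function(trait) {
  d <- data.frame(line = factor(trait$line),
                  experiment = factor(trait$experiment),
                  value = trait$value)
  d <- d[!is.na(d$value), ]
  if (nlevels(droplevels(d$line)) < 2) stop("need >= 2 lines")
  crossed <- any(rowSums(table(d$line, d$experiment) > 0) > 1)
  form <- if (crossed && nlevels(droplevels(d$experiment)) > 1) {
    value ~ line + experiment + line:experiment
  } else {
    if (!crossed) warning("line and experiment fully confounded; dropping interaction")
    value ~ line + experiment
  }
  fit <- stats::lm(form, data = d,
                   contrasts = list(line = "contr.sum",
                                    experiment = "contr.sum"))
  a <- car::Anova(fit, type = 3, singular.ok = TRUE)
  a <- a[!rownames(a) %in% c("(Intercept)"), , drop = FALSE]
  fcol <- grep("^F value", colnames(a), value = TRUE)[1]  # "F value(s)"
  data.frame(term = rownames(a), ss = a[["Sum Sq"]], df = a[["Df"]],
             F = a[[fcol]], p = a[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Broad-sense heritability by expected mean squares
#'
#' On the balanced randomized-complete-block design (two experiments, two
#' blocks each), variance components come from the expected mean squares of
#' the replicate-level ANOVA. Within one experiment,
#' Vg = (MS_line - MS_error) / r. Across the combined experiments the
#' line x experiment mean square replaces the error in the numerator, so Vg
#' is the strict among-line variance with experiment and G x E variance
#' removed (they stay in Vp): Vg = (MS_line - MS_int) / (r E),
#' Vgxe = (MS_int - MS_error) / r, Vexp = (MS_exp - MS_int) / (r G).
#' Replicate numbers are harmonic means, so mildly unbalanced data are
#' tolerated. Negative estimates are truncated to zero and
#' H2 = Vg / (Vg + Vexp + Vgxe + Verr).
#'
#' @param trait data.frame with `line`, `experiment`, `value` (and any other
#'   columns, ignored) for one trait.
#' @param scope "combined" (default), "exp1" or "exp2".
#' @param include_gxe_in_vg count G x E variance as genetic in the combined
#'   scope (default FALSE, strict broad sense).
#' @return list (class `variance_components`) with Vg, Vexp, Vgxe, Verr, Vp,
#'   H2.
#' @export
broad_sense_h2 <- function(trait, scope = c("combined", "exp1", "exp2"),
                           include_gxe_in_vg = FALSE) {
  scope <- match.arg(scope)
  d <- trait[!is.na(trait$value), c("line", "experiment", "value")]
  if (scope == "exp1") d <- d[d$experiment == 1, ]
  if (scope == "exp2") d <- d[d$experiment == 2, ]
  d$line <- as.character(d$line)
  nrep <- table(d$line)
  if (max(nrep) < 2) stop("single replicate per line: H2 undefined")
  if (stats::var(d$value) == 0) {
    return(structure(list(Vg = 0, Vexp = 0, Vgxe = 0, Verr = 0, Vp = 0,
                          H2 = 0, scope = scope),
                     class = "variance_components"))
  }
  grand <- mean(d$value)
  if (scope != "combined") {
    lm_ <- tapply(d$value, d$line, mean)
    r_h <- 1 / mean(1 / nrep[names(lm_)])
    G <- length(lm_)
    ss_line <- sum(nrep[names(lm_)] * (lm_ - grand)^2)
    ms_line <- ss_line / (G - 1)
    resid <- d$value - lm_[d$line]
    df_err <- nrow(d) - G
    ms_err <- sum(resid^2) / df_err
    Vg <- max((ms_line - ms_err) / r_h, 0)
    Verr <- ms_err
    Vp <- Vg + Verr
    return(structure(list(Vg = Vg, Vexp = 0, Vgxe = 0, Verr = Verr, Vp = Vp,
                          H2 = if (Vp > 0) Vg / Vp else 0, scope = scope),
                     class = "variance_components"))
  }
  d$experiment <- as.character(d$experiment)
  E <- length(unique(d$experiment))
  if (E < 2) stop("combined scope needs two experiments")
  cellkey <- paste(d$line, d$experiment, sep = "\r")
  cellm <- tapply(d$value, cellkey, mean)
  celln <- table(cellkey)
  linem <- tapply(d$value, d$line, mean)
  expm <- tapply(d$value, d$experiment, mean)
  G <- length(linem)
  r_cell <- 1 / mean(1 / celln)                 # blocks per line x exp cell
  ss_line <- sum(table(d$line)[names(linem)] * (linem - grand)^2)
  ss_exp <- sum(table(d$experiment)[names(expm)] * (expm - grand)^2)
  lg <- sub("\r.*$", "", names(cellm))
  le <- sub("^.*\r", "", names(cellm))
  ss_int <- sum(celln * (cellm - linem[lg] - expm[le] + grand)^2)
  resid <- d$value - cellm[cellkey]
  df_err <- nrow(d) - length(cellm)
  ms_line <- ss_line / (G - 1)
  ms_exp <- ss_exp / (E - 1)
  ms_int <- ss_int / ((G - 1) * (E - 1))
  ms_err <- sum(resid^2) / df_err
  Vg <- max((ms_line - ms_int) / (r_cell * E), 0)
  Vgxe <- max((ms_int - ms_err) / r_cell, 0)
  Vexp <- max((ms_exp - ms_int) / (r_cell * G), 0)
  Verr <- ms_err
  if (include_gxe_in_vg) { Vg <- Vg + Vgxe; Vgxe <- 0 }
  Vp <- Vg + Vexp + Vgxe + Verr
  structure(list(Vg = Vg, Vexp = Vexp, Vgxe = Vgxe, Verr = Verr, Vp = Vp,
                 H2 = if (Vp > 0) Vg / Vp else 0, scope = scope),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("H2 = %.3f (%s scope): Vg %.3g, Vexp %.3g, Vgxe %.3g, Verr %.3g\n",
              x$H2, x$scope, x$Vg, x$Vexp, x$Vgxe, x$Verr))
  invisible(x)
}

#' Heritability table for a whole panel
#'
#' @param traits a `trait_table`.
#' @param scopes character vector of scopes to compute.
#' @return data.frame `trait`, `scope`, `Vg`, `Vexp`, `Vgxe`, `Verr`, `Vp`,
#'   `H2`.
#' @export
heritability_table <- function(traits,
                               scopes = c("exp1", "exp2", "combined")) {
  trs <- unique(traits$trait)
  rows <- list()
  for (t in trs) {
    sub <- traits[traits$trait == t, ]
    for (s in scopes) {
      v <- broad_sense_h2(sub, scope = s)
      rows[[paste(t, s)]] <- data.frame(
        trait = t, scope = s, Vg = v$Vg, Vexp = v$Vexp, Vgxe = v$Vgxe,
        Verr = v$Verr, Vp = v$Vp, H2 = v$H2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-line coefficient of variation
#'
#' CV = sample standard deviation / mean of a line's replicates (all
#' replicates across both experiments by default): the dimensionless
#' stochastic-variation phenotype. Lines with fewer than two replicates or a
#' non-positive mean get NA (with a warning for non-positive means).
#'
#' @param trait data.frame with `line`, `value` (one trait; optionally
#'   `experiment` when `per_experiment = TRUE`).
#' @param per_experiment compute CV within each experiment, then average.
#' @return Named numeric vector of per-line CVs.
#' @export
line_cv <- function(trait, per_experiment = FALSE) {
  d <- trait[!is.na(trait$value), ]
  one <- function(sub) {
    m <- tapply(sub$value, sub$line, mean)
    s <- tapply(sub$value, sub$line, stats::sd)
    n <- tapply(sub$value, sub$line, length)
    cv <- s / m
    cv[n < 2] <- NA_real_
    bad <- !is.na(m) & m <= 0 & n >= 2
    if (any(bad)) {
      warning("non-positive line mean(s); CV set missing for: ",
              paste(names(m)[bad], collapse = ", "))
      cv[bad] <- NA_real_
    }
    cv
  }
  if (!per_experiment) return(one(d))
  cvs <- lapply(split(d, d$experiment), one)
  lines <- unique(d$line)
  out <- rowMeans(vapply(cvs, function(v) v[lines], numeric(length(lines))),
                  na.rm = TRUE)
  names(out) <- lines
  out[is.nan(out)] <- NA_real_
  out
}

#' CV trait table for the stochastic-variation mapping branch
#'
#' Converts a replicated panel into per-line CV "observations" in the same
#' long format, so the scan machinery consumes them unchanged (one pseudo
#' replicate per line, experiment = 1, block = 1).
#'
#' @param traits a `trait_table`.
#' @param per_experiment see [line_cv()].
#' @return A `trait_table` of CV values.
#' @export
cv_trait_table <- function(traits, per_experiment = FALSE) {
  rows <- lapply(unique(traits$trait), function(t) {
    cv <- line_cv(traits[traits$trait == t, ], per_experiment)
    data.frame(line = names(cv), experiment = 1L, block = 1L,
               trait = paste0("CV_", t), value = as.numeric(cv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Median-normalize a replicated trait panel
#'
#' Divides each sample's values (one line x experiment x block) by that
#' sample's median across traits, putting every sample's median at 1 —
#' the standard correction for sample-to-sample technical intensity
#' differences. Samples with a zero or missing median are flagged with a
#' warning and left unscaled.
#'
#' @param traits a `trait_table`.
#' @return The normalized `trait_table`.
#' @export
median_normalize <- function(traits) {
  key <- paste(traits$line, traits$experiment, traits$block, sep = "\r")
  med <- tapply(traits$value, key, stats::median, na.rm = TRUE)
  scl <- med[key]
  bad <- is.na(scl) | scl == 0
  if (any(bad)) {
    warning("sample(s) with zero/NA median left unscaled: ",
            paste(unique(gsub("\r", "/", key[bad])), collapse = ", "))
    scl[bad] <- 1
  }
  traits$value <- traits$value / as.numeric(scl)
  traits
}
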