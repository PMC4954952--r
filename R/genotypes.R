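#' Construct and validate a RIL genotype matrix
#'
#' RIL genotypes are one of two homozygous parental classes: "A" (Lemont-type)
#' or "B" (Teqing-type), with NA for missing calls. Columns must match the
#' map's markers in order.
#'
#' @param calls character matrix, lines x markers, values in {"A","B",NA};
#'   rownames are line ids, colnames marker names.
#' @param map the `genetic_map` the columns correspond to.
#' @return A `genotype_matrix` (the validated character matrix with the map
#'   attached as attribute `"map"`).
#' @export
genotype_matrix <- function(calls, map) {
  stopifnot(inherits(map, "genetic_map"), is.matrix(calls))
  if (is.null(rownames(calls))) rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) stop("genotype matrix needs marker colnames")
  if (!identical(colnames(calls), map$marker)) {
    if (!setequal(colnames(calls), map$marker)) {
      missing <- setdiff(colnames(calls), map$marker)
      extra <- setdiff(map$marker, colnames(calls))
      stop("map/genotype marker mismatch: ",
           paste(c(missing, extra), collapse = ", "))
    }
    calls <- calls[, map$marker, drop = FALSE]
  }
  bad <- !(calls %in% c("A", "B") | is.na(calls))
  if (any(bad)) stop("unknown genotype codes: ",
                     paste(unique(calls[bad]), collapse = ", "))
  all_missing <- colSums(!is.na(calls)) == 0L
  if (any(all_missing)) {
    warning("markers with no calls at all: ",
            paste(colnames(calls)[all_missing], collapse = ", "))
  }
  structure(calls, map = map, class = c("genotype_matrix", class(calls)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("RIL genotypes: %d lines x %d markers (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(unclass(x)))))
  invisible(x)
}

# two-state RIL transition: P(same class after d cM)
.ril_stay <- function(d, map_function = "haldane") {
  1 - ril_recfrac_cm(d, map_function)
}

#' Conditional QTL-genotype probabilities on a scan grid
#'
#' For every line and grid position, the probability of carrying the "A"
#' (Lemont) class, conditioned on the nearest non-missing flanking markers.
#' The genotype process along a selfed-RIL chromosome is treated as a
#' two-state Markov chain whose transition probability over d cM is the
#' RIL-scale recombination fraction `ril_recfrac_cm(d)`. At a non-missing
#' marker the probability is exactly 1 (call "A") or 0 (call "B"); with no
#' informative marker on the chromosome it falls back to the unconditional
#' 1/2 with a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @param grid a `scan_grid` from [build_scan_grid()].
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return Numeric matrix, lines x grid positions, of P(A).
#' @export
genotype_probs <- function(genotypes, grid, map_function = "haldane") {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(grid, "scan_grid"))
  map <- attr(genotypes, "map")
  n <- nrow(genotypes)
  P <- matrix(NA_real_, n, nrow(grid),
              dimnames = list(rownames(genotypes), NULL))
  warned <- FALSE
  for (chr in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == chr)
    gpos <- grid$position_cM[gi]
    mi <- which(map$chromosome == chr)
    mpos <- map$position_cM[mi]
    calls <- unclass(genotypes)[, mi, drop = FALSE]
    x <- matrix(NA_real_, n, length(mi))  # 1 = A, 0 = B
    x[calls == "A"] <- 1; x[calls == "B"] <- 0
    for (l in seq_len(n)) {
      obs <- which(!is.na(x[l, ]))
      if (length(obs) == 0L) {
        if (!warned) {
          warning("line(s) with no informative markers on chromosome ", chr,
                  "; using unconditional 1/2")
          warned <- TRUE
        }
        P[l, gi] <- 0.5
        next
      }
      opos <- mpos[obs]
      og <- x[l, obs]
      left <- findInterval(gpos, opos)            # 0 if before first obs
      right <- length(obs) + 1L - findInterval(-gpos, rev(-opos))
      pl <- rep(NA_real_, length(gpos))
      # both flanks
      both <- left >= 1L & right <= length(obs)
      if (any(both)) {
        dl <- gpos[both] - opos[left[both]]
        dr <- opos[right[both]] - gpos[both]
        sl <- .ril_stay(dl, map_function); sr <- .ril_stay(dr, map_function)
        gl <- og[left[both]]; gr <- og[right[both]]
        # P(flank_left -> A over dl) and P(A -> flank_right over dr)
        pLA <- ifelse(gl == 1, sl, 1 - sl)
        pAR <- ifelse(gr == 1, sr, 1 - sr)
        pLB <- ifelse(gl == 1, 1 - sl, sl)
        pBR <- ifelse(gr == 1, 1 - sr, sr)
        pl[both] <- pLA * pAR / (pLA * pAR + pLB * pBR)
      }
      onlyl <- left >= 1L & right > length(obs)
      if (any(onlyl)) {
        dl <- gpos[onlyl] - opos[left[onlyl]]
        sl <- .ril_stay(dl, map_function)
        pl[onlyl] <- ifelse(og[left[onlyl]] == 1, sl, 1 - sl)
      }
      onlyr <- left < 1L & right <= length(obs)
      if (any(onlyr)) {
        dr <- opos[right[onlyr]] - gpos[onlyr]
        sr <- .ril_stay(dr, map_function)
        pl[onlyr] <- ifelse(og[right[onlyr]] == 1, sr, 1 - sr)
      }
      P[l, gi] <- pl
    }
  }
  P
}

#' Conditional P(A) for one line at one map position
#'
#' Scalar convenience wrapper around [genotype_probs()] for a single
#' (chromosome, cM) query.
#'
#' @param genotypes a `genotype_matrix`.
#' @param line line id or row index.
#' @param chromosome chromosome label.
#' @param position_cM genetic position on that chromosome.
#' @inheritParams genotype_probs
#' @return P(genotype = A) in [0, 1].
#' @export
conditional_genotype_prob <- function(genotypes, line, chromosome, position_cM,
                                      map_function = "haldane") {
  map <- attr(genotypes, "map")
  if (!chromosome %in% map$chromosome) stop("position not on a mapped chromosome")
  g <- data.frame(chromosome = as.character(chromosome),
                  position_cM = position_cM, marker = NA_character_,
                  stringsAsFactors = FALSE)
  class(g) <- c("scan_grid", "data.frame")
  gm <- genotypes[line, , drop = FALSE]
  gm <- structure(gm, map = map, class = c("genotype_matrix", class(unclass(gm))))
  unname(genotype_probs(gm, g, map_function)[1, 1])
}
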