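#' Construct and validate a genetic map
#'
#' A genetic map is the coordinate system for every scan: an ordered table of
#' markers with a chromosome label and a genetic position in centiMorgans.
#'
#' @param marker character vector of unique marker names.
#' @param chromosome vector of chromosome labels (coerced to character).
#' @param position_cM numeric, non-negative genetic positions; must be
#'   non-decreasing within each chromosome.
#' @return A `genetic_map`: a data.frame with columns `marker`, `chromosome`,
#'   `position_cM`, rows ordered by chromosome then position.
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (length(marker) == 0L) stop("empty map")
  if (anyDuplicated(marker)) {
    stop("duplicate marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(is.na(position_cM)) || any(position_cM < 0)) {
    stop("positions must be non-negative and non-missing")
  }
  chr_levels <- unique(chromosome)
  ord <- order(match(chromosome, chr_levels), position_cM)
  m <- data.frame(marker = marker[ord], chromosome = chromosome[ord],
                  position_cM = position_cM[ord], stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d chromosomes, %.1f cM total\n",
              nrow(x), length(unique(x$chromosome)),
              sum(tapply(x$position_cM, x$chromosome, function(p) diff(range(p))))))
  invisible(x)
}

#' Haldane map function
#'
#' Converts genetic distance to a meiotic recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d genetic distance in cM (non-negative, vectorized).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_cm_to_recfrac <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Kosambi map function (interference-adjusted alternative)
#'
#' @param d genetic distance in cM.
#' @return Recombination fraction in [0, 0.5).
#' @export
kosambi_cm_to_recfrac <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("distance must be non-negative")
  0.5 * tanh(2 * d / 100)
}

#' Map-expansion for selfed recombinant inbred lines
#'
#' On a selfed RIL, repeated meioses accumulate crossovers, so the observed
#' (fixed-line) recombination fraction R between two loci exceeds the
#' single-meiosis fraction r: R = 2r / (1 + 2r).
#'
#' @param r meiotic recombination fraction in [0, 0.5].
#' @return Effective RIL recombination fraction; R(0) = 0, R(0.5) = 0.5.
#' @export
ril_recfrac <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fraction must lie in [0, 0.5]")
  }
  2 * r / (1 + 2 * r)
}

#' Effective RIL recombination fraction at a map distance
#' @param d distance in cM.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return RIL-scale recombination fraction.
#' @export
ril_recfrac_cm <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  f <- switch(map_function, haldane = haldane_cm_to_recfrac,
              kosambi = kosambi_cm_to_recfrac)
  ril_recfrac(f(d))
}

#' Build an evaluation grid for interval mapping
#'
#' Covers each chromosome from its first to last marker, keeping every marker
#' position and subdividing each inter-marker interval into equal steps so
#' that no gap exceeds `step`.
#'
#' @param map a `genetic_map`.
#' @param step maximum pseudomarker spacing in cM (default 1).
#' @return A `scan_grid`: data.frame with `chromosome`, `position_cM`,
#'   `marker` (name at marker positions, NA at pseudomarkers).
#' @export
build_scan_grid <- function(map, step = 1) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  chrs <- unique(map$chromosome)
  out <- vector("list", length(chrs))
  for (i in seq_along(chrs)) {
    sub <- map[map$chromosome == chrs[i], ]
    pos <- sub$position_cM
    nm <- sub$marker
    # collapse co-located markers to one grid point (first name kept)
    keep <- !duplicated(pos)
    pos <- pos[keep]; nm <- nm[keep]
    if (length(pos) == 1L) {
      out[[i]] <- data.frame(chromosome = chrs[i], position_cM = pos,
                             marker = nm, stringsAsFactors = FALSE)
      next
    }
    gp <- pos[1]
    gm <- nm[1]
    for (j in seq_len(length(pos) - 1L)) {
      gap <- pos[j + 1L] - pos[j]
      k <- ceiling(gap / step)
      if (k > 1L) {
        mids <- pos[j] + gap * seq_len(k - 1L) / k
        gp <- c(gp, mids); gm <- c(gm, rep(NA_character_, k - 1L))
      }
      gp <- c(gp, pos[j + 1L]); gm <- c(gm, nm[j + 1L])
    }
    out[[i]] <- data.frame(chromosome = chrs[i], position_cM = gp,
                           marker = gm, stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  class(g) <- c("scan_grid", "data.frame")
  g
}
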