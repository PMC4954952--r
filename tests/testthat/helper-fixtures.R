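# shared fixtures, built in code and memoized per test run

# small 5-chromosome map (8 markers each, 70 cM, even 10 cM spacing)
toy_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- genetic_map(
        marker = sprintf("t%02dm%02d", rep(1:5, each = 8), rep(1:8, 5)),
        chromosome = as.character(rep(1:5, each = 8)),
        position_cM = rep(seq(0, 70, by = 10), 5))
    }
    cache
  }
})

toy_genotypes <- local({
  cache <- list()
  function(n_lines = 60, seed = 7) {
    key <- paste(n_lines, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_ril_genotypes(toy_map(), n_lines, seed)
    }
    cache[[key]]
  }
})

toy_grid <- function(step = 2) build_scan_grid(toy_map(), step)

# one-QTL architecture at a toy-map marker
toy_arch_qtl <- function(marker = "t03m04", a = 0.6, sigma = 1, mu = 10,
                         map = toy_map()) {
  i <- match(marker, map$marker)
  trait_architecture(qtl = data.frame(chromosome = map$chromosome[i],
                                      position_cM = map$position_cM[i],
                                      a = a),
                     sigma = sigma, mu = mu)
}

# independent marker-regression LOD oracle: two-group fit via lm at a marker
marker_regression_lod <- function(y, calls) {
  keep <- !is.na(y) & !is.na(calls)
  y <- y[keep]; g <- factor(calls[keep])
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::residuals(stats::lm(y ~ g))^2)
  (n / 2) * log10(rss0 / rss1)
}
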