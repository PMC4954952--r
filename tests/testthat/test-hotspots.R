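test_that("window counts match direct enumeration and ignore input order", {
  grid <- toy_grid(2)
  qtls <- data.frame(chromosome = c("1", "1", "2"),
                     position_cM = c(5, 8, 6))
  wc <- window_counts(qtls, grid, window = 10)
  # position chr1 @ 6: both chr-1 peaks within +/- 5
  expect_equal(wc$count[wc$chromosome == "1" & wc$position_cM == 6], 2)
  # position chr1 @ 14: only the peak at 8 lies within [9, 19]... check: no
  expect_equal(wc$count[wc$chromosome == "1" & wc$position_cM == 12], 1)
  expect_equal(wc$count[wc$chromosome == "2" & wc$position_cM == 6], 1)
  expect_true(all(wc$count[wc$chromosome %in% c("3", "4", "5")] == 0))
  # order invariance
  wc2 <- window_counts(qtls[c(3, 1, 2), ], grid, window = 10)
  expect_identical(wc$count, wc2$count)
  # empty input -> all-zero profile
  expect_true(all(window_counts(qtls[0, ], grid, 10)$count == 0))
})

test_that("hotspot permutation threshold matches exhaustive placement enumeration", {
  # tiny case: 2 identical chromosomes, 2 markers each, 3 QTLs; all 4^3
  # equally likely marker placements enumerated
  m <- genetic_map(sprintf("m%d", 1:4), c("1", "1", "2", "2"),
                   c(0, 40, 0, 40))
  grid <- build_scan_grid(m, 10)   # 5 positions per chromosome
  window <- 10
  cells <- which(!is.na(grid$marker))
  place <- as.matrix(expand.grid(cells, cells, cells))
  maxcount <- apply(place, 1, function(ix) {
    q <- data.frame(chromosome = grid$chromosome[ix],
                    position_cM = grid$position_cM[ix])
    max(window_counts(q, grid, window)$count)
  })
  oracle <- sort(maxcount)[ceiling(0.95 * length(maxcount))]
  got <- hotspot_permutation_threshold(3, grid, window, n_perm = 4000,
                                       alpha = 0.05, seed = 5)
  expect_equal(as.numeric(got), as.numeric(oracle))
  # and the sampled null frequencies agree with the exact ones loosely
  tab_exact <- table(maxcount) / length(maxcount)
  tab_samp <- table(attr(got, "null_max")) / 4000
  common <- intersect(names(tab_exact), names(tab_samp))
  expect_gt(length(common), 1)
  expect_lt(max(abs(tab_exact[common] - tab_samp[common])), 0.03)
})

test_that("hotspot thresholds behave monotonically and degenerate cases hold", {
  grid <- toy_grid(2)
  expect_equal(as.numeric(hotspot_permutation_threshold(1, grid, 10,
                                                        n_perm = 100,
                                                        seed = 1)), 1)
  thr <- vapply(c(10, 50, 200), function(nq)
    as.numeric(hotspot_permutation_threshold(nq, grid, 10, n_perm = 300,
                                             seed = 3)), numeric(1))
  expect_true(all(diff(thr) >= 0))
  expect_error(hotspot_permutation_threshold(0, grid, 10), "at least one")
})

test_that("hotspot extraction and merging follow single linkage", {
  map <- toy_map()
  peaks <- data.frame(
    dataset = c("combined", "exp1", "exp2", "combined"),
    chromosome = c("1", "1", "1", "3"),
    peak_cM = c(20, 20, 20, 50),
    nearest_marker = c("t01m03", "t01m03", "t01m03", "t03m06"),
    count = c(30, 28, 25, 26), threshold = 20,
    stringsAsFactors = FALSE)
  mg <- merge_hotspots(peaks, map, radius = 10)
  expect_equal(nrow(mg), 2)           # identical peaks collapse to one
  expect_equal(mg$marker, c("t01m03", "t03m06"))
  # peaks 25 cM apart stay distinct at radius 10
  p2 <- data.frame(dataset = "combined", chromosome = "2",
                   peak_cM = c(10, 35), nearest_marker = c("a", "b"),
                   count = c(25, 30), threshold = 20)
  expect_equal(nrow(merge_hotspots(p2, map, 10)), 2)
  # chain 0, 8, 16 at radius 10 -> one cluster (single linkage)
  p3 <- data.frame(dataset = "combined", chromosome = "2",
                   peak_cM = c(0, 8, 16), nearest_marker = "x",
                   count = c(25, 40, 25), threshold = 20)
  m3 <- merge_hotspots(p3, map, 10)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$peak_cM, 8)         # represented by the highest count
  # idempotence: merging the merged set changes nothing
  m3b <- merge_hotspots(
    data.frame(dataset = "merged", chromosome = m3$chromosome,
               peak_cM = m3$peak_cM, nearest_marker = m3$marker,
               count = m3$count, threshold = 20), map, 10)
  expect_equal(m3b$peak_cM, m3$peak_cM)
  expect_equal(m3b$marker, m3$marker)
})

test_that("find_hotspots collapses threshold exceedances to peaks", {
  grid <- toy_grid(2)
  qtls <- data.frame(chromosome = rep("2", 30),
                     position_cM = rep(c(28, 30, 32), 10))
  wc <- window_counts(qtls, grid, 10)
  hs <- find_hotspots(wc, 20, toy_map(), "combined")
  expect_equal(nrow(hs), 1)
  expect_equal(hs$chromosome, "2")
  expect_equal(hs$nearest_marker, "t02m04")   # 30 cM
  expect_equal(hs$count, 30)
  expect_equal(nrow(find_hotspots(wc, 40, toy_map())), 0)
})

test_that("hotspot validation flags a shared locus and controls the null", {
  g <- toy_genotypes(150, seed = 37)
  markers <- c("t01m03", "t02m05", "t04m04")
  arch <- c(
    lapply(1:25, function(i) toy_arch_qtl("t02m05", a = 0.5)),
    lapply(1:75, function(i) trait_architecture(sigma = 1, mu = 10)))
  names(arch) <- sprintf("T%03d", 1:100)
  tt <- simulate_trait_panel(g, arch, seed = 41)
  v <- validate_hotspots_marker_model(tt, markers, g, n_perm = 100, seed = 2)
  expect_true(v$validated[v$marker == "t02m05"])
  # null markers validated at most rarely (2 null markers at alpha = 0.05)
  expect_lte(sum(v$validated[v$marker != "t02m05"]), 1)
  expect_gt(v$n_significant[v$marker == "t02m05"], 15)
  # scaling consistency: duplicating every trait doubles observed and null
  # counts, leaving the planted verdict unchanged
  tt2 <- tt
  tt2$trait <- paste0(tt2$trait, "b")
  both <- rbind(tt, tt2)
  class(both) <- class(tt)
  v2 <- validate_hotspots_marker_model(both, markers, g, n_perm = 100,
                                       seed = 2)
  expect_equal(v2$n_significant, 2L * v$n_significant)
  expect_equal(v2$null_threshold, 2L * v$null_threshold)
  expect_true(v2$validated[v2$marker == "t02m05"])
})

test_that("marker x experiment partitioning separates main and G x E signal", {
  g <- toy_genotypes(150, seed = 43)
  markers <- c("t01m03", "t03m04")
  arch <- c(
    lapply(1:30, function(i) toy_arch_qtl("t01m03", a = 0.5)),
    lapply(1:30, function(i) trait_architecture(
      gxe = data.frame(chromosome = "3", position_cM = 30, effect = 0.6),
      sigma = 1, mu = 10)),
    lapply(1:40, function(i) trait_architecture(sigma = 1, mu = 10)))
  names(arch) <- sprintf("T%03d", seq_along(arch))
  tt <- simulate_trait_panel(g, arch, seed = 47)
  mx <- marker_by_experiment_model(tt, markers, g)
  expect_true(all(mx$n_main <= 100 & mx$n_gxe <= 100))
  expect_gt(mx$n_main[mx$marker == "t01m03"], 15)
  expect_gt(mx$n_gxe[mx$marker == "t03m04"], 15)
  expect_true(mx$main_dominant[mx$marker == "t01m03"])
  expect_false(mx$main_dominant[mx$marker == "t03m04"])
})

test_that("hotspot effect tables carry the Lemont-positive sign convention", {
  g <- toy_genotypes(200, seed = 53)
  # two trait groups with opposite-sign effects at one marker (the
  # sugar-up / amino-down pattern), plus null traits
  arch <- c(
    lapply(1:10, function(i) toy_arch_qtl("t05m04", a = 0.6)),
    lapply(1:10, function(i) toy_arch_qtl("t05m04", a = -0.6)),
    lapply(1:10, function(i) trait_architecture(sigma = 1, mu = 10)))
  names(arch) <- c(sprintf("up%02d", 1:10), sprintf("dn%02d", 1:10),
                   sprintf("ns%02d", 1:10))
  tt <- simulate_trait_panel(g, arch, seed = 59)
  et <- hotspot_effect_table(tt, "t05m04", g)
  up <- et$trait %in% sprintf("up%02d", 1:10)
  dn <- et$trait %in% sprintf("dn%02d", 1:10)
  expect_true(all(et$effect[up] > 0))
  expect_true(all(et$effect[dn] < 0))
  expect_true(all(et$direction[up & et$significant] == "lemont_up"))
  expect_true(all(et$direction[dn & et$significant] == "teqing_up"))
  expect_gte(sum(et$significant[up | dn]), 18)
  expect_lte(sum(et$significant[!(up | dn)]), 2)
  # a = +0.6 with mu = 10: standardized effect 2a/mu = 0.12
  expect_equal(mean(et$effect[up]), 0.12, tolerance = 0.035)
})
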