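test_that("LOD of a two-group fit matches the hand-computed value", {
  # genotype classes A,A,B,B with trait (1,2,3,4): RSS0 = 5, RSS1 = 1,
  # LOD = (4/2) log10(5) ~ 1.39794
  P <- matrix(c(1, 1, 0, 0), 4, 1)
  fit <- ricemqtl:::.lod_columns(P, c(1, 2, 3, 4))
  expect_equal(fit$rss0, 5)
  expect_equal(fit$rss[1], 1)
  expect_equal(fit$lod[1], 2 * log10(5), tolerance = 1e-10)
  expect_equal(fit$lod[1], 1.39794, tolerance = 1e-5)
})

test_that("HK at markers equals marker regression with complete genotypes", {
  g <- toy_genotypes(50)
  grid <- toy_grid(2)
  arch <- list(T1 = toy_arch_qtl("t01m04", a = 0.7))
  y <- trait_means_matrix(simulate_trait_panel(g, arch, seed = 2),
                          "combined")[, 1]
  prof <- hk_scan(y, g, grid)
  mi <- which(!is.na(grid$marker))
  oracle <- vapply(grid$marker[mi], function(m)
    marker_regression_lod(y, unclass(g)[names(y), m]), numeric(1))
  expect_equal(unname(prof$lod[mi]), unname(oracle), tolerance = 1e-8)
})

test_that("LOD is invariant to affine trait transformations", {
  g <- toy_genotypes(50)
  grid <- toy_grid(5)
  y <- trait_means_matrix(
    simulate_trait_panel(g, list(T1 = toy_arch_qtl()), seed = 3),
    "combined")[, 1]
  l1 <- hk_scan(y, g, grid)$lod
  l2 <- hk_scan(-2.5 * y + 7, g, grid)$lod
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("degenerate traits are handled: constants give zero LOD, short traits error", {
  g <- toy_genotypes(20)
  grid <- toy_grid(10)
  y <- stats::setNames(rep(3, 20), rownames(g))
  expect_warning(prof <- hk_scan(y, g, grid), "zero-variance")
  expect_true(all(prof$lod == 0))
  expect_error(hk_scan(y[1:5], g, grid), ">= 10 lines")
})

test_that("permutation threshold is the documented order statistic and matches exhaustive enumeration", {
  # 12 lines (enumeration-free checks first)
  g <- toy_genotypes(60)
  grid <- toy_grid(10)
  y <- trait_means_matrix(
    simulate_trait_panel(g, list(T1 = trait_architecture(sigma = 1)),
                         seed = 4), "combined")[, 1]
  P <- genotype_probs(g, grid)
  t10 <- permutation_threshold(y, g, grid, n_perm = 200, alpha = 0.10,
                               seed = 1, probs = P)
  t05 <- permutation_threshold(y, g, grid, n_perm = 200, alpha = 0.05,
                               seed = 1, probs = P)
  expect_lte(as.numeric(t10), as.numeric(t05))  # non-increasing in alpha
  expect_equal(as.numeric(t05),
               sort(attr(t05, "null_max"))[ceiling(0.95 * 200)])
  # reproducible under the seed
  expect_identical(
    as.numeric(permutation_threshold(y, g, grid, 100, seed = 9, probs = P)),
    as.numeric(permutation_threshold(y, g, grid, 100, seed = 9, probs = P)))
  expect_error(permutation_threshold(y, g, grid, n_perm = 10, alpha = 0.05),
               "n_perm")

  # exhaustive oracle: 4 lines x 2 markers, all 24 permutations enumerated
  m <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  calls <- matrix(c("A", "A", "B", "B", "A", "B", "A", "B"), 4, 2,
                  dimnames = list(paste0("l", 1:4), c("a", "b")))
  gt <- genotype_matrix(calls, m)
  gr <- build_scan_grid(m, 1)
  y4 <- stats::setNames(c(1, 2, 3, 4), rownames(calls))
  Pm <- genotype_probs(gt, gr)
  perms <- rbind(
    c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
    c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
    c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
    c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
  exhaustive <- apply(perms, 1, function(ix)
    max(ricemqtl:::.lod_columns(Pm, y4[ix])$lod))
  oracle_thr <- sort(exhaustive)[ceiling(0.95 * 24)]
  got <- permutation_threshold(y4, gt, gr, n_perm = 5000, alpha = 0.05,
                               seed = 21, probs = Pm)
  expect_equal(as.numeric(got), oracle_thr, tolerance = 1e-10)
})

test_that("null genome-wide max LOD grows with marker count", {
  g <- toy_genotypes(60)
  map <- toy_map()
  chr1 <- genetic_map(map$marker[map$chromosome == "1"],
                      rep("1", sum(map$chromosome == "1")),
                      map$position_cM[map$chromosome == "1"])
  grid_small <- build_scan_grid(chr1, 10)
  grid_full <- toy_grid(10)
  set.seed(1)
  y <- stats::setNames(stats::rnorm(60), rownames(g))
  g1 <- simulate_ril_genotypes(chr1, 60, seed = 7)
  t_small <- permutation_threshold(y, g1, grid_small, 400, seed = 2)
  t_full <- permutation_threshold(y, g, grid_full, 400, seed = 2)
  expect_gt(mean(attr(t_full, "null_max")), mean(attr(t_small, "null_max")))
})

test_that("1.5-LOD support intervals follow the profile shape", {
  # synthetic tent profile crossing peak-1.5 at +/-4 cM
  pos <- seq(0, 20, by = 1)
  lod <- 5 - abs(pos - 10) * 1.5 / 4
  grid <- data.frame(chromosome = "1", position_cM = pos,
                     marker = ifelse(pos %% 10 == 0, paste0("m", pos), NA))
  class(grid) <- c("scan_grid", "data.frame")
  prof <- structure(list(grid = grid, lod = lod), class = "lod_profile")
  iv <- lod_support_interval(prof, "1")
  expect_equal(iv$peak_cM, 10)
  expect_equal(iv$low_cM, 5)    # crossing at 6, expanded one grid point
  expect_equal(iv$high_cM, 15)
  expect_equal(iv$low_marker, "m0")
  expect_equal(iv$high_marker, "m20")
  # flat profile -> whole chromosome
  prof2 <- structure(list(grid = grid, lod = rep(2, length(pos))),
                     class = "lod_profile")
  iv2 <- lod_support_interval(prof2, "1")
  expect_equal(c(iv2$low_cM, iv2$high_cM), c(0, 20))
  # peak at chromosome end -> one-sided
  prof3 <- structure(list(grid = grid, lod = seq(0, 5, length.out = 21)),
                     class = "lod_profile")
  iv3 <- lod_support_interval(prof3, "1")
  expect_equal(iv3$peak_cM, 20)
  expect_equal(iv3$high_cM, 20)
  expect_lt(iv3$low_cM, 20)
})

test_that("standardized additive effects follow the study's scale and sign convention", {
  y <- stats::setNames(c(12, 12, 8, 8, 10, 10), paste0("l", 1:6))
  cls <- c("A", "A", "B", "B", "A", "B")
  eff <- standardized_additive_effect(y, cls)
  expect_equal(eff$effect, (mean(c(12, 12, 10)) - mean(c(8, 8, 10))) /
                 mean(y))
  # hand case: mean_A 12, mean_B 8, grand mean 10 -> +0.4
  y2 <- stats::setNames(c(12, 12, 8, 8), paste0("l", 1:4))
  cls2 <- c("A", "A", "B", "B")
  expect_equal(standardized_additive_effect(y2, cls2)$effect, 0.4)
  # equal class means -> 0; label swap flips the sign exactly
  y3 <- stats::setNames(c(5, 7, 5, 7), paste0("l", 1:4))
  expect_equal(standardized_additive_effect(y3, cls2)$effect, 0)
  swap <- c(A = "B", B = "A")[cls2]
  expect_equal(standardized_additive_effect(y2, swap)$effect, -0.4)
  expect_error(standardized_additive_effect(
    stats::setNames(c(-1, 1, -2, 2), paste0("l", 1:4)), cls2), "grand mean")
  expect_error(standardized_additive_effect(y2, rep("A", 4)), "both genotype")
})
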