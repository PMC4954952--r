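test_that("BH adjustment matches the hand-worked example and its properties", {
  expect_equal(fdr_adjust(c(0.01, 0.03, 0.04, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  p <- c(0.001, 0.2, 0.8, 0.04, 0.5)
  expect_true(all(fdr_adjust(p) >= p))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "outside")
})

test_that("the joint epistasis ANOVA matches car's Type III table on a toy design", {
  g <- toy_genotypes(80, seed = 61)
  arch <- list(T1 = trait_architecture(
    qtl = data.frame(chromosome = "1", position_cM = 20, a = 0.4),
    epistasis = data.frame(chromosome1 = "1", position1 = 20,
                           chromosome2 = "3", position2 = 30, w = 0.5),
    exp_effect = 0.8, sigma = 1, mu = 10))
  tt <- simulate_trait_panel(g, arch, seed = 67)
  mk <- c("t01m03", "t03m04")
  rec <- pairwise_epistasis_anova(tt[tt$trait == "T1", ], mk, g)
  # independent oracle: car::Anova type III on the same line x exp means
  M <- trait_means_matrix(tt, "exp1")
  d <- rbind(
    data.frame(y = trait_means_matrix(tt, "exp1")[, 1], e = "e1",
               line = rownames(M)),
    data.frame(y = trait_means_matrix(tt, "exp2")[, 1], e = "e2",
               line = rownames(M)))
  cls <- unclass(g)[d$line, mk]
  # numeric +/-1 codes give the same single-df sum-to-zero contrasts
  d$x1 <- ifelse(cls[, 1] == "A", 1, -1)
  d$x2 <- ifelse(cls[, 2] == "A", 1, -1)
  d$ev <- ifelse(d$e == "e1", 1, -1)
  fit <- stats::lm(y ~ x1 + x2 + ev + x1:x2 + x1:x2:ev, data = d)
  or <- car::Anova(fit, type = 3)
  expect_equal(rec$ss[rec$term == mk[1]], or["x1", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(rec$ss[rec$term == mk[2]], or["x2", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(rec$ss[rec$term == paste0(mk[1], ":", mk[2])],
               or["x1:x2", "Sum Sq"], tolerance = 1e-8)
  expect_equal(rec$ss[rec$term == "experiment"], or["ev", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(rec$ss[rec$term == "Residuals"], or["Residuals", "Sum Sq"],
               tolerance = 1e-6)
  # planted terms significant, three-way not
  expect_lt(rec$q[rec$term == paste0(mk[1], ":", mk[2])], 0.05)
  expect_gt(min(rec$p[rec$type == "pair_exp"]), 0.001)
})

test_that("Type III equals sequential SS on balanced orthogonal designs and sums correctly", {
  # fully balanced 2x2x2 factorial with 2 replicates, constructed by hand
  cells <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), e = c(-1, 1))
  X <- cells[rep(seq_len(nrow(cells)), each = 2), ]
  set.seed(3)
  y <- 5 + 0.7 * X$x1 - 0.4 * X$x2 + 0.9 * X$x1 * X$x2 + 0.3 * X$e +
    stats::rnorm(nrow(X), 0, 0.4)
  D <- cbind(1, X$x1, X$x2, X$x1 * X$x2, X$e, X$x1 * X$x2 * X$e)
  colnames(D) <- c("(Intercept)", "m1", "m2", "m1:m2", "e", "m1:m2:e")
  fit <- ricemqtl:::.mtlm(D, matrix(y))
  # sequential (Type I) SS from anova() on the same ordering
  seq_ss <- stats::anova(stats::lm(y ~ X$x1 + X$x2 + I(X$x1 * X$x2) +
                                     X$e + I(X$x1 * X$x2 * X$e)))
  expect_equal(unname(fit$ss[-1, 1]), seq_ss$`Sum Sq`[1:5],
               tolerance = 1e-8)
  # term SS + residual SS = total SS on the orthogonal design
  expect_equal(sum(fit$ss[-1, 1]) + fit$rss[1], sum((y - mean(y))^2),
               tolerance = 1e-8)
})

test_that("epistatic variance fractions follow the design arithmetic", {
  # noise-free orthogonal design: fractions are exact
  cells <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
  X <- cells[rep(seq_len(nrow(cells)), each = 5), ]
  a1 <- 0.8; w <- 0.4
  y <- 10 + a1 * X$x1 + w * X$x1 * X$x2
  D <- cbind(`(Intercept)` = 1, m1 = X$x1, m2 = X$x2,
             `m1:m2` = X$x1 * X$x2)
  fit <- ricemqtl:::.mtlm(D, matrix(y))
  rec <- data.frame(term = c("m1", "m2", "m1:m2"),
                    type = c("main", "main", "pair"),
                    ss = fit$ss[-1, 1])
  frac <- epistatic_variance_fraction(rec)
  expect_equal(frac, 100 * w^2 / (a1^2 + w^2), tolerance = 1e-6)
  # degenerate cases
  rec0 <- data.frame(term = "m1", type = "main", ss = 0.5)
  expect_equal(epistatic_variance_fraction(rec0), 0)
  rec1 <- data.frame(term = "m1:m2", type = "pair", ss = 3)
  expect_equal(epistatic_variance_fraction(rec1), 100)
  expect_warning(
    z <- epistatic_variance_fraction(
      data.frame(term = "m1", type = "main", ss = 0)), "zero model SS")
  expect_equal(z, 0)
})

test_that("group comparison reproduces the Welch t-test by hand", {
  a <- c(27, 28, 29); b <- c(24, 25, 23)
  out <- compare_variance_fractions(a, b)
  sa2 <- stats::var(a) / 3; sb2 <- stats::var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(sa2 + sb2)
  df_hand <- (sa2 + sb2)^2 / (sa2^2 / 2 + sb2^2 / 2)
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, df_hand, tolerance = 1e-10)
  expect_equal(out$p, 2 * stats::pt(abs(t_hand), df_hand,
                                    lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(out$se_A, stats::sd(a) / sqrt(3))
  idem <- compare_variance_fractions(a, a)
  expect_equal(idem$p, 1, tolerance = 1e-10)
  expect_error(compare_variance_fractions(a, 1), ">= 2")
})

test_that("planted interactions are retained by enrichment and nulls controlled", {
  g <- toy_genotypes(200, seed = 71)
  mk <- c("t01m03", "t02m05", "t04m04", "t05m06")
  arch <- c(
    lapply(1:20, function(i) trait_architecture(
      epistasis = data.frame(chromosome1 = "1", position1 = 20,
                             chromosome2 = "4", position2 = 30, w = 0.45),
      sigma = 1, mu = 10)),
    lapply(1:80, function(i) trait_architecture(sigma = 1, mu = 10)))
  names(arch) <- sprintf("T%03d", 1:100)
  tt <- simulate_trait_panel(g, arch, seed = 73)
  epi <- epistasis_enrichment(tt, mk, g, n_perm = 60, seed = 3)
  planted <- epi$marker1 == "t01m03" & epi$marker2 == "t04m04"
  expect_true(epi$retained[planted])
  expect_gt(epi$n_significant_traits[planted], 10)
  expect_lte(sum(epi$retained[!planted]), 1)
  # determinism under the seed
  epi2 <- epistasis_enrichment(tt, mk, g, n_perm = 60, seed = 3)
  expect_identical(epi, epi2)
})

test_that("network export round-trips through SIF", {
  edges <- data.frame(marker1 = c("a", "b", "c"),
                      marker2 = c("b", "c", "d"),
                      n_significant_traits = c(5L, 3L, 8L),
                      enrichment_p = c(0.01, 0.02, 0.001),
                      experiment_dependent = c(TRUE, FALSE, FALSE))
  sif <- file.path(withr::local_tempdir(), "net.sif")
  export_network(edges, sif)
  back <- read_network(sif)
  expect_equal(nrow(back), 3)
  expect_equal(sort(unique(c(back$marker1, back$marker2))),
               c("a", "b", "c", "d"))
  expect_equal(back$interaction, rep("epistasis", 3))
  expect_setequal(paste(back$marker1, back$marker2),
                  paste(edges$marker1, edges$marker2))
  attr_tab <- utils::read.delim(sub("\\.sif$", ".edges.tsv", sif))
  expect_equal(attr_tab$line_style, c("dashed", "solid", "solid"))
  # empty set -> valid empty SIF
  export_network(edges[0, ], sif)
  expect_equal(nrow(read_network(sif)), 0)
})
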