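# hand-computable balanced toy: 2 lines x 2 experiments x 2 blocks
balanced_toy <- function() {
  data.frame(
    line = rep(c("L1", "L2"), each = 4),
    experiment = rep(rep(1:2, each = 2), 2),
    block = rep(1:2, 4),
    trait = "y",
    value = c(10, 12, 14, 16,   20, 22, 26, 28))
}

test_that("G x E ANOVA reproduces the hand-computed balanced two-way table", {
  d <- balanced_toy()
  a <- fit_gxe_anova(d)
  # hand computation: grand mean 18.5; line means 13, 24; exp means 16, 21
  # SS_line = 4*((13-18.5)^2 + (24-18.5)^2) = 242
  # SS_exp  = 4*((16-18.5)^2 + (21-18.5)^2) = 50
  # cell means 11,15,21,27 -> SS_int = 2*sum((cell - line - exp + grand)^2) = 2
  # SS_err  = sum((y - cell)^2) = 8 * 1 = 8
  expect_equal(a$ss[a$term == "line"], 242)
  expect_equal(a$ss[a$term == "experiment"], 50)
  expect_equal(a$ss[a$term == "line:experiment"], 2)
  expect_equal(a$ss[a$term == "Residuals"], 8)
  expect_equal(a$df[a$term == "Residuals"], 4)
  expect_equal(a$F[a$term == "line"], (242 / 1) / (8 / 4))
})

test_that("pure line and pure experiment effects land on the right terms", {
  g <- toy_genotypes(40, seed = 19)
  lines <- rownames(g)
  base <- expand.grid(line = lines, experiment = 1:2, block = 1:2,
                      stringsAsFactors = FALSE)
  set.seed(1)
  d1 <- data.frame(base, trait = "y",
                   value = as.numeric(factor(base$line)) * 2 +
                     stats::rnorm(nrow(base), 0, 1e-3))
  a1 <- fit_gxe_anova(d1)
  expect_lt(a1$p[a1$term == "line"], 1e-10)
  expect_gt(a1$p[a1$term == "experiment"], 0.01)
  d2 <- data.frame(base, trait = "y",
                   value = (base$experiment == 2) * 3 +
                     stats::rnorm(nrow(base), 0, 1))
  a2 <- fit_gxe_anova(d2)
  expect_lt(a2$p[a2$term == "experiment"], 1e-6)
  expect_gt(a2$p[a2$term == "line"], 0.001)
  # fully confounded design drops the interaction with a warning
  half <- d1[(d1$experiment == 1) == (as.integer(factor(d1$line)) <= 20), ]
  expect_warning(fit_gxe_anova(half), "confounded")
})

test_that("broad-sense heritability handles the degenerate and perfect cases", {
  d <- data.frame(line = rep(c("a", "b", "c"), each = 4),
                  experiment = rep(rep(1:2, each = 2), 3),
                  value = rep(c(1, 5, 9), each = 4))
  v <- broad_sense_h2(d, "combined")
  expect_equal(v$H2, 1)
  expect_equal(v$Verr, 0)
  d0 <- d; d0$value <- 4
  expect_equal(broad_sense_h2(d0, "combined")$H2, 0)
  d1 <- d[d$experiment == 1 & d$line != "c" | d$experiment == 2, ]
  d1 <- d1[!duplicated(d1$line), ]
  expect_error(broad_sense_h2(d1, "combined"), "single replicate")
})

test_that("heritability estimates recover the simulated truth", {
  map <- toy_map()
  # unlinked loci on separate chromosomes; per-observation
  # H2 = Vg / (Vg + sigma^2)
  for (target in c(0.25, 0.5)) {
    Vg <- target / (1 - target)       # sigma = 1
    a <- sqrt(Vg / 4)
    est <- numeric(12)
    for (s in seq_along(est)) {
      g <- simulate_ril_genotypes(map, 250, seed = 1000 + s)
      arch <- list(T1 = trait_architecture(
        qtl = data.frame(chromosome = c("1", "2", "4", "5"),
                         position_cM = c(20, 30, 40, 50), a = a),
        sigma = 1, mu = 10))
      tt <- simulate_trait_panel(g, arch, seed = 2000 + s)
      est[s] <- broad_sense_h2(tt[tt$trait == "T1", ], "combined")$H2
    }
    expect_equal(mean(est), target, tolerance = 0.05)
  }
})

test_that("planted G x E depresses combined-scope H2 below within-experiment H2", {
  map <- toy_map()
  g <- simulate_ril_genotypes(map, 200, seed = 31)
  # additive loci and G x E loci kept separate so both experiments carry
  # the same within-experiment genetic variance
  arch <- list(T1 = trait_architecture(
    qtl = data.frame(chromosome = c("1", "3"), position_cM = c(30, 40),
                     a = 0.5),
    gxe = data.frame(chromosome = c("4", "5"), position_cM = c(30, 40),
                     effect = 0.45),
    exp_effect = 1, sigma = 1, mu = 10))
  tt <- simulate_trait_panel(g, arch, seed = 5)
  d <- tt[tt$trait == "T1", ]
  h_comb <- broad_sense_h2(d, "combined")$H2
  h_e1 <- broad_sense_h2(d, "exp1")$H2
  h_e2 <- broad_sense_h2(d, "exp2")$H2
  expect_lt(h_comb, h_e1)
  expect_lt(h_comb, h_e2)
})

test_that("line CV has the documented arithmetic and invariances", {
  d <- data.frame(line = rep("a", 2), experiment = 1:2, value = c(1, 3))
  expect_equal(unname(line_cv(d)["a"]), sqrt(2) / 2)
  d2 <- data.frame(line = rep(c("a", "b"), each = 4),
                   experiment = rep(rep(1:2, each = 2), 2),
                   value = c(2, 2, 2, 2, 4, 5, 6, 7))
  cv <- line_cv(d2)
  expect_equal(unname(cv["a"]), 0)
  # scale invariance
  d3 <- d2; d3$value <- d3$value * 10
  expect_equal(line_cv(d3), cv)
  # non-positive mean -> NA with warning
  d4 <- data.frame(line = rep(c("a", "b"), each = 2), experiment = 1,
                   value = c(-1, 1, 2, 4))
  expect_warning(cv4 <- line_cv(d4), "non-positive")
  expect_true(is.na(cv4["a"]))
  expect_false(is.na(cv4["b"]))
})

test_that("median normalization scales each sample to median 1", {
  tt <- data.frame(line = "L1", experiment = 1, block = 1,
                   trait = c("x", "y", "z"), value = c(2, 4, 6))
  out <- median_normalize(tt)
  expect_equal(out$value, c(0.5, 1, 1.5))
  # idempotent on a median-1 sample; rank order preserved
  out2 <- median_normalize(out)
  expect_equal(out2$value, out$value)
  expect_equal(order(out$value), order(tt$value))
  # zero-median sample flagged and left alone
  tt0 <- data.frame(line = "L1", experiment = 1, block = 1,
                    trait = c("x", "y", "z"), value = c(-2, 0, 2))
  expect_warning(out0 <- median_normalize(tt0), "unscaled")
  expect_equal(out0$value, tt0$value)
})
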