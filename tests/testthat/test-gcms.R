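test_that("peak-area normalisation yields within-sample percentages", {
  one <- data.frame(sample_id = "s1", area = 42)
  expect_equal(normalise_peak_areas(one)$pct, 100)
  four <- data.frame(sample_id = "s1", area = rep(7, 4))
  expect_equal(normalise_peak_areas(four)$pct, rep(25, 4))
  set.seed(3)
  tab <- data.frame(sample_id = rep(c("a", "b"), each = 5),
                    area = runif(10, 0, 100))
  nt <- normalise_peak_areas(tab)
  expect_equal(as.numeric(tapply(nt$pct, nt$sample_id, sum)), c(100, 100))
  # invariant to uniform per-sample rescaling; idempotent on pct
  tab2 <- tab; tab2$area <- tab$area * ifelse(tab$sample_id == "a", 3, 0.5)
  expect_equal(normalise_peak_areas(tab2)$pct, nt$pct)
  expect_error(normalise_peak_areas(data.frame(sample_id = "z", area = 0)),
               "zero total")
})

test_that("compounds are classified by elemental formula", {
  expect_equal(classify_compound(c("C10H16", "C15H24", "C7H6O2", "C8H8O",
                                   "C21H30O3", "C29H50O2", "C16H34")),
               c("monoterpene", "sesquiterpene", "oxidation_C7_C8",
                 "oxidation_C7_C8", "oxidation_C20plus", "oxidation_C20plus",
                 "other"))
  # oxygen-free C10/C15 off-stoichiometry compounds stay unclassified
  expect_equal(classify_compound("C10H18"), "other")
  expect_error(classify_compound("notaformula!"), "unparseable")
  ov <- c("weird terpene" = "monoterpene")
  expect_equal(classify_compound("C16H34", "weird terpene", ov), "monoterpene")
})

test_that("class aggregation reproduces a hand-summed profile", {
  tab <- data.frame(
    sample_id = "s1",
    compound = c("a-pinene", "benzoic acid", "coumaran", "germacrene D", "bg"),
    formula = c("C10H16", "C7H6O2", "C8H8O", "C15H24", "C16H34"),
    area = c(10, 20, 20, 40, 10))
  prof <- aggregate_classes(normalise_peak_areas(tab))
  get <- function(cl) prof$pct[prof$class == cl]
  expect_equal(get("monoterpene"), 10)
  expect_equal(get("oxidation_C7_C8"), 40) # 20 + 20 summed by hand
  expect_equal(get("sesquiterpene"), 40)
  expect_equal(get("oxidation_C20plus"), 0) # empty class present as 0
  expect_equal(get("other"), 10)
  expect_equal(sum(prof$pct), 100, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  gA <- c(24.1, 25.3, 23.8, 26.0)
  gB <- c(20.2, 19.5, 21.1, 20.8)
  gC <- c(15.4, 16.2, 14.9, 15.9)
  res <- one_way_anova(c(gA, gB, gC), rep(c("A", "B", "C"), each = 4))
  expect_equal(res$F, oracle$anova_F, tolerance = 1e-9)
  expect_equal(res$p, oracle$anova_p, tolerance = 1e-6)
  expect_equal(unname(res$df), c(2, 9))
  # group means and 0.95 t-intervals
  expect_equal(res$means$mean[1], mean(gA))
  expect_equal(res$means$upr[1] - res$means$mean[1],
               qt(0.975, 3) * sd(gA) / 2)
  # location invariance
  res2 <- one_way_anova(c(gA, gB, gC) + 100, rep(c("A", "B", "C"), each = 4))
  expect_equal(res2$F, res$F, tolerance = 1e-9)
})

test_that("ANOVA edge cases behave classically", {
  # identical group means -> F = 0
  v <- c(1, 2, 3, 1, 2, 3)
  expect_equal(one_way_anova(v, rep(c("A", "B"), each = 3))$F, 0,
               tolerance = 1e-12)
  # two groups: F equals the squared pooled t statistic
  set.seed(9)
  a <- rnorm(8); b <- rnorm(8, 1)
  res <- one_way_anova(c(a, b), rep(c("A", "B"), each = 8))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_true(res$p > 0 && res$p <= 1)
  # zero within-group variance with unequal means -> infinite F
  res_inf <- one_way_anova(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_equal(res_inf$F, Inf)
  expect_equal(res_inf$p, 0)
  expect_error(one_way_anova(1:3, c("A", "A", "A")), "2 groups")
  expect_error(one_way_anova(c(1, 2), c("A", "B")), "degenerate")
})
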