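test_that("TOST interval matches hand-computed Welch construction", {
  x <- c(1, 2, 3, 4, 5)
  res <- tost_equivalence(x, x, k1 = 1.5, alpha = 0.05)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$se, 1, tolerance = 1e-12)
  expect_equal(res$df, 8, tolerance = 1e-12)
  # +- t_{0.95, 8} * SE = +-1.8595
  expect_equal(res$ci_high, qt(0.95, 8), tolerance = 1e-10)
  expect_equal(res$ci_high, 1.8595, tolerance = 1e-4)
  expect_equal(res$ci_low, -res$ci_high, tolerance = 1e-12)
  expect_equal(res$margin, 1.5 * sd(x), tolerance = 1e-12)
  expect_equal(res$margin, 2.3717, tolerance = 1e-4)
  expect_true(res$pass)
})

test_that("TOST interval agrees with t.test's 90% two-sided interval", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    res <- tost_equivalence(x, y, variance_mode = "welch")
    tt <- t.test(x, y, conf.level = 0.90)
    expect_equal(c(res$ci_low, res$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-10)
    resp <- tost_equivalence(x, y, variance_mode = "pooled")
    ttp <- t.test(x, y, conf.level = 0.90, var.equal = TRUE)
    expect_equal(c(resp$ci_low, resp$ci_high), as.numeric(ttp$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("TOST edge behaviour: zero margin, gross shift, error contracts", {
  x <- c(1, 2, 3, 4, 5)
  # k1 = 0 collapses the margin: any interval with positive width fails
  expect_false(tost_equivalence(x, x, k1 = 0)$pass)
  # a shift of 100 reference SDs can never pass: the interval sits far
  # outside the margin (brute-force location check)
  set.seed(7)
  ref <- rnorm(10)
  test <- rnorm(6) + 100 * sd(ref)
  res <- tost_equivalence(test, ref)
  expect_false(res$pass)
  expect_gt(res$ci_low, res$margin)
  # degenerate reference SD
  expect_error(tost_equivalence(x, rep(2, 5)), "zero standard deviation")
  # insufficient lots
  expect_error(tost_equivalence(c(1, 2), x), "insufficient lots")
})

test_that("Welch and pooled agree when arms share n and sample variance", {
  x <- c(1, 2, 3, 4, 5)
  y <- x + 0.3  # same sample variance, same n
  w <- tost_equivalence(x, y, variance_mode = "welch")
  p <- tost_equivalence(x, y, variance_mode = "pooled")
  expect_equal(w$ci_low, p$ci_low, tolerance = 1e-12)
  expect_equal(w$ci_high, p$ci_high, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-9)
})

test_that("quality range matches hand arithmetic and the closed-interval rule", {
  ref <- c(1, 2, 3, 4, 5)  # mean 3, sd 1.5811
  res <- quality_range(c(2, 3, 9), ref, k2 = 3, pass_fraction = 0.9)
  expect_equal(res$qr_low, 3 - 3 * sd(ref), tolerance = 1e-12)
  expect_equal(res$qr_high, 3 + 3 * sd(ref), tolerance = 1e-12)
  expect_equal(res$qr_low, -1.7434, tolerance = 1e-4)
  expect_equal(res$qr_high, 7.7434, tolerance = 1e-4)
  expect_equal(res$n_inside, 2L)
  expect_equal(res$fraction_inside, 2 / 3, tolerance = 1e-12)
  expect_false(res$pass)

  # all lots at the reference mean sit at the center of the range
  center <- quality_range(rep(3, 6), ref)
  expect_equal(center$fraction_inside, 1)
  expect_true(center$pass)

  # a lot exactly on the bound is inside (closed interval)
  at_bound <- quality_range(c(3 + 3 * sd(ref)), ref)
  expect_equal(at_bound$n_inside, 1L)

  # upper-sided mode for impurity-style attributes
  up <- quality_range(c(-100, 3), ref, sidedness = "upper")
  expect_equal(up$qr_low, -Inf)
  expect_equal(up$n_inside, 2L)

  expect_error(quality_range(c(1, 2), rep(4, 5)), "zero standard deviation")
})

test_that("quality range n_inside equals brute-force per-lot membership", {
  set.seed(55)
  for (i in 1:50) {
    ref <- rnorm(sample(3:12, 1))
    test <- rnorm(sample(1:12, 1), sd = 2)
    res <- quality_range(test, ref)
    lo <- mean(ref) - 3 * sd(ref); hi <- mean(ref) + 3 * sd(ref)
    brute <- 0L
    for (v in test) if (v >= lo && v <= hi) brute <- brute + 1L
    expect_identical(res$n_inside, brute)
  }
})

test_that("tier-3 descriptive comparison flags disjoint and overlapping ranges", {
  # clearly separated glycan levels: zero overlap, flagged lower
  res <- tier3_compare(c(2.2, 2.5, 2.9), c(6.7, 8.0, 8.4))
  expect_equal(res$range_overlap, 0)
  expect_equal(res$flag, "lower")
  # identical samples overlap completely
  idem <- tier3_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idem$range_overlap, 1)
  expect_equal(idem$flag, "similar")
  # partial overlap: intersection 1, union 3
  part <- tier3_compare(c(0, 2), c(1, 3))
  expect_equal(part$range_overlap, 1 / 3, tolerance = 1e-12)
  expect_equal(part$flag, "similar")
  # test entirely above reference
  expect_equal(tier3_compare(c(10, 11), c(1, 2))$flag, "higher")
  # touching ranges are not disjoint
  expect_equal(tier3_compare(c(1, 2), c(2, 3))$flag, "similar")
  # overlap bounded in [0, 1]
  expect_true(part$range_overlap >= 0 && part$range_overlap <= 1)
})

test_that("pass decisions are invariant to affine rescaling a*x + b, a > 0", {
  set.seed(202)
  for (i in 1:40) {
    test <- rnorm(6, mean = runif(1, -2, 2))
    ref <- rnorm(10, sd = runif(1, 0.5, 2))
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    expect_identical(tost_equivalence(a * test + b, a * ref + b)$pass,
                     tost_equivalence(test, ref)$pass)
    expect_identical(quality_range(a * test + b, a * ref + b)$pass,
                     quality_range(test, ref)$pass)
    expect_identical(tier3_compare(a * test + b, a * ref + b)$flag,
                     tier3_compare(test, ref)$flag)
  }
})

test_that("pass is monotone in the margin and range multipliers", {
  set.seed(303)
  k_grid <- c(0.25, 0.5, 1, 1.5, 2, 3, 5)
  for (i in 1:20) {
    test <- rnorm(6, mean = runif(1, -1, 1))
    ref <- rnorm(10)
    t1 <- vapply(k_grid, function(k) tost_equivalence(test, ref, k1 = k)$pass,
                 logical(1))
    expect_true(all(diff(t1) >= 0))  # once passing, stays passing
    t2 <- vapply(k_grid, function(k) quality_range(test, ref, k2 = k)$pass,
                 logical(1))
    expect_true(all(diff(t2) >= 0))
  }
  # quality-range pass is monotone in the number of inside lots
  ref <- c(1, 2, 3, 4, 5)
  lo <- mean(ref) - 3 * sd(ref); hi <- mean(ref) + 3 * sd(ref)
  passes <- vapply(0:6, function(k) {
    test <- c(rep(mean(ref), k), rep(hi + 10, 6 - k))
    quality_range(test, ref)$pass
  }, logical(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("run_similarity dispatches each tier to its procedure", {
  # equal-mean attributes across all three tiers at generous lot counts
  set.seed(9)
  n <- 50
  lots <- lot_table(rbind(
    data.frame(product = "test", lot_id = sprintf("T%02d", 1:n),
               attribute = "potency", value = rnorm(n, 100, 5), unit = "%"),
    data.frame(product = "reference", lot_id = sprintf("R%02d", 1:n),
               attribute = "potency", value = rnorm(n, 100, 5), unit = "%"),
    data.frame(product = "test", lot_id = sprintf("T%02d", 1:n),
               attribute = "monomer", value = rnorm(n, 99, 0.3), unit = "%"),
    data.frame(product = "reference", lot_id = sprintf("R%02d", 1:n),
               attribute = "monomer", value = rnorm(n, 99, 0.3), unit = "%"),
    data.frame(product = "test", lot_id = sprintf("T%02d", 1:n),
               attribute = "cdc", value = rnorm(n, 100, 10), unit = "%"),
    data.frame(product = "reference", lot_id = sprintf("R%02d", 1:n),
               attribute = "cdc", value = rnorm(n, 100, 10), unit = "%")))
  tiers <- data.frame(attribute = c("potency", "monomer", "cdc", "ghost"),
                      assay = "assay", tier = c(1L, 2L, 3L, 2L))
  rep <- run_similarity(lots, tiers)
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$decision[1:3], c("pass", "pass", "similar"))
  # tier-1 rows carry the equivalence statistics, tier-2 the range, tier-3
  # the overlap, and nothing else
  expect_false(is.na(rep$ci_low[1])); expect_true(is.na(rep$qr_low[1]))
  expect_false(is.na(rep$qr_low[2])); expect_true(is.na(rep$ci_low[2]))
  expect_false(is.na(rep$range_overlap[3])); expect_true(is.na(rep$margin[3]))
  # tiered attribute without data is reported, not a crash
  expect_equal(rep$decision[4], "not evaluated")
  # row order follows the tier table
  expect_equal(rep$attribute, tiers$attribute)
})

test_that("run_similarity on an empty tier table gives an empty report", {
  lots <- make_lots(1:3, 4:6)
  rep <- run_similarity(lots, data.frame(attribute = character(),
                                         assay = character(),
                                         tier = integer()))
  expect_s3_class(rep, "similarity_report")
  expect_equal(nrow(rep), 0L)
})

test_that("separated %HM levels are flagged lower while the equal-mean glycan stays similar", {
  lots <- generate_lots(glycan_scenario(seed = 20))
  rep <- run_similarity(lots, glycan_tiers())
  expect_equal(rep$decision[rep$attribute == "High mannose"], "lower")
  expect_equal(rep$range_overlap[rep$attribute == "High mannose"], 0)
  expect_equal(rep$decision[rep$attribute == "Afucosylation"], "similar")
})
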