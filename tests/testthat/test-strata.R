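test_that("median splits label strictly-above-median scores as high", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # equal-to-median goes low
  expect_equal(as.character(median_split(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_equal(as.character(median_split(rep(5, 6))), rep("low", 6))
  expect_error(median_split(numeric(0)), "non-empty")
})

test_that("group combination crosses labels with low/low as reference", {
  prs <- factor(c("low", "high", "low", "high"), c("low", "high"))
  idx <- factor(c("low", "low", "high", "high"), c("low", "high"))
  g <- combine_groups(prs, idx)
  expect_equal(levels(g), c("low/low", "high/low", "low/high", "high/high"))
  expect_equal(as.character(g[1]), "low/low")
  expect_equal(dplyr::n_distinct(g), 4)
  expect_error(combine_groups(prs[1:3], idx), "same subjects")
})

test_that("median-unbiased OR has exact symmetries", {
  sym <- median_unbiased_or(5, 5, 5, 5)
  expect_equal(sym$or_hat, 1, tolerance = 1e-8)
  expect_equal(sym$p, 1)

  # label symmetry: swapping exposed and reference inverts the OR
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rmultinom(1, sample(12:40, 1), rep(0.25, 4))
      if (any(x + c(x[2], x[1], x[4], x[3]) == 0)) next
      if (x[1] + x[3] == 0 || x[2] + x[4] == 0 ||
          x[1] + x[2] == 0 || x[3] + x[4] == 0) next
      f <- median_unbiased_or(x[1], x[2], x[3], x[4])
      r <- median_unbiased_or(x[3], x[4], x[1], x[2])
      if (is.finite(f$or_hat) && f$or_hat > 0) {
        expect_equal(f$or_hat * r$or_hat, 1, tolerance = 1e-6)
      }
    }
  })
})

test_that("the estimate shrinks the crude OR toward 1 and matches the oracle", {
  # The mid-p median-unbiased estimate is less extreme than both the crude
  # cross-product ratio and the conditional MLE (it sits slightly on the
  # null side of the cMLE), so the checkable ordering is shrinkage toward
  # the null, with the grid-refined tail inversion as the exact reference.
  withr::with_seed(11, {
    for (i in 1:30) {
      x <- rmultinom(1, sample(16:40, 1), c(0.3, 0.2, 0.2, 0.3))
      if (any(x == 0)) next
      a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
      mue <- median_unbiased_or(a, b, c, d)$or_hat
      crude <- a * d / (b * c)
      expect_lte(abs(log(mue)), abs(log(crude)) + 1e-9)
      if (abs(log(crude)) > 1e-9) {
        expect_equal(sign(log(mue)), sign(log(crude)))
      }
      expect_equal(mue, or_grid_oracle(a, b, c, d), tolerance = 1e-3)
    }
  })
})

test_that("zero cells give one-sided estimates without error", {
  res0 <- median_unbiased_or(0, 10, 5, 5)
  expect_equal(res0$or_hat, 0)
  expect_equal(res0$ci_low, 0)
  expect_true(is.finite(res0$ci_high))

  resInf <- median_unbiased_or(10, 0, 5, 5)
  expect_equal(resInf$or_hat, Inf)
  expect_true(is.finite(resInf$ci_low))

  expect_error(median_unbiased_or(0, 5, 0, 5), "margin")
  expect_error(median_unbiased_or(1.5, 5, 2, 5), "integers")
})

test_that("risk tables count groups and invert under label swap", {
  grp <- factor(rep(c("low/low", "high/high"), each = 20),
                levels = c("low/low", "high/high"))
  y <- c(rep(0:1, c(15, 5)), rep(0:1, c(5, 15)))
  rt <- risk_table(grp, y)
  expect_equal(nrow(rt), 2)
  expect_equal(rt$or_hat[1], 1)
  expect_equal(rt$cases, c(5, 15))
  expect_equal(rt$controls, c(15, 5))

  # swapping case/control status gives the reciprocal OR
  rt_swap <- risk_table(grp, 1 - y)
  expect_equal(rt$or_hat[2] * rt_swap$or_hat[2], 1, tolerance = 1e-6)

  expect_error(risk_table(factor(rep("g1", 10)), rep(0:1, 5)),
               "at least two")
  bad_ref <- factor(rep(c("a", "b"), each = 5), c("a", "b"))
  expect_error(risk_table(bad_ref, c(rep(1, 5), rep(0, 5))),
               "reference")
})

test_that("validation-set style reconstruction keeps the bookkeeping", {
  co <- generate_cohort(tiny_config(seed = 81))
  phen <- co$phenotypes
  va <- phen$set == "validation"
  prs <- compute_prs(co$genotypes, co$snps[, c("snp_id", "prs_weight")])
  s1 <- prs$prs[va]
  s2 <- colMeans(co$betas$cervical[co$truth$case_cpgs, va])
  grp <- combine_groups(median_split(s1), median_split(s2))
  expect_equal(sum(table(grp)), sum(va))
  rt <- risk_table(grp, phen$case[va])
  expect_equal(sum(rt$cases + rt$controls), sum(va))
})

test_that("quantile OR curves recover planted stochastic ordering", {
  withr::with_seed(21, {
    n <- 4000
    y <- rbinom(n, 1, 0.3)
    s <- rnorm(n) + 1.2 * y
    rt <- quantile_or_curve(s, case_status = y)
    expect_equal(rt$or_hat[1], 1)
    expect_true(all(diff(rt$or_hat) > 0))  # monotone shift -> rising ORs

    # null scores: no bin shows real signal (ORs near 1, no tiny p)
    s0 <- rnorm(n)
    rt0 <- quantile_or_curve(s0, case_status = y)
    expect_true(all(abs(log(rt0$or_hat[-1])) < 0.5))
    expect_true(all(rt0$p[-1] > 0.001))

    # combined standardized score path
    rt2 <- quantile_or_curve(s, rnorm(n), case_status = y)
    expect_equal(nrow(rt2), 4)
  })
  expect_error(quantile_or_curve(1:10, case_status = rep(0:1, 5),
                                 cut_points = c(50, 25)),
               "strictly increasing")
})
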