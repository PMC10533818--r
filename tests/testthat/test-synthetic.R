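test_that("genotype sampling respects allele frequencies and edge cases", {
  snps0 <- tibble::tibble(snp_id = c("a", "b"), maf = c(0, 1))
  g <- generate_genotypes(20, snps0, seed = 1)
  expect_true(all(g[, "a"] == 0))
  expect_true(all(g[, "b"] == 2))

  empty <- generate_genotypes(0, snps0, seed = 1)
  expect_equal(dim(empty), c(0L, 2L))

  snps <- tibble::tibble(snp_id = "s", maf = 0.3)
  g <- generate_genotypes(10000, snps, seed = 42)
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(g) - 0.6), 3 * se)
  expect_true(all(g %in% 0:2))

  expect_error(generate_genotypes(-1, snps), "non-negative")
  expect_identical(generate_genotypes(50, snps, seed = 9),
                   generate_genotypes(50, snps, seed = 9))
})

test_that("methylation generator hits its deterministic limits", {
  snps <- snp_panel(n_snps = 4, seed = 2)
  map <- mqtl_map(snps, n_cpgs = 6, n_multi = 0, seed = 2)
  g <- generate_genotypes(30, snps, seed = 3)
  phen <- tibble::tibble(
    subject_id = rownames(g), case = rep(0:1, 15),
    age = rnorm(30, 55, 5), bmi = rnorm(30, 26, 3),
    immune_fraction = rep(0, 30)
  )
  # zero effects, vanishing noise, f = 0: beta -> logistic(baseline)
  prof <- tissue_profile("cervical", map$cpg_id, baseline_logit = 0.7,
                         immune_baseline_logit = -2, noise_sd = 1e-12)
  map0 <- map
  map0$effect <- 0
  b <- generate_methylation(g, map0, phen, prof, seed = 4)
  expect_equal(unname(b[1, ]), rep(plogis(0.7), 30), tolerance = 1e-9)

  # f = 1: betas carry no genotype or covariate signal at all
  phen1 <- phen
  phen1$immune_fraction <- rep(1, 30)
  prof1 <- tissue_profile("cervical", map$cpg_id, 0.7, -2, noise_sd = 0.5)
  b1 <- generate_methylation(g, map, phen1, prof1,
                             effect_config(case_effect = setNames(2, map$cpg_id[1])),
                             seed = 5)
  expect_true(all(abs(b1 - plogis(-2)) < 1e-12))

  expect_error(
    generate_methylation(g, dplyr::mutate(map, snp_id = "rs_missing"),
                         phen, prof, seed = 1),
    "absent from genotypes"
  )
})

test_that("regression on dosage recovers a planted mQTL effect", {
  snps <- tibble::tibble(snp_id = "rs1", maf = 0.4)
  g <- generate_genotypes(2000, snps, seed = 11)
  phen <- tibble::tibble(subject_id = rownames(g), case = 0,
                         age = 55, bmi = 26, immune_fraction = 0)
  map <- tibble::tibble(snp_id = "rs1", cpg_id = "cg1", effect = 0.5)
  prof <- tissue_profile("cervical", "cg1", baseline_logit = 0,
                         immune_baseline_logit = 0, noise_sd = 0.1)
  b <- generate_methylation(g, map, phen, prof, seed = 12)
  fit <- lm(qlogis(b["cg1", ]) ~ g[, "rs1"])
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 0.5), 3 * se)
})

test_that("cohort bundles are deterministic, consistent, and bounded", {
  cfg <- tiny_config(seed = 21)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)

  expect_equal(nrow(co1$phenotypes), 240)
  expect_equal(as.vector(table(co1$phenotypes$set)[c(
    "discovery-train", "discovery-internal-validation", "validation")]),
    c(120L, 60L, 60L))
  expect_identical(co1$phenotypes$subject_id, rownames(co1$genotypes))
  expect_identical(co1$phenotypes$subject_id,
                   colnames(co1$betas$cervical))
  b <- co1$betas$cervical
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(co1$genotypes %in% 0:2))
  # pairs exceed unique CpGs via multi-mapping
  expect_gt(nrow(co1$mqtl), length(unique(co1$mqtl$cpg_id)))
  expect_false(any(duplicated(co1$mqtl[c("snp_id", "cpg_id")])))
})

test_that("null cohorts show calibrated case/control differences", {
  cfg <- tiny_config(seed = 31, case_effect = 0, age_effect = 0,
                     bmi_effect = 0)
  co <- generate_cohort(cfg)
  b <- co$betas$cervical
  case <- co$phenotypes$case == 1
  pvals <- apply(b, 1, function(row) {
    t.test(row[case], row[!case])$p.value
  })
  # with no planted effects, ~5% of CpGs significant at alpha = 0.05
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("immune mixing moves betas linearly toward the immune profile", {
  snps <- tibble::tibble(snp_id = "rs1", maf = 0.3)
  g <- generate_genotypes(3, snps, seed = 1)
  map <- tibble::tibble(snp_id = "rs1", cpg_id = "cg1", effect = 0)
  prof <- tissue_profile("cervical", "cg1", baseline_logit = 1,
                         immune_baseline_logit = -3, noise_sd = 1e-12)
  fr <- c(0, 0.5, 1)
  phen <- tibble::tibble(subject_id = rownames(g), case = 0, age = 55,
                         bmi = 26, immune_fraction = fr)
  b <- generate_methylation(g, map, phen, prof, seed = 2)["cg1", ]
  expected <- (1 - fr) * plogis(1) + fr * plogis(-3)
  expect_equal(unname(b), expected, tolerance = 1e-9)
})
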