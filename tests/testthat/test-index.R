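# Training, selection, finalization, and scoring of the methylation risk
# index.

make_separable <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    b <- rbind(
      ifelse(y == 1, 0.8, 0.2) + rnorm(n, 0, 0.02),
      ifelse(y == 1, 0.3, 0.7) + rnorm(n, 0, 0.02),
      matrix(runif(3 * n), 3, n)
    )
    list(betas = toy_betas(pmin(pmax(b, 0), 1)), labels = y)
  })
}

test_that("index scoring is exact hand arithmetic", {
  m <- wid_index(c("cg001", "cg002"), c(2, -1), mu = 0.1, sigma = 2)
  b <- toy_betas(matrix(0.5, 2, 1), cpg_ids = c("cg001", "cg002"))
  expect_equal(compute_index(b, m)$score, ((1 - 0.5) - 0.1) / 2)  # 0.2

  ident <- wid_index("cg001", 1)
  b1 <- toy_betas(matrix(c(0.12, 0.93), 1, 2), cpg_ids = "cg001")
  expect_equal(compute_index(b1, ident)$score, c(0.12, 0.93))

  expect_error(compute_index(b1, wid_index("cgX", 1)), "cgX")
  expect_error(wid_index("cg1", 1, sigma = 0), "positive")
})

test_that("separable data trains to perfect in-sample discrimination", {
  d <- make_separable()
  fit <- fit_penalized_classifier(d$betas, d$labels, penalty = "L1",
                                  k_folds = 5, seed = 1)
  scores <- compute_index(d$betas, fit$model)$score
  expect_equal(roc_auc(scores, d$labels)$auc, 1)
  expect_true(fit$report$chosen_lambda %in% fit$report$cv_curve$lambda)
  expect_equal(fit$report$n_nonzero, length(fit$model$cpg_ids))
})

test_that("the L1 shrinkage limit zeroes every weight", {
  d <- make_separable()
  x <- scale(t(d$betas))
  y <- d$labels - mean(d$labels)
  lambda_max <- max(abs(crossprod(x, y))) / length(y)
  fit <- fit_penalized_classifier(d$betas, d$labels, penalty = "L1",
                                  k_folds = 5, seed = 1,
                                  lambda = lambda_max * 1.05)
  expect_length(fit$model$cpg_ids, 0)
  expect_error(
    finalize_index(d$betas, d$labels, lambda = lambda_max * 1.05),
    "no non-zero"
  )
})

test_that("fitting rejects degenerate inputs", {
  d <- make_separable()
  expect_error(fit_penalized_classifier(d$betas, rep(1, ncol(d$betas))),
               "both classes")
  expect_error(fit_penalized_classifier(d$betas, d$labels, k_folds = 1),
               "k_folds")
  expect_error(
    fit_penalized_classifier(d$betas, d$labels,
                             k_folds = ncol(d$betas) + 1),
    "k_folds"
  )
  bad <- d$betas
  bad[1, 1] <- NA
  expect_error(fit_penalized_classifier(bad, d$labels), "missing")
})

test_that("model selection maximizes internal AUC with a sparsity tie-break", {
  withr::with_seed(7, {
    y <- rep(0:1, each = 30)
    b <- toy_betas(rbind(y * 0.5 + runif(60, 0, 0.4),
                         matrix(runif(120), 2, 60)))
  })
  good <- list(model = wid_index(rownames(b)[1], 1, penalty = "L1"),
               report = structure(list(n_nonzero = 1), class = "wid_train_report"))
  noisy <- list(model = wid_index(rownames(b)[2], 1, penalty = "L2"),
                report = structure(list(n_nonzero = 3), class = "wid_train_report"))
  pick <- select_model(list(noisy, good), b, y)
  expect_identical(pick$model$cpg_ids, rownames(b)[1])
  expect_equal(pick$report$internal_validation_auc,
               auc_brute(b[1, ], y))

  # equal AUC (identical scoring weights): sparser candidate wins
  dense <- list(model = wid_index(rownames(b)[1], 1, penalty = "L2"),
                report = structure(list(n_nonzero = 500), class = "wid_train_report"))
  pick2 <- select_model(list(dense, good), b, y)
  expect_equal(pick2$report$n_nonzero, 1)

  one <- select_model(list(good), b, y)
  expect_identical(one$model$cpg_ids, good$model$cpg_ids)
  expect_error(select_model(list(), b, y), "non-empty")
})

test_that("finalized indices score the discovery set to mean 0, SD 1", {
  co <- generate_cohort(tiny_config(seed = 61))
  phen <- co$phenotypes
  disc <- phen$subject_id[phen$set != "validation"]
  b <- co$betas$cervical[co$truth$mqtl_cpgs, disc]
  model <- finalize_index(b, phen$case[match(disc, phen$subject_id)],
                          seed = 8)
  scores <- compute_index(b, model)$score
  expect_lt(abs(mean(scores)), 1e-10)
  expect_lt(abs(sd(scores) - 1), 1e-10)

  # determinism of the refit
  model2 <- finalize_index(b, phen$case[match(disc, phen$subject_id)],
                           seed = 8)
  expect_identical(model$weights, model2$weights)
})

test_that("adding a constant to the raw sum leaves scores unchanged", {
  co <- generate_cohort(tiny_config(seed = 62))
  b <- co$betas$cervical[1:10, 1:50]
  m <- wid_index(rownames(b), rnorm(10, 0, 0.5))
  raw <- drop(crossprod(b[m$cpg_ids, ], m$weights))
  m$mu <- mean(raw)
  m$sigma <- sd(raw)
  base_scores <- compute_index(b, m)$score

  # shift every raw sum by c through a constant pseudo-CpG, refit mu
  b2 <- rbind(b, const = 1)
  m2 <- wid_index(c(m$cpg_ids, "const"), c(m$weights, 3))
  raw2 <- drop(crossprod(b2[m2$cpg_ids, ], m2$weights))
  m2$mu <- mean(raw2)
  m2$sigma <- sd(raw2)
  expect_equal(compute_index(b2, m2)$score, base_scores, tolerance = 1e-12)
})

test_that("permuted labels give chance-level internal validation", {
  co <- generate_cohort(tiny_config(seed = 63, n_train = 200,
                                    n_internal = 100))
  phen <- co$phenotypes
  tr <- phen$set == "discovery-train"
  iv <- phen$set == "discovery-internal-validation"
  b <- co$betas$cervical[co$truth$mqtl_cpgs, ]
  aucs <- vapply(1:20, function(s) {
    y_perm <- withr::with_seed(100 + s, sample(phen$case[tr]))
    fit <- fit_penalized_classifier(b[, tr], y_perm, penalty = "L1",
                                    k_folds = 5, seed = s)
    sc <- compute_index(b[, iv], fit$model)$score
    if (length(unique(sc)) == 1) 0.5 else roc_auc(sc, phen$case[iv])$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("large sparse effects are fully recovered and strongly enriched", {
  # Large effects are planted at mid-range baselines (logit 0), where a
  # logit shift is observable on the beta scale; saturated CpGs would
  # carry no usable signal regardless of the planted effect size.
  for (s in 1:2) {
    snps <- snp_panel(20, seed = s)
    map <- mqtl_map(snps, 40, 4, seed = s)
    g <- generate_genotypes(600, snps, seed = s + 100)
    cpgs <- sort(unique(map$cpg_id))
    phen <- withr::with_seed(s + 200, tibble::tibble(
      subject_id = rownames(g), case = rbinom(600, 1, 0.4),
      age = rnorm(600, 55, 8), bmi = rnorm(600, 26, 4),
      immune_fraction = 0
    ))
    prof <- tissue_profile("cervical", cpgs, 0, -1, noise_sd = 0.3)
    planted <- withr::with_seed(s + 300, sample(cpgs, 5))
    eff <- effect_config(case_effect = setNames(rep(2, 5), planted))
    b <- generate_methylation(g, map, phen, prof, eff, seed = s + 400)
    model <- finalize_index(b, phen$case, seed = 9)
    # every planted CpG is selected...
    expect_true(all(planted %in% model$cpg_ids))
    # ...and selection is far denser in planted CpGs than the base rate
    precision <- mean(model$cpg_ids %in% planted)
    expect_gt(precision, 3 * length(planted) / length(cpgs))
  }
})

test_that("tidy and glance summarize a fitted index", {
  m <- wid_index(c("cg1", "cg2"), c(0.5, -0.2), mu = 1, sigma = 2,
                 penalty = "L1", lambda = 0.01)
  td <- tidy(m)
  expect_named(td, c("cpg_id", "weight"))
  expect_equal(nrow(td), 2)
  gl <- glance(m)
  expect_equal(gl$n_cpgs, 2)
  expect_equal(gl$sigma, 2)
})
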