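# Synthetic cohort generator: genotype-coupled methylation at mQTL CpGs,
# covariate and disease effects on the logit scale, and epithelial/immune
# cell-type mixing. Used to exercise every downstream stage without any
# external download.

#' Build a SNP panel for simulation
#'
#' Each SNP carries a minor/effect allele frequency and a polygenic-score
#' log-odds-ratio weight. REF/ALT alleles are assigned so the panel can be
#' round-tripped through VCF; the ALT allele is the effect allele.
#'
#' @param n_snps Number of SNPs.
#' @param maf_range Range the allele frequencies are drawn from (uniform).
#' @param weight_sd SD of the Normal(0, weight_sd) PRS log-OR weights.
#' @param seed Integer seed.
#' @return Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `maf`, `prs_weight`.
#' @export
snp_panel <- function(n_snps = 50, maf_range = c(0.05, 0.5),
                      weight_sd = 0.1, seed = 1) {
  stopifnot(n_snps >= 0, length(maf_range) == 2,
            all(maf_range >= 0), all(maf_range <= 1))
  withr::with_seed(as.integer(seed), {
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
    tibble(
      snp_id = sprintf("rs%05d", seq_len(n_snps)),
      chrom = sample(1:22, n_snps, replace = TRUE),
      pos = sort(sample.int(1e8, n_snps)),
      ref = ref,
      alt = unname(alt),
      effect_allele = unname(alt),
      maf = runif(n_snps, maf_range[1], maf_range[2]),
      prs_weight = rnorm(n_snps, 0, weight_sd)
    )
  })
}

#' Build an mQTL map (SNP-CpG pairs with per-allele logit effects)
#'
#' Every CpG is driven by one SNP; `n_multi` additional pairs give a second
#' SNP to randomly chosen CpGs, so the number of pairs exceeds the number of
#' unique CpGs (real mQTL catalogues collapse the same way, e.g. 822 pairs
#' over 704 unique CpGs).
#'
#' @param snps SNP panel tibble (needs `snp_id`).
#' @param n_cpgs Number of unique mQTL CpGs.
#' @param n_multi Number of extra SNP-CpG pairs on already-mapped CpGs.
#' @param effect_range Magnitude range of per-allele logit shifts; signs
#'   are random.
#' @param seed Integer seed.
#' @return Tibble with columns `snp_id`, `cpg_id`, `effect`; each
#'   (snp_id, cpg_id) pair unique.
#' @export
mqtl_map <- function(snps, n_cpgs = 120, n_multi = 10,
                     effect_range = c(0.2, 0.8), seed = 1) {
  stopifnot(n_cpgs >= 0, n_multi >= 0)
  if (n_cpgs == 0) {
    return(tibble(snp_id = character(), cpg_id = character(), effect = double()))
  }
  withr::with_seed(as.integer(seed), {
    cpg_id <- sprintf("cg%07d", seq_len(n_cpgs))
    base <- tibble(
      snp_id = sample(snps$snp_id, n_cpgs, replace = TRUE),
      cpg_id = cpg_id
    )
    extra <- tibble(snp_id = character(), cpg_id = character())
    if (n_multi > 0) {
      host <- sample(cpg_id, n_multi, replace = (n_multi > n_cpgs))
      other <- vapply(host, function(cg) {
        used <- base$snp_id[base$cpg_id == cg]
        sample(setdiff(snps$snp_id, used), 1)
      }, character(1))
      extra <- tibble(snp_id = unname(other), cpg_id = host)
    }
    out <- dplyr::bind_rows(base, extra)
    out$effect <- sample(c(-1, 1), nrow(out), replace = TRUE) *
      runif(nrow(out), effect_range[1], effect_range[2])
    out <- dplyr::distinct(out, .data$snp_id, .data$cpg_id, .keep_all = TRUE)
    dplyr::arrange(out, .data$cpg_id, .data$snp_id)
  })
}

#' Tissue profile: per-CpG epithelial and immune baselines plus logit noise
#'
#' @param tissue_name Label, e.g. "breast", "cervical", "buccal", "blood".
#' @param cpg_ids CpG identifiers the profile covers.
#' @param baseline_logit Per-CpG epithelial baseline on the logit scale
#'   (recycled if scalar).
#' @param immune_baseline_logit Per-CpG immune-cell baseline on the logit
#'   scale (recycled if scalar).
#' @param noise_sd Residual SD on the logit scale; must be > 0.
#' @return A `tissue_profile` object.
#' @export
tissue_profile <- function(tissue_name, cpg_ids, baseline_logit,
                           immune_baseline_logit, noise_sd = 0.5) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0) {
    abort("noise_sd must be a single positive number")
  }
  n <- length(cpg_ids)
  baseline_logit <- rep_len(baseline_logit, n)
  immune_baseline_logit <- rep_len(immune_baseline_logit, n)
  structure(
    list(
      tissue_name = tissue_name,
      cpg_ids = as.character(cpg_ids),
      baseline_logit = setNames(baseline_logit, cpg_ids),
      immune_baseline_logit = setNames(immune_baseline_logit, cpg_ids),
      noise_sd = noise_sd
    ),
    class = "tissue_profile"
  )
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("<tissue_profile> %s: %d CpGs, logit noise sd %.3g\n",
              x$tissue_name, length(x$cpg_ids), x$noise_sd))
  invisible(x)
}

#' Sample effect-allele dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, maf), independent across subjects and SNPs.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param snps SNP panel tibble with `snp_id` and `maf`.
#' @param seed Integer seed.
#' @return Numeric matrix, subjects x SNPs, dosages in \{0, 1, 2\}.
#' @export
generate_genotypes <- function(n_subjects, snps, seed = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 0) {
    abort("n_subjects must be a single non-negative number")
  }
  if (any(snps$maf < 0 | snps$maf > 1)) abort("maf must lie in [0, 1]")
  n_subjects <- as.integer(n_subjects)
  ids <- sprintf("S%04d", seq_len(n_subjects))
  g <- withr::with_seed(as.integer(seed), {
    vapply(snps$maf, function(m) rbinom(n_subjects, 2L, m),
           numeric(n_subjects))
  })
  g <- matrix(g, nrow = n_subjects, ncol = nrow(snps),
              dimnames = list(ids, snps$snp_id))
  g
}

#' Per-CpG effect configuration for the methylation generator
#'
#' Named numeric vectors (names = CpG ids); CpGs absent from a vector get
#' effect 0. Units are logits per case, per centred year of age, and per
#' centred BMI unit respectively.
#'
#' @param case_effect,age_effect,bmi_effect Named numeric vectors.
#' @return List of class `effect_config`.
#' @export
effect_config <- function(case_effect = numeric(), age_effect = numeric(),
                          bmi_effect = numeric()) {
  chk <- function(x, nm) {
    if (length(x) > 0 && is.null(names(x))) {
      abort(sprintf("%s must be a named numeric vector (names = cpg_id)", nm))
    }
    x
  }
  structure(
    list(case_effect = chk(case_effect, "case_effect"),
         age_effect = chk(age_effect, "age_effect"),
         bmi_effect = chk(bmi_effect, "bmi_effect")),
    class = "effect_config"
  )
}

effect_vector <- function(cfg_part, cpg_ids) {
  out <- setNames(numeric(length(cpg_ids)), cpg_ids)
  if (length(cfg_part)) {
    hit <- intersect(names(cfg_part), cpg_ids)
    out[hit] <- cfg_part[hit]
  }
  out
}

#' Generate a beta-value methylation matrix for one tissue
#'
#' Per subject j and CpG i the epithelial logit is
#' `baseline + sum(effect * dosage) + case_effect*case + age_effect*age_c +
#' bmi_effect*bmi_c + Normal(0, noise_sd)`; the observed beta mixes the
#' epithelial signal with a fixed immune profile:
#' `beta = (1 - f_j) * logistic(logit) + f_j * logistic(immune_baseline)`,
#' where `f_j` is the subject's immune-cell fraction. Age and BMI are
#' centred within the cohort before effects apply.
#'
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param mqtl Map tibble (`snp_id`, `cpg_id`, `effect`); every referenced
#'   SNP must be a column of `genotypes`.
#' @param phenotypes Tibble with `subject_id`, `case`, `age`, `bmi`,
#'   `immune_fraction` (rows = subjects of `genotypes`).
#' @param tissue A [tissue_profile()].
#' @param effects An [effect_config()].
#' @param seed Integer seed.
#' @return Numeric matrix, CpGs x subjects, values in `[0, 1]`.
#' @export
generate_methylation <- function(genotypes, mqtl, phenotypes, tissue,
                                 effects = effect_config(), seed = 1) {
  check_named_matrix(genotypes, "genotypes")
  missing_snp <- setdiff(mqtl$snp_id, colnames(genotypes))
  if (length(missing_snp)) {
    abort(sprintf("mqtl map references SNPs absent from genotypes: %s",
                  paste(head(missing_snp, 5), collapse = ", ")))
  }
  if (!all(phenotypes$subject_id == rownames(genotypes))) {
    abort("phenotypes$subject_id must match rownames(genotypes) in order")
  }
  cpg_ids <- tissue$cpg_ids
  n_cpg <- length(cpg_ids)
  n_sub <- nrow(genotypes)
  f <- phenotypes$immune_fraction
  if (any(f < 0 | f > 1)) abort("immune_fraction must lie in [0, 1]")
  case <- normalize_labels(phenotypes$case)
  age_c <- phenotypes$age - mean(phenotypes$age)
  bmi_c <- phenotypes$bmi - mean(phenotypes$bmi)

  ce <- effect_vector(effects$case_effect, cpg_ids)
  ae <- effect_vector(effects$age_effect, cpg_ids)
  be <- effect_vector(effects$bmi_effect, cpg_ids)

  # CpGs x subjects epithelial logit
  L <- matrix(tissue$baseline_logit, n_cpg, n_sub,
              dimnames = list(cpg_ids, rownames(genotypes)))
  map <- mqtl[mqtl$cpg_id %in% cpg_ids, , drop = FALSE]
  if (nrow(map) && n_sub > 0) {
    for (k in seq_len(nrow(map))) {
      L[map$cpg_id[k], ] <- L[map$cpg_id[k], ] +
        map$effect[k] * genotypes[, map$snp_id[k]]
    }
  }
  if (n_sub > 0) {
    L <- L + outer(ce, case) + outer(ae, age_c) + outer(be, bmi_c)
    L <- L + withr::with_seed(as.integer(seed),
                              matrix(rnorm(n_cpg * n_sub, 0, tissue$noise_sd),
                                     n_cpg, n_sub))
  }
  imm <- logistic(tissue$immune_baseline_logit)
  eps <- logistic(L)
  # mix columns: beta_ij = (1 - f_j) eps_ij + f_j imm_i
  sweep(eps, 2, 1 - f, "*") + outer(imm, f)
}

#' Default cohort configuration
#'
#' The defaults are the desk-scale study conditions used throughout the
#' test-suite: a 50-SNP panel, 120 unique mQTL CpGs (130 SNP-CpG pairs) plus
#' 880 background CpGs, discovery-train/internal-validation/validation sizes
#' 600/300/300 with one third cases, a 0.15-logit case effect on 30 mQTL
#' CpGs, small age/BMI effects, and a cervical tissue profile with logit
#' noise SD 0.5 and immune fractions ~ Beta(2, 6).
#'
#' @param n_train,n_internal,n_validation Set sizes.
#' @param case_fraction Probability a subject is a case.
#' @param n_snps,maf_range,weight_sd Passed to [snp_panel()].
#' @param n_mqtl_cpgs,n_multi_mqtl,mqtl_effect_range Passed to [mqtl_map()].
#' @param n_background_cpgs CpGs with no SNP coupling (permutation pool).
#' @param n_case_cpgs,case_effect Number of mQTL CpGs carrying the disease
#'   effect and its logit magnitude.
#' @param n_age_cpgs,age_effect,n_bmi_cpgs,bmi_effect Covariate effects
#'   (logits per centred unit) and how many CpGs carry each.
#' @param tissues Character vector naming tissue profiles to simulate; the
#'   first is the primary tissue used by the downstream pipeline.
#' @param noise_sd Named (by tissue) or scalar logit noise SD.
#' @param immune_shape Named list (by tissue) of Beta shape pairs for
#'   immune fractions.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions.
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n_train = 600, n_internal = 300, n_validation = 300,
                          case_fraction = 1 / 3,
                          n_snps = 50, maf_range = c(0.05, 0.5),
                          weight_sd = 0.1,
                          n_mqtl_cpgs = 120, n_multi_mqtl = 10,
                          mqtl_effect_range = c(0.2, 0.8),
                          n_background_cpgs = 880,
                          n_case_cpgs = 30, case_effect = 0.15,
                          n_age_cpgs = 30, age_effect = 0.01,
                          n_bmi_cpgs = 30, bmi_effect = 0.02,
                          tissues = "cervical",
                          noise_sd = c(cervical = 0.5, breast = 0.5,
                                       buccal = 0.6, blood = 0.3),
                          immune_shape = list(cervical = c(2, 6),
                                              breast = c(2, 8),
                                              buccal = c(2, 6),
                                              blood = c(50, 2)),
                          age_mean = 55, age_sd = 8,
                          bmi_mean = 26, bmi_sd = 4,
                          seed = 1) {
  cfg <- as.list(environment())
  if (case_fraction < 0 || case_fraction > 1) {
    abort("case_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a full synthetic cohort bundle
#'
#' Produces genotypes, per-tissue beta matrices, a phenotype table with
#' disjoint discovery-train / discovery-internal-validation / validation
#' set assignments, per-tissue immune fractions, and the complete generating
#' truth. Deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle` list: `genotypes`, `betas` (named list of
#'   CpGs x subjects matrices), `phenotypes`, `immune_fractions`, `snps`,
#'   `mqtl`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- c(config$n_train, config$n_internal, config$n_validation)
  if (any(n < 0)) abort("set sizes must be non-negative")
  n_total <- sum(n)
  seeds <- child_seeds(config$seed, 8 + 2 * length(config$tissues))

  snps <- snp_panel(config$n_snps, config$maf_range, config$weight_sd,
                    seed = seeds[1])
  mqtl <- mqtl_map(snps, config$n_mqtl_cpgs, config$n_multi_mqtl,
                   config$mqtl_effect_range, seed = seeds[2])
  mqtl_cpgs <- sort(unique(mqtl$cpg_id))
  bg_cpgs <- if (config$n_background_cpgs > 0) {
    sprintf("bg%07d", seq_len(config$n_background_cpgs))
  } else character(0)
  cpg_ids <- c(mqtl_cpgs, bg_cpgs)

  genotypes <- generate_genotypes(n_total, snps, seed = seeds[3])

  phenotypes <- withr::with_seed(seeds[4], tibble(
    subject_id = rownames(genotypes),
    case = rbinom(n_total, 1, config$case_fraction),
    age = rnorm(n_total, config$age_mean, config$age_sd),
    bmi = rnorm(n_total, config$bmi_mean, config$bmi_sd),
    set = rep(c("discovery-train", "discovery-internal-validation",
                "validation"), n)
  ))

  pick <- function(k, pool, s) {
    withr::with_seed(s, sample(pool, min(k, length(pool))))
  }
  case_cpgs <- pick(config$n_case_cpgs, mqtl_cpgs, seeds[5])
  age_cpgs <- pick(config$n_age_cpgs, cpg_ids, seeds[6])
  bmi_cpgs <- pick(config$n_bmi_cpgs, cpg_ids, seeds[7])
  effects <- effect_config(
    case_effect = setNames(rep(config$case_effect, length(case_cpgs)), case_cpgs),
    age_effect = setNames(rep(config$age_effect, length(age_cpgs)), age_cpgs),
    bmi_effect = setNames(rep(config$bmi_effect, length(bmi_cpgs)), bmi_cpgs)
  )

  baselines <- withr::with_seed(seeds[8], list(
    epithelial = setNames(rnorm(length(cpg_ids), 0, 1.5), cpg_ids),
    immune = setNames(rnorm(length(cpg_ids), -1, 1.5), cpg_ids)
  ))

  noise_of <- function(tis) {
    ns <- config$noise_sd
    if (length(ns) == 1 && is.null(names(ns))) return(ns)
    if (!tis %in% names(ns)) abort(sprintf("no noise_sd for tissue '%s'", tis))
    ns[[tis]]
  }
  shape_of <- function(tis) {
    sh <- config$immune_shape[[tis]]
    if (is.null(sh)) abort(sprintf("no immune_shape for tissue '%s'", tis))
    sh
  }

  betas <- list()
  imm_fracs <- list()
  profiles <- list()
  for (i in seq_along(config$tissues)) {
    tis <- config$tissues[i]
    sh <- shape_of(tis)
    f <- withr::with_seed(seeds[8 + 2 * i - 1],
                          rbeta(n_total, sh[1], sh[2]))
    prof <- tissue_profile(tis, cpg_ids, baselines$epithelial,
                           baselines$immune, noise_of(tis))
    ph <- phenotypes
    ph$immune_fraction <- f
    betas[[tis]] <- generate_methylation(genotypes, mqtl, ph, prof,
                                         effects, seed = seeds[8 + 2 * i])
    imm_fracs[[tis]] <- tibble(subject_id = ph$subject_id, tissue = tis,
                               immune_fraction = f)
    profiles[[tis]] <- prof
  }
  phenotypes$immune_fraction <- imm_fracs[[config$tissues[1]]]$immune_fraction

  structure(
    list(
      genotypes = genotypes,
      betas = betas,
      phenotypes = phenotypes,
      immune_fractions = dplyr::bind_rows(imm_fracs),
      snps = snps,
      mqtl = mqtl,
      truth = list(config = unclass(config), seeds = seeds,
                   case_cpgs = sort(case_cpgs), age_cpgs = sort(age_cpgs),
                   bmi_cpgs = sort(bmi_cpgs), mqtl_cpgs = mqtl_cpgs,
                   background_cpgs = bg_cpgs, profiles = profiles)
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d subjects, %d SNPs, %d CpGs (%d mQTL), tissues: %s\n",
    nrow(x$genotypes), ncol(x$genotypes),
    nrow(x$betas[[1]]), length(x$truth$mqtl_cpgs),
    paste(names(x$betas), collapse = ", ")
  ))
  print(dplyr::count(x$phenotypes, .data$set, .data$case))
  invisible(x)
}
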