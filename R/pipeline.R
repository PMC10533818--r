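# End-to-end driver: simulate (or load) -> variability -> train/select ->
# finalize -> score -> PRS -> median-split strata -> permutation ->
# evaluation, with a manifest and a single JSON-serializable report.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] used when `simulate = TRUE`.
#' @param simulate Generate a synthetic cohort (`TRUE`) or load inputs
#'   from the paths below.
#' @param beta_tsv,phenotype_csv,genotype_tsv Input paths when
#'   `simulate = FALSE`.
#' @param penalties Candidate penalties compared on internal validation.
#' @param k_folds CV folds.
#' @param n_perm Permutations for the specificity null (0 disables the
#'   stage).
#' @param perm_n_cpgs CpGs per permutation (defaults to the mQTL set
#'   size).
#' @param quantile_cuts Percentile cut points for the OR curve.
#' @param variability_percentile Top-variable percentile summarized.
#' @param immune_bins Immune-fraction bin breaks.
#' @param output_dir Optional directory for artifact files.
#' @param seed Master seed.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), simulate = TRUE,
                            beta_tsv = NULL, phenotype_csv = NULL,
                            genotype_tsv = NULL,
                            penalties = c("L1", "L2"), k_folds = 10,
                            n_perm = 0, perm_n_cpgs = NULL,
                            quantile_cuts = c(25, 50, 75),
                            variability_percentile = 10,
                            immune_bins = c(0, 0.25, 0.75, 1),
                            output_dir = NULL, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' On a synthetic cohort (default) or on loaded beta/genotype/phenotype
#' files: summarizes variability, trains L1 and L2 classifiers on the
#' discovery-train split, selects on internal-validation AUC, finalizes on
#' the whole discovery set with mean-0/SD-1 scaling, scores the validation
#' set, computes the PRS, builds median-split combined risk groups with
#' exact odds ratios per set, optionally runs the permutation null, and
#' evaluates AUC and case-control separation.
#'
#' @param config A [pipeline_config()].
#' @return A `wid_run` list with per-stage results, headline `report`, and
#'   a `manifest` (config hash, seed, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- child_seeds(config$seed, 4)

  if (isTRUE(config$simulate)) {
    cohort <- run_stage("simulate", {
      cc <- config$cohort
      cc$seed <- seeds[1]
      generate_cohort(cc)
    })
    betas <- cohort$betas[[config$cohort$tissues[1]]]
    phen <- cohort$phenotypes
    genotypes <- cohort$genotypes
    weights <- cohort$snps[, c("snp_id", "prs_weight")]
    mqtl_cpgs <- cohort$truth$mqtl_cpgs
  } else {
    cohort <- NULL
    run_stage("load", {
      for (p in c(config$beta_tsv, config$phenotype_csv,
                  config$genotype_tsv)) {
        if (!is.null(p) && !file.exists(p)) {
          abort(sprintf("input file not found: %s", p))
        }
      }
      if (is.null(config$beta_tsv) || is.null(config$phenotype_csv)) {
        abort("beta_tsv and phenotype_csv are required when simulate = FALSE")
      }
    })
    betas <- read_beta_tsv(config$beta_tsv)
    phen <- readr::read_csv(config$phenotype_csv, show_col_types = FALSE)
    genotypes <- if (!is.null(config$genotype_tsv)) {
      read_dosage_tsv(config$genotype_tsv)
    }
    weights <- NULL
    mqtl_cpgs <- rownames(betas)
  }

  sets <- list(
    train = phen$subject_id[phen$set == "discovery-train"],
    internal = phen$subject_id[phen$set == "discovery-internal-validation"],
    validation = phen$subject_id[phen$set == "validation"]
  )
  discovery <- c(sets$train, sets$internal)
  case_of <- setNames(normalize_labels(phen$case), phen$subject_id)
  mqtl_present <- intersect(mqtl_cpgs, rownames(betas))

  variability <- run_stage("variability", {
    vt <- cpg_sd(betas)
    top <- top_variable(vt, config$variability_percentile)
    list(table = vt, top = top)
  })

  selected <- run_stage("train", {
    xb <- betas[mqtl_present, sets$train, drop = FALSE]
    cands <- purrr::map(config$penalties, function(pen) {
      fit_penalized_classifier(xb, case_of[sets$train], penalty = pen,
                               k_folds = config$k_folds, seed = seeds[2])
    })
    select_model(cands, betas[mqtl_present, sets$internal, drop = FALSE],
                 case_of[sets$internal])
  })

  index <- run_stage("finalize", {
    refit <- function(pen) {
      finalize_index(betas[mqtl_present, discovery, drop = FALSE],
                     case_of[discovery], penalty = pen,
                     k_folds = config$k_folds, seed = seeds[3])
    }
    # On signal-free data the lasso CV may pick the intercept-only model,
    # which cannot be scaled; ridge always yields non-zero weights, so it
    # serves as the refit penalty in that degenerate case.
    tryCatch(refit(selected$model$penalty), error = function(e) {
      if (grepl("no non-zero", conditionMessage(e)) &&
          selected$model$penalty == "L1") {
        refit("L2")
      } else {
        stop(e)
      }
    })
  })

  scores <- run_stage("score", {
    s <- compute_index(betas, index)
    s$set <- phen$set[match(s$subject_id, phen$subject_id)]
    s
  })

  prs <- if (is.null(genotypes) || is.null(weights)) NULL else
    run_stage("prs", {
      qc <- qc_filter(genotypes)
      list(scores = compute_prs(qc$genotypes, weights), qc_report = qc$report)
    })

  strata <- if (is.null(prs)) NULL else run_stage("stratify", {
    per_set <- function(ids) {
      ids <- intersect(ids, prs$scores$subject_id)  # QC may drop subjects
      idx <- scores$subject_id %in% ids
      pr <- prs$scores$prs[match(scores$subject_id[idx],
                                 prs$scores$subject_id)]
      grp <- combine_groups(median_split(pr),
                            median_split(scores$score[idx]))
      risk_table(grp, case_of[scores$subject_id[idx]])
    }
    list(discovery = per_set(discovery),
         validation = per_set(sets$validation))
  })

  perm <- if (config$n_perm < 1) NULL else run_stage("permute", {
    permutation_null(
      betas, mqtl_present, case_of[colnames(betas)],
      split = list(train = sets$train, validation = sets$validation),
      n_perm = config$n_perm,
      n_cpgs = config$perm_n_cpgs %||% length(mqtl_present),
      k_folds = config$k_folds, seed = seeds[4]
    )
  })

  evaluation <- run_stage("evaluate", {
    va <- scores$set == "validation"
    auc <- roc_auc(scores$score[va], case_of[scores$subject_id[va]])
    p_t <- group_difference_test(
      scores$score[va][case_of[scores$subject_id[va]] == 1],
      scores$score[va][case_of[scores$subject_id[va]] == 0]
    )
    list(validation_auc = auc, case_control_p = p_t)
  })

  report <- list(
    selected_penalty = index$penalty,
    internal_validation_auc = selected$report$internal_validation_auc,
    n_index_cpgs = length(index$cpg_ids),
    validation_auc = evaluation$validation_auc$auc,
    validation_auc_ci = c(evaluation$validation_auc$ci_low,
                          evaluation$validation_auc$ci_high),
    case_control_p = evaluation$case_control_p,
    risk_table_validation = if (!is.null(strata)) {
      as.data.frame(strata$validation)
    },
    permutation_median_auc = if (!is.null(perm)) perm$median_auc
  )
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mqtlrisk"))
  )

  out <- structure(
    list(cohort = cohort, variability = variability, selected = selected,
         index = index, scores = scores, prs = prs, strata = strata,
         permutation = perm, evaluation = evaluation,
         report = report, manifest = manifest, config = config),
    class = "wid_run"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(c(manifest, report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_index_model(index, file.path(config$output_dir, "index"))
    readr::write_csv(scores, file.path(config$output_dir, "index_scores.csv"))
  }
  out
}

#' @export
print.wid_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<wid_run> %s index with %d CpGs; internal AUC %.3f; validation AUC %.3f\n",
    r$selected_penalty, r$n_index_cpgs, r$internal_validation_auc,
    r$validation_auc
  ))
  if (!is.null(r$permutation_median_auc)) {
    cat(sprintf("  permutation null median AUC %.3f\n",
                r$permutation_median_auc))
  }
  invisible(x)
}

#' Published risk-group counts from the WID-qtBC study
#'
#' Case/control counts for the four combined PRS/index median-split risk
#' groups in the discovery and validation cohorts of the published
#' WID-qtBC breast-cancer analysis, as printed in its risk-stratification
#' table. These counts are inputs for [reproduce_table1()].
#'
#' @return Tibble: `set`, `group`, `cases`, `controls`.
#' @export
table1_counts <- function() {
  tibble(
    set = rep(c("discovery", "validation"), each = 4),
    group = rep(c("low/low", "high/low", "low/high", "high/high"), 2),
    cases = c(16L, 23L, 89L, 184L, 14L, 18L, 24L, 55L),
    controls = c(301L, 221L, 155L, 132L, 70L, 59L, 53L, 28L)
  )
}

#' Recompute the published risk-stratification odds ratios from counts
#'
#' Feeds the printed per-group case/control counts directly into the
#' median-unbiased odds-ratio machinery (each group versus the low/low
#' reference, separately per set).
#'
#' @param counts Tibble with `set`, `group`, `cases`, `controls`;
#'   defaults to [table1_counts()]. The first group per set is the
#'   reference.
#' @return Tibble: `set`, `group`, `cases`, `controls`, `or_hat`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
reproduce_table1 <- function(counts = table1_counts()) {
  need <- c("set", "group", "cases", "controls")
  if (!all(need %in% names(counts))) {
    abort(sprintf("counts must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(counts$cases < 0) || any(counts$controls < 0) ||
      any(counts$cases != round(counts$cases)) ||
      any(counts$controls != round(counts$controls))) {
    abort("cases and controls must be non-negative integers")
  }
  purrr::map_dfr(unique(counts$set), function(s) {
    sub <- counts[counts$set == s, ]
    ref <- sub[1, ]
    stats_tbl <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      if (i == 1) {
        tibble(or_hat = 1, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_)
      } else {
        median_unbiased_or(sub$cases[i], sub$controls[i],
                           ref$cases, ref$controls)
      }
    })
    dplyr::bind_cols(sub, stats_tbl)
  })
}
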