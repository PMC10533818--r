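# Plain-text I/O: beta TSVs, dosage TSVs, minimal VCF, phenotype CSVs,
# model weight tables with JSON sidecars, and YAML pipeline configs.

#' Write / read a beta matrix as TSV
#'
#' Rows are CpGs (first column `cpg_id`), columns are sample ids.
#'
#' @param betas CpGs x samples matrix.
#' @param path File path.
#' @return `read_beta_tsv()` returns the matrix; `write_beta_tsv()` its
#'   path, invisibly.
#' @export
write_beta_tsv <- function(betas, path) {
  check_named_matrix(betas, "betas")
  df <- dplyr::bind_cols(tibble(cpg_id = rownames(betas)),
                         as_tibble(betas))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Rows are subjects (first column `subject_id`), columns are SNP ids;
#' missing calls are empty cells.
#'
#' @param genotypes Subjects x SNPs matrix.
#' @param path File path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  check_named_matrix(genotypes, "genotypes")
  df <- dplyr::bind_cols(tibble(subject_id = rownames(genotypes)),
                         as_tibble(genotypes))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write genotypes as a minimal VCF
#'
#' One biallelic record per SNP with GT genotypes (`0/0`, `0/1`, `1/1`,
#' `./.`); the ALT allele is the effect allele, so GT allele counts equal
#' effect-allele dosages.
#'
#' @param genotypes Subjects x SNPs dosage matrix (`NA` = missing).
#' @param snps Tibble with `snp_id`, `chrom`, `pos`, `ref`, `alt` covering
#'   every column of `genotypes`.
#' @param path File path.
#' @export
write_vcf <- function(genotypes, snps, path) {
  check_named_matrix(genotypes, "genotypes")
  info <- snps[match(colnames(genotypes), snps$snp_id), ]
  if (anyNA(info$snp_id)) abort("snps must describe every genotype column")
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    paste(c(info$chrom[j], info$pos[j], info$snp_id[j], info$ref[j],
            info$alt[j], ".", "PASS", ".", "GT",
            gt_code(genotypes[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' GT genotypes are converted to ALT-allele counts; with `field = "DS"`
#' dosages are read directly and rounded to \{0, 1, 2\}.
#'
#' @param path VCF path.
#' @param field "GT" (default) or "DS".
#' @return List with `genotypes` (subjects x SNPs matrix, `NA` = missing)
#'   and `variants` (tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_vcf_dosages <- function(path, field = c("GT", "DS")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  variants <- tibble(
    snp_id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
    pos = vcfR::getPOS(v), ref = vcfR::getREF(v), alt = vcfR::getALT(v)
  )
  raw <- vcfR::extract.gt(v, element = field)
  if (field == "GT") {
    dos <- apply(raw, 2, function(g) {
      g <- gsub("|", "/", g, fixed = TRUE)
      out <- rep(NA_real_, length(g))
      known <- !is.na(g) & !grepl("\\.", g)
      out[known] <- vapply(strsplit(g[known], "/"), function(al) {
        sum(al != "0")
      }, numeric(1))
      out
    })
  } else {
    dos <- apply(raw, 2, function(g) round(as.numeric(g)))
  }
  dos <- matrix(dos, nrow = nrow(variants),
                dimnames = list(variants$snp_id, colnames(raw)))
  list(genotypes = t(dos), variants = variants)
}

comp_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Harmonize PRS weights against VCF variant alleles
#'
#' Aligns a weight table (`snp_id`, `effect_allele`, `other_allele`,
#' `weight`) to VCF REF/ALT coding. If the effect allele matches ALT the
#' weight is kept; if it matches REF the weight sign is flipped (dosage of
#' ALT counts the non-effect allele); strand flips (allele complements)
#' are resolved the same way. Ambiguous A/T and C/G SNPs are used as-is
#' with a warning; SNPs whose alleles cannot be reconciled are dropped.
#'
#' @param variants Tibble from [read_vcf_dosages()] (`snp_id`, `ref`,
#'   `alt`).
#' @param weights Tibble with `snp_id`, `effect_allele`, `other_allele`,
#'   `weight`.
#' @return Tibble `snp_id`, `weight` (aligned to ALT dosages), `action`
#'   (kept / sign_flipped / strand_flipped / strand_flipped_sign /
#'   dropped).
#' @export
harmonize_weights <- function(variants, weights) {
  need <- c("snp_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(weights))) {
    abort(sprintf("weights must have columns: %s", paste(need, collapse = ", ")))
  }
  merged <- dplyr::inner_join(weights, variants, by = "snp_id")
  ambiguous <- merged$effect_allele == comp_allele(merged$other_allele)
  if (any(ambiguous)) {
    warn(sprintf("%d ambiguous A/T or C/G SNP(s) used as-is: %s",
                 sum(ambiguous),
                 paste(head(merged$snp_id[ambiguous], 5), collapse = ", ")))
  }
  action <- dplyr::case_when(
    merged$effect_allele == merged$alt & merged$other_allele == merged$ref ~
      "kept",
    merged$effect_allele == merged$ref & merged$other_allele == merged$alt ~
      "sign_flipped",
    comp_allele(merged$effect_allele) == merged$alt &
      comp_allele(merged$other_allele) == merged$ref ~ "strand_flipped",
    comp_allele(merged$effect_allele) == merged$ref &
      comp_allele(merged$other_allele) == merged$alt ~ "strand_flipped_sign",
    TRUE ~ "dropped"
  )
  if (any(action == "dropped")) {
    warn(sprintf("%d SNP(s) dropped: alleles irreconcilable with VCF",
                 sum(action == "dropped")))
  }
  out <- tibble(
    snp_id = merged$snp_id,
    weight = ifelse(action %in% c("sign_flipped", "strand_flipped_sign"),
                    -merged$weight, merged$weight),
    action = action
  )
  out[out$action != "dropped", ]
}

#' Serialize / load a risk-index model
#'
#' Writes a TSV of (cpg_id, weight) plus a JSON sidecar holding the
#' scaling constants and fitting metadata.
#'
#' @param model A [wid_index()].
#' @param prefix Path prefix; writes `<prefix>_weights.tsv` and
#'   `<prefix>_model.json`.
#' @export
write_index_model <- function(model, prefix) {
  stopifnot(inherits(model, "wid_index"))
  readr::write_tsv(tidy(model), paste0(prefix, "_weights.tsv"))
  jsonlite::write_json(
    list(mu = model$mu, sigma = model$sigma, intercept = model$intercept,
         penalty = model$penalty, lambda = model$lambda),
    paste0(prefix, "_model.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(prefix) {
  w <- readr::read_tsv(paste0(prefix, "_weights.tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"),
                              simplifyVector = TRUE)
  wid_index(w$cpg_id, w$weight, mu = meta$mu, sigma = meta$sigma,
            intercept = meta$intercept, penalty = meta$penalty,
            lambda = meta$lambda)
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Beta TSVs per tissue, genotypes as dosage TSV and minimal VCF,
#' phenotypes and immune fractions as CSV, SNP panel and mQTL map as TSV,
#' and generating truth as JSON.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in names(cohort$betas)) {
    write_beta_tsv(cohort$betas[[tis]],
                   file.path(dir, sprintf("betas_%s.tsv", tis)))
  }
  write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_vcf(cohort$genotypes, cohort$snps, file.path(dir, "genotypes.vcf"))
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_csv(cohort$immune_fractions,
                   file.path(dir, "immune_fractions.csv"))
  readr::write_tsv(cohort$snps, file.path(dir, "snp_panel.tsv"))
  readr::write_tsv(cohort$mqtl, file.path(dir, "mqtl_map.tsv"))
  truth <- cohort$truth
  truth$profiles <- NULL  # baselines are large; regenerable from seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Recursively check that every key in `cfg` exists in `defaults`.
check_config_keys <- function(cfg, defaults, path = character()) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s",
                  paste(c(path, unknown[1]), collapse = "$")))
  }
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      check_config_keys(cfg[[k]], defaults[[k]], c(path, k))
    }
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override [pipeline_config()] defaults; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  check_config_keys(raw, defaults)
  cohort_over <- raw$cohort
  raw$cohort <- NULL
  cfg <- utils::modifyList(unclass(defaults), raw)
  if (!is.null(cohort_over)) {
    check_config_keys(cohort_over, unclass(cohort_config()))
    cfg$cohort <- do.call(
      cohort_config,
      utils::modifyList(as.list(unclass(cfg$cohort)), cohort_over)
    )
  }
  structure(cfg, class = "pipeline_config")
}
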