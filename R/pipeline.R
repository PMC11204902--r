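## End-to-end orchestration: QC -> harmonize -> score -> PCA/TW ->
## association -> report, for a set of scoring files against one panel.

#' Default pipeline configuration
#'
#' @param panel,phenotypes,scores,ld input paths (\code{scores} is a
#'   character vector of scoring files; \code{ld} an optional LD TSV).
#' @param out_dir output directory.
#' @param ... overrides for nested options, e.g.
#'   \code{qc = list(hwe_alpha = 1e-5)}.
#' @return configuration list understood by \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(panel, phenotypes, scores, ld = NULL,
                           out_dir = tempdir(), ...) {
  cfg <- list(
    paths = list(panel = panel, phenotypes = phenotypes,
                 scores = scores, ld = ld, out_dir = out_dir),
    qc = list(sample_call_rate = 0.95, het_sd = 3,
              hwe_alpha = 1e-4, variant_call_rate = 0.98),
    harmonize = list(r2_min = 0.8, proxy_window_kb = 500,
                     palindromic_policy = "drop"),
    pca = list(k_max = 15, tw_alpha = 0.05, pc_policy = "tw", k_cap = 15),
    association = list(models = c("model1", "model2"),
                       or_scale = "per_sd", bonferroni_alpha = 0.05),
    seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the \code{\link{pipelineConfig}} structure.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig,
          c(cfg$paths, cfg[setdiff(names(cfg), "paths")]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full replication pipeline
#'
#' Stages, in fixed order: read inputs (data_io), sample and variant QC,
#' PCA with Tracy-Widom PC selection, then per scoring file harmonization,
#' scoring and nested-model association, Bonferroni adjustment within each
#' model family, and report writing. All intermediate artifacts (QC report,
#' harmonization audits, per-sample scores, PC coordinates) and a JSON run
#' log with counts at every stage are written under \code{out_dir}.
#'
#' @param config list from \code{\link{pipelineConfig}} /
#'   \code{\link{readRunConfig}}.
#' @return invisibly, a list with \code{results} (per model, lists of
#'   \linkS4class{AssociationResult}), \code{reports} (paths) and
#'   \code{log}.
#' @export
runPipeline <- function(config) {
  out <- config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, thresholds = config[c("qc", "harmonize",
                                                        "pca",
                                                        "association")])

  panel <- stage("data_io", {
    if (!file.exists(config$paths$panel %||% ""))
      stop("panel path missing: ", config$paths$panel)
    readGenotypesVcf(config$paths$panel)
  })
  pheno <- stage("data_io", readPhenotypes(config$paths$phenotypes, panel))
  scoresets <- stage("data_io",
                     lapply(config$paths$scores, readScoreFile))
  ld_ref <- stage("data_io", {
    if (is.null(config$paths$ld)) NULL else
      readLDReference(config$paths$ld,
                      window = config$harmonize$proxy_window_kb * 1000)
  })
  log$input <- list(n_samples = nSamples(panel),
                    n_variants = nVariants(panel),
                    n_scores = length(scoresets))

  qc1 <- stage("qc", sampleQC(panel,
                              call_rate_min = config$qc$sample_call_rate,
                              k_sd = config$qc$het_sd))
  qc2 <- stage("qc", variantQC(qc1$panel,
                               hwe_alpha = config$qc$hwe_alpha,
                               call_rate_min = config$qc$variant_call_rate))
  panel <- qc2$panel
  writeQCReport(qc1$report, file.path(out, "qc_samples.tsv"))
  writeQCReport(qc2$report, file.path(out, "qc_variants.tsv"))
  log$qc <- list(samples_removed = nrow(samplesRemoved(qc1$report)),
                 variants_removed = nrow(variantsRemoved(qc2$report)),
                 n_samples = nSamples(panel), n_variants = nVariants(panel))

  pcs <- stage("structure_pca", {
    x <- normalizeGenotypes(panel)
    computePCs(x, k_max = config$pca$k_max, alpha = config$pca$tw_alpha,
               k_cap = config$pca$k_cap)
  })
  n_pcs <- if (identical(config$pca$pc_policy, "fixed15"))
    min(15L, ncol(pcCoords(pcs))) else nSignificant(pcs)
  writePCReport(pcs, file.path(out, "pc_coords.tsv"),
                file.path(out, "pc_eigen.tsv"))
  log$pca <- list(tw_selected = nSignificant(pcs), n_pcs_used = n_pcs)

  results <- list()
  log$harmonization <- list()
  for (ss in scoresets) {
    id <- pgsId(ss)
    harm <- stage("harmonize",
      harmonizeScoreSet(ss, panel, ld_ref = ld_ref,
                        r2_min = config$harmonize$r2_min,
                        palindromic_policy =
                          config$harmonize$palindromic_policy))
    writeAudit(harm, file.path(out, paste0("audit_", id, ".tsv")))
    acts <- table(auditTable(harm)$action)
    log$harmonization[[id]] <- as.list(acts)
    prs <- stage("scoring", standardizePRS(computePRS(harm, panel)))
    writePRS(prs, file.path(out, paste0("prs_", id, ".tsv")))
    for (mod in config$association$models) {
      res <- stage("association",
        suppressMessages(
          evaluatePRS(prs, pheno, pcs, model = mod, n_pcs = n_pcs,
                      or_scale = config$association$or_scale)))
      results[[mod]] <- c(results[[mod]], res)
    }
  }

  reports <- character(0)
  for (mod in names(results)) {
    results[[mod]] <- stage("association",
      flagBonferroni(results[[mod]],
                     alpha = config$association$bonferroni_alpha))
    fp <- file.path(out, paste0("report_", mod, ".tsv"))
    rp <- file.path(out, paste0("report_", mod, "_raw.tsv"))
    writeReport(results[[mod]], fp, style = "formatted")
    writeReport(results[[mod]], rp, style = "raw")
    reports <- c(reports, fp, rp)
  }
  log$package_version <- as.character(utils::packageVersion("prscad"))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, reports = reports, log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete cohort on disk
#'
#' Convenience wrapper: simulates a panel and phenotypes, emits one or more
#' (optionally corrupted) scoring files, and writes VCF, phenotype TSV,
#' score TSVs, LD TSV and a truth-ledger JSON under \code{out_dir}. The
#' whole output is reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param out_dir output directory.
#' @param n_scores number of scoring files to emit (default 1). The first
#'   score is the phenotype-linked causal score; any further scores are
#'   independent null scores with their own causal draws.
#' @param corruption corruption fractions passed to
#'   \code{\link{emitScoreFile}}.
#' @return invisibly, list of written paths.
#' @export
simulateCohort <- function(config, out_dir, n_scores = 1,
                           corruption = c(allele_switch = 0,
                                          strand_flip = 0,
                                          drop_with_proxy = 0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePanel(config)
  pheno <- simulatePhenotypes(sim$panel, sim$truth, config)
  panel <- sim$panel
  truth <- sim$truth
  score_paths <- character(n_scores)
  ld_tab <- NULL
  for (k in seq_len(n_scores)) {
    score_paths[k] <- file.path(out_dir, sprintf("score_%02d.tsv", k))
    truth_k <- truth
    if (k > 1)
      truth_k$causal <- drawNullScore(panel, nrow(truth$causal),
                                      seed = config$seed + 1000L * k)
    em <- emitScoreFile(truth_k, panel, corruption = corruption,
                        path = score_paths[k],
                        pgsId = sprintf("PGS_SYNTH_%02d", k),
                        seed = config$seed + k)
    panel <- em$panel
    truth$proxy_pairs <- em$truth$proxy_pairs
    truth$corruption <- em$truth$corruption
  }
  ld_tab <- data.frame(key_a = truth$proxy_pairs$dropped_key,
                       key_b = truth$proxy_pairs$proxy_key,
                       r2 = truth$proxy_pairs$r2)
  vcf <- file.path(out_dir, "panel.vcf")
  writeGenotypesVcf(panel, vcf)
  ph <- file.path(out_dir, "phenotypes.tsv")
  write.table(pheno, ph, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- NULL
  if (!is.null(ld_tab) && nrow(ld_tab)) {
    ld <- file.path(out_dir, "ld.tsv")
    write.table(ld_tab, ld, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(causal = truth$causal, per_sd_or = truth$per_sd_or,
         proxy_pairs = truth$proxy_pairs, corruption = truth$corruption),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf, phenotypes = ph, scores = score_paths, ld = ld,
                 truth = truth))
}
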