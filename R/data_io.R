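## Readers/writers: PGS-Catalog-style scoring files, VCF dosage panels,
## phenotype tables, and the result report.

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-separated file; lines starting with \code{#} are header metadata
#' (a \code{#pgs_id=...} line, when present, names the score). Recognised
#' columns: \code{rsID}, \code{chr_name}, \code{chr_position},
#' \code{effect_allele}, \code{other_allele}, \code{effect_weight}.
#' \code{effect_allele} and \code{effect_weight} are mandatory.
#'
#' @param path file path.
#' @param pgsId override for the score id (default: from header, else the
#'   file name).
#' @return a \linkS4class{ScoreSet} with variants in file order.
#' @export
readScoreFile <- function(path, pgsId = NULL) {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- lines[hdr]
  if (is.null(pgsId)) {
    m <- regmatches(meta, regexpr("pgs_id=\\S+", meta))
    pgsId <- if (length(m)) sub("pgs_id=", "", m[[1]][1]) else
      sub("\\.[^.]*$", "", basename(path))
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(body)]
  if (!length(body)) stop("scoring file has no data rows: ", path)
  con <- textConnection(body)
  on.exit(close(con))
  tab <- read.delim(con, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("effect_allele", "effect_weight") %in% names(tab)))
    stop("scoring file lacks mandatory columns effect_allele/effect_weight: ",
         path)
  w <- suppressWarnings(as.numeric(tab$effect_weight))
  if (anyNA(w)) {
    # report the first offending line, 1-based over data rows (excl. header)
    bad <- which(is.na(w))[1]
    stop("non-numeric effect_weight at data row ", bad, " of ", path)
  }
  n <- nrow(tab)
  getcol <- function(nm, default) if (nm %in% names(tab)) tab[[nm]] else
    rep(default, n)
  other <- getcol("other_allele", NA_character_)
  other[!is.na(other) & !nzchar(other)] <- NA_character_
  pos <- suppressWarnings(as.integer(getcol("chr_position", NA_character_)))
  ids <- getcol("rsID", NA_character_)
  if (anyNA(ids) || !all(nzchar(ids)))
    ids <- ifelse(is.na(ids) | !nzchar(ids),
                  paste0("var", seq_len(n)), ids)
  ScoreSet(pgsId, data.frame(
    variant_id = ids,
    chrom = as.character(getcol("chr_name", NA_character_)),
    pos = pos,
    effect_allele = toupper(tab$effect_allele),
    other_allele = toupper(other),
    weight = w,
    stringsAsFactors = FALSE))
}

#' Write a ScoreSet as a PGS-Catalog-style scoring file
#'
#' @param scoreset a \linkS4class{ScoreSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeScoreFile <- function(scoreset, path) {
  v <- scoreVariants(scoreset)
  out <- data.frame(rsID = v$variant_id, chr_name = v$chrom,
                    chr_position = v$pos, effect_allele = v$effect_allele,
                    other_allele = ifelse(is.na(v$other_allele), "",
                                          v$other_allele),
                    effect_weight = format(v$weight, digits = 17,
                                           scientific = FALSE, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#format=prscad-scoring-file",
               paste0("#pgs_id=", pgsId(scoreset))), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Biallelic SNP records only; multiallelic or non-SNP records are skipped
#' with a warning. Dosage comes from the \code{DS} FORMAT field when
#' present, else from the \code{GT} allele count; \code{./.} is missing.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a \linkS4class{GenotypePanel} (samples x variants).
#' @export
readGenotypesVcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2) stop("VCF has no sample columns: ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ok <- vcfR::is.biallelic(vcf) &
    fix$REF %in% VALID_BASES & fix$ALT %in% VALID_BASES
  if (any(!ok))
    warning(sum(!ok), " multiallelic/non-SNP records skipped")
  if (!any(ok)) stop("no usable biallelic SNP records in ", path)
  vcf <- vcf[ok, ]
  fix <- fix[ok, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ds <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
  gtd <- gt_to_dosage(gt)
  dos <- ifelse(!is.na(ds), ds, gtd)
  dos <- t(dos)  # vcfR is variants x samples
  vm <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   id = ifelse(is.na(fix$ID) | fix$ID == ".",
                               variantKey(fix$CHROM, fix$POS), fix$ID),
                   stringsAsFactors = FALSE)
  GenotypePanel(dos, vm)
}

## "0/1", "1|1", "./." etc. -> ALT allele count or NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || !length(al)) return(NA_real_)
    sum(al != "0")
  }, numeric(1))
  out <- lut[match(gt, u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a GenotypePanel as VCF (GT:DS)
#'
#' Emits a minimal VCF 4.2 with hard-called \code{GT} (rounded dosage) and
#' the real-valued \code{DS} dosage; missing cells become \code{./.:.}.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGenotypesVcf <- function(panel, path) {
  vm <- variantMeta(panel)
  d <- dosage(panel)
  hc <- round(d)
  gtcode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(panel)), collapse = "\t")), con)
  for (j in seq_len(nrow(vm))) {
    cells <- ifelse(is.na(d[, j]), "./.:.",
                    paste0(gtcode[hc[, j] + 1], ":",
                           format(d[, j], digits = 10, trim = TRUE)))
    writeLines(paste(c(vm$chrom[j], vm$pos[j], vm$id[j], vm$ref[j],
                       vm$alt[j], ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

PHENO_COLS <- c("sample_id", "case_status", "sex", "age", "weight", "t2dm",
                "smoking", "sbp", "total_chol")

#' Read a phenotype/covariate table
#'
#' Expects a delimited table (TSV or CSV, sniffed from the header line) with
#' columns \code{sample_id}, \code{case_status} (1 = case), \code{sex}
#' (1 = male), \code{age} (years), \code{weight} (kg), \code{t2dm},
#' \code{smoking} (0/1), \code{sbp} (mmHg), \code{total_chol} (mg/dl).
#' Unknown columns are dropped with a warning.
#'
#' @param path file path.
#' @param panel optional \linkS4class{GenotypePanel}; phenotype samples
#'   absent from the panel are reported with a warning.
#' @return \code{data.frame} in file order.
#' @export
readPhenotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("phenotype table not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PHENO_COLS, names(tab))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), PHENO_COLS)
  if (length(extra)) {
    warning("ignoring unknown phenotype columns: ",
            paste(extra, collapse = ", "))
    tab <- tab[PHENO_COLS]
  }
  tab$sample_id <- as.character(tab$sample_id)
  validatePhenotypes(tab)
  if (!is.null(panel)) {
    absent <- setdiff(tab$sample_id, sampleIds(panel))
    if (length(absent))
      warning(length(absent), " phenotype samples absent from panel: ",
              paste(head(absent, 5), collapse = ", "))
  }
  tab
}

validatePhenotypes <- function(tab) {
  if (!all(tab$case_status %in% c(0, 1)))
    stop("case_status outside {0,1}")
  if (any(!is.na(tab$age) & tab$age <= 0)) stop("age must be positive")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_ids")
  invisible(tab)
}

#' Write the association report
#'
#' One row per evaluated score. The \code{"formatted"} style mirrors the
#' conventional replication-table layout: R-squared values as percentages to
#' one decimal, odds ratios to three decimals, p-values in scientific
#' notation. The \code{"raw"} style writes full-precision numeric columns.
#'
#' @param results list of \linkS4class{AssociationResult}.
#' @param path output TSV path.
#' @param style \code{"formatted"} or \code{"raw"}.
#' @return invisibly, the path.
#' @export
writeReport <- function(results, path, style = c("formatted", "raw")) {
  style <- match.arg(style)
  if (!length(results)) stop("no results to report")
  raw <- do.call(rbind, lapply(results, as.data.frame))
  if (style == "raw") {
    write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  out <- data.frame(
    ID = raw$pgs_id,
    model = raw$model,
    R2 = pct(raw$r2_full),
    R2_null = pct(raw$r2_null),
    Adjusted_PRS_R2 = pct(raw$adjusted_prs_r2),
    PRS_OR = sprintf("%.3f", ifelse(raw$or_scale == "per_sd",
                                    raw$or_per_sd, raw$or_raw)),
    p_value = sprintf("%.2e", raw$p_value),
    bonferroni_significant = raw$bonferroni_significant,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
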