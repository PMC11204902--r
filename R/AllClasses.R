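#' @import methods
#' @importFrom stats sd var rbinom rnorm runif rbeta binomial coef glm.fit
#'   plogis qgamma pgamma pnorm qnorm uniroot setNames cor complete.cases
#' @importFrom utils read.delim write.table head
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' ScoreSet: a published polygenic score
#'
#' Holds the variants and per-effect-allele weights of one published
#' polygenic score, as distributed in PGS-Catalog-style scoring files.
#'
#' @slot pgsId Accession or label of the score (e.g. \code{"PGS000747"}).
#' @slot variants \code{data.frame} with columns \code{variant_id},
#'   \code{chrom}, \code{pos} (1-based), \code{effect_allele},
#'   \code{other_allele} (may be \code{NA}), \code{weight} (per-effect-allele
#'   log-odds weight).
#' @name ScoreSet-class
#' @aliases ScoreSet-class
#' @exportClass ScoreSet
setClass("ScoreSet",
  representation(pgsId = "character", variants = "data.frame"))

setValidity("ScoreSet", function(object) {
  v <- object@variants
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "weight")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) == 0) return(TRUE)
  if (anyDuplicated(v$variant_id)) return("variant_ids must be unique")
  if (!all(is.finite(v$weight))) return("weights must be finite")
  if (any(!is.na(v$pos) & v$pos < 1)) return("positions must be >= 1")
  both <- !is.na(v$other_allele)
  if (any(v$effect_allele[both] == v$other_allele[both]))
    return("effect_allele must differ from other_allele")
  TRUE
})

#' GenotypePanel: samples-by-variants dosage matrix
#'
#' ALT-allele dosages in [0, 2] for a set of samples at biallelic SNPs,
#' with a missingness mask and per-variant metadata. Missing cells hold
#' \code{NA} in the dosage matrix and \code{TRUE} in the mask.
#'
#' @slot dosage numeric matrix, samples in rows, variants in columns;
#'   dimnames are sample ids and variant keys (\code{"chrom:pos"}).
#' @slot missing logical matrix of the same shape.
#' @slot variantMeta \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{id}, one row per dosage column.
#' @name GenotypePanel-class
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(dosage = "matrix", missing = "matrix",
                 variantMeta = "data.frame"))

setValidity("GenotypePanel", function(object) {
  d <- object@dosage; m <- object@missing; vm <- object@variantMeta
  if (!all(dim(d) == dim(m))) return("dosage and missing shapes differ")
  if (nrow(vm) != ncol(d)) return("variantMeta rows must match dosage columns")
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(vm)))
    return(paste("variantMeta must have columns:", paste(need, collapse = ", ")))
  if (nrow(vm) > 0 && any(vm$ref == vm$alt)) return("ref must differ from alt")
  obs <- d[!m]
  if (length(obs) && (anyNA(obs) || any(obs < 0 | obs > 2)))
    return("observed dosages must lie in [0, 2]")
  if (is.null(rownames(d))) return("dosage must carry sample ids as rownames")
  if (anyDuplicated(rownames(d))) return("duplicate sample ids")
  TRUE
})

#' HarmonizedScore: a score aligned to a panel
#'
#' Result of harmonizing a \linkS4class{ScoreSet} against a
#' \linkS4class{GenotypePanel}: one audit row per source variant recording
#' the action taken (exact / switched / flipped / flipped_switched /
#' proxied / ambiguous_dropped / dropped), the resolved panel variant, the
#' panel-oriented (ALT-dosage) weight, and the proxy r-squared when a proxy
#' was substituted.
#'
#' @slot pgsId score accession.
#' @slot entries \code{data.frame} with columns \code{variant_id},
#'   \code{action}, \code{panel_key}, \code{aligned_weight}, \code{proxy_r2},
#'   \code{reason}.
#' @name HarmonizedScore-class
#' @aliases HarmonizedScore-class
#' @exportClass HarmonizedScore
setClass("HarmonizedScore",
  representation(pgsId = "character", entries = "data.frame"))

USED_ACTIONS <- c("exact", "switched", "flipped", "flipped_switched",
                  "proxied")
ALL_ACTIONS <- c(USED_ACTIONS, "ambiguous_dropped", "dropped")

setValidity("HarmonizedScore", function(object) {
  e <- object@entries
  need <- c("variant_id", "action", "panel_key", "aligned_weight", "proxy_r2",
            "reason")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(e$action %in% ALL_ACTIONS)) return("unknown action")
  used <- e$action %in% USED_ACTIONS
  if (any(is.na(e$aligned_weight[used])))
    return("used entries must carry an aligned weight")
  if (any(!is.na(e$aligned_weight[!used])))
    return("dropped entries must not carry a weight")
  if (any(is.na(e$proxy_r2[e$action == "proxied"])))
    return("proxied entries must carry proxy_r2")
  if (any(!is.na(e$proxy_r2[e$action != "proxied"])))
    return("proxy_r2 only valid for proxied entries")
  if (anyDuplicated(e$panel_key[used]))
    return("used entries must resolve to distinct panel variants")
  TRUE
})

#' PRSVector: per-sample polygenic score values
#'
#' @slot pgsId score accession.
#' @slot values named numeric vector of raw scores (log-odds units).
#' @slot zscores named numeric vector, z-scored values (empty until
#'   \code{\link{standardizePRS}} is applied).
#' @slot nVariantsUsed number of panel variants contributing.
#' @slot missingPolicy one of \code{"mean"}, \code{"zero"},
#'   \code{"drop-variant"}.
#' @name PRSVector-class
#' @aliases PRSVector-class
#' @exportClass PRSVector
setClass("PRSVector",
  representation(pgsId = "character", values = "numeric",
                 zscores = "numeric", nVariantsUsed = "integer",
                 missingPolicy = "character"))

setValidity("PRSVector", function(object) {
  if (!all(is.finite(object@values))) return("scores must be finite")
  if (is.null(names(object@values))) return("values must be named by sample")
  if (length(object@zscores) &&
      length(object@zscores) != length(object@values))
    return("zscores length mismatch")
  TRUE
})

#' PCResult: genotype PCA with Tracy-Widom selection
#'
#' @slot eigenvalues all nonzero eigenvalues of the sample covariance of the
#'   normalized genotype matrix, descending.
#' @slot coords samples x k matrix of PC coordinates
#'   (eigenvector times sqrt(eigenvalue)).
#' @slot twStats Tracy-Widom statistics for the leading eigenvalues tested.
#' @slot nSignificant number of PCs significant at \code{alpha}, capped.
#' @slot alpha test level used.
#' @name PCResult-class
#' @aliases PCResult-class
#' @exportClass PCResult
setClass("PCResult",
  representation(eigenvalues = "numeric", coords = "matrix",
                 twStats = "numeric", nSignificant = "integer",
                 alpha = "numeric"))

setValidity("PCResult", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev))) return("eigenvalues must be descending")
  if (any(ev < -1e-8)) return("eigenvalues must be nonnegative")
  if (object@nSignificant > ncol(object@coords))
    return("nSignificant exceeds retained PCs")
  TRUE
})

#' AssociationResult: one score's incremental contribution to disease risk
#'
#' Nested-logistic evaluation of one polygenic score under one covariate
#' model: Nagelkerke pseudo-R-squared of the null (covariates + PCs) and
#' full (+ PRS) models, their difference (the adjusted PRS R-squared), and
#' the PRS odds ratio with Wald 95\% CI and p-value, on both the raw-score
#' and per-SD scales.
#'
#' @slot pgsId score accession.
#' @slot model \code{"model1"} or \code{"model2"}.
#' @slot r2Null,r2Full Nagelkerke R-squared of null and full model.
#' @slot adjustedPrsR2 \code{r2Full - r2Null}.
#' @slot orRaw,orPerSd odds ratio per raw score unit / per score SD.
#' @slot ciLow,ciHigh Wald 95\% CI on the headline (\code{orScale}) scale.
#' @slot pValue Wald p-value of the PRS term.
#' @slot orScale headline OR scale, \code{"per_sd"} or \code{"raw"}.
#' @slot bonferroniSignificant logical; \code{NA} until adjusted.
#' @slot converged both fits converged.
#' @slot n samples analysed.
#' @name AssociationResult-class
#' @aliases AssociationResult-class
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(pgsId = "character", model = "character",
                 r2Null = "numeric", r2Full = "numeric",
                 adjustedPrsR2 = "numeric",
                 orRaw = "numeric", orPerSd = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 pValue = "numeric", orScale = "character",
                 bonferroniSignificant = "logical",
                 converged = "logical", n = "integer"))

setValidity("AssociationResult", function(object) {
  if (!object@orScale %in% c("per_sd", "raw")) return("bad orScale")
  if (!object@model %in% c("model1", "model2")) return("bad model name")
  hl <- if (object@orScale == "per_sd") object@orPerSd else object@orRaw
  if (object@converged && !(object@ciLow <= hl && hl <= object@ciHigh))
    return("CI must bracket the odds ratio")
  TRUE
})

#' QCReport: record of quality-control removals
#'
#' @slot samplesRemoved \code{data.frame(sample_id, reason)}.
#' @slot variantsRemoved \code{data.frame(variant_key, reason)}.
#' @slot thresholds named list echoing the thresholds applied.
#' @name QCReport-class
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
  representation(samplesRemoved = "data.frame",
                 variantsRemoved = "data.frame", thresholds = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet", object@pgsId, "with", nrow(object@variants), "variants\n")
  if (nrow(object@variants)) print(head(object@variants, 3))
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "variants;",
      sprintf("%.2f%% missing\n", 100 * mean(object@missing)))
})

setMethod("show", "HarmonizedScore", function(object) {
  tab <- table(factor(object@entries$action, levels = ALL_ACTIONS))
  cat("HarmonizedScore", object@pgsId, "-", nUsed(object), "used,",
      nDropped(object), "dropped\n")
  print(tab[tab > 0])
})

setMethod("show", "PRSVector", function(object) {
  cat("PRSVector", object@pgsId, "for", length(object@values),
      "samples over", object@nVariantsUsed, "variants",
      sprintf("(missing policy: %s)\n", object@missingPolicy))
})

setMethod("show", "PCResult", function(object) {
  cat("PCResult:", ncol(object@coords), "PCs retained;",
      object@nSignificant, "significant by Tracy-Widom at alpha =",
      object@alpha, "\n")
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult %s [%s]: R2 null %.3f full %.3f (PRS %.3f); OR[%s] %.3f (%.3f-%.3f), p = %.3g\n",
    object@pgsId, object@model, object@r2Null, object@r2Full,
    object@adjustedPrsR2, object@orScale,
    if (object@orScale == "per_sd") object@orPerSd else object@orRaw,
    object@ciLow, object@ciHigh, object@pValue))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", nrow(object@samplesRemoved), "samples and",
      nrow(object@variantsRemoved), "variants removed\n")
})
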