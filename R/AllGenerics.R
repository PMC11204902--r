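## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @export
setGeneric("pgsId", function(x) standardGeneric("pgsId"))
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @export
setGeneric("scoreVariants", function(x) standardGeneric("scoreVariants"))
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @export
setGeneric("variantMeta", function(x) standardGeneric("variantMeta"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("auditTable", function(x) standardGeneric("auditTable"))
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))
#' @export
setGeneric("prsValues", function(x) standardGeneric("prsValues"))
#' @export
setGeneric("prsZScores", function(x) standardGeneric("prsZScores"))
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @export
setGeneric("pcCoords", function(x) standardGeneric("pcCoords"))
#' @export
setGeneric("twStats", function(x) standardGeneric("twStats"))
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))
#' @export
setGeneric("samplesRemoved", function(x) standardGeneric("samplesRemoved"))
#' @export
setGeneric("variantsRemoved", function(x) standardGeneric("variantsRemoved"))

#' Accessors for prscad classes
#'
#' Read-only accessors for the slots of \linkS4class{ScoreSet},
#' \linkS4class{GenotypePanel}, \linkS4class{HarmonizedScore},
#' \linkS4class{PRSVector}, \linkS4class{PCResult} and
#' \linkS4class{QCReport}.
#'
#' @param x the object.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
#' @aliases pgsId nVariants scoreVariants dosage missingMask variantMeta
#'   sampleIds variantKeys nSamples auditTable nUsed nDropped prsValues
#'   prsZScores eigenvalues pcCoords twStats nSignificant samplesRemoved
#'   variantsRemoved
NULL

setMethod("pgsId", "ScoreSet", function(x) x@pgsId)
setMethod("pgsId", "HarmonizedScore", function(x) x@pgsId)
setMethod("pgsId", "PRSVector", function(x) x@pgsId)
setMethod("pgsId", "AssociationResult", function(x) x@pgsId)

setMethod("nVariants", "ScoreSet", function(x) nrow(x@variants))
setMethod("nVariants", "GenotypePanel", function(x) ncol(x@dosage))
setMethod("scoreVariants", "ScoreSet", function(x) x@variants)

setMethod("dosage", "GenotypePanel", function(x) x@dosage)
setMethod("missingMask", "GenotypePanel", function(x) x@missing)
setMethod("variantMeta", "GenotypePanel", function(x) x@variantMeta)
setMethod("sampleIds", "GenotypePanel", function(x) rownames(x@dosage))
setMethod("nSamples", "GenotypePanel", function(x) nrow(x@dosage))
setMethod("variantKeys", "GenotypePanel",
          function(x) variantKey(x@variantMeta$chrom, x@variantMeta$pos))

setMethod("auditTable", "HarmonizedScore", function(x) x@entries)
setMethod("nUsed", "HarmonizedScore",
          function(x) sum(x@entries$action %in% USED_ACTIONS))
setMethod("nDropped", "HarmonizedScore",
          function(x) sum(!x@entries$action %in% USED_ACTIONS))

setMethod("prsValues", "PRSVector", function(x) x@values)
setMethod("prsZScores", "PRSVector", function(x) x@zscores)

setMethod("eigenvalues", "PCResult", function(x) x@eigenvalues)
setMethod("pcCoords", "PCResult", function(x) x@coords)
setMethod("twStats", "PCResult", function(x) x@twStats)
setMethod("nSignificant", "PCResult", function(x) x@nSignificant)

setMethod("samplesRemoved", "QCReport", function(x) x@samplesRemoved)
setMethod("variantsRemoved", "QCReport", function(x) x@variantsRemoved)

#' Coerce an AssociationResult to a one-row data.frame
#'
#' @param x an \linkS4class{AssociationResult}.
#' @param ... ignored.
#' @return one-row \code{data.frame} with every reported field.
#' @export
as.data.frame.AssociationResult <- function(x, ...) {
  data.frame(pgs_id = x@pgsId, model = x@model, n = x@n,
             r2_null = x@r2Null, r2_full = x@r2Full,
             adjusted_prs_r2 = x@adjustedPrsR2,
             or_raw = x@orRaw, or_per_sd = x@orPerSd,
             ci_low = x@ciLow, ci_high = x@ciHigh,
             p_value = x@pValue, or_scale = x@orScale,
             bonferroni_significant = x@bonferroniSignificant,
             converged = x@converged, stringsAsFactors = FALSE)
}
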