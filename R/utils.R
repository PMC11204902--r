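#' Build a panel variant key from chromosome and position
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions.
#' @return character vector \code{"chrom:pos"}.
#' @export
variantKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Complement nucleotide bases
#'
#' @param x character vector of single bases in \code{A,C,G,T}.
#' @return complemented bases.
#' @export
complementBase <- function(x) {
  bad <- !x %in% VALID_BASES
  if (any(bad)) stop("invalid allele character: ", paste(unique(x[bad]), collapse = ","))
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Construct a GenotypePanel
#'
#' @param dosage samples x variants numeric matrix of ALT dosages in [0,2];
#'   \code{NA} marks missing calls. Rownames are sample ids.
#' @param variantMeta data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{id}; one row per dosage column.
#' @param missing optional logical mask; defaults to \code{is.na(dosage)}.
#' @return a \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(dosage, variantMeta, missing = NULL) {
  if (is.null(missing)) missing <- is.na(dosage)
  dosage[missing] <- NA_real_
  colnames(dosage) <- variantKey(variantMeta$chrom, variantMeta$pos)
  dimnames(missing) <- dimnames(dosage)
  rownames(variantMeta) <- NULL
  new("GenotypePanel", dosage = dosage, missing = missing,
      variantMeta = variantMeta)
}

#' Construct a ScoreSet
#'
#' @param pgsId score accession/label.
#' @param variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele} (\code{NA}
#'   allowed), \code{weight}.
#' @return a \linkS4class{ScoreSet}.
#' @export
ScoreSet <- function(pgsId, variants) {
  rownames(variants) <- NULL
  new("ScoreSet", pgsId = pgsId, variants = variants)
}

#' Subset a panel
#'
#' Keep the given samples and/or variants (logical, integer or name index
#' into rows/columns of the dosage matrix).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param samples,variants index of rows / columns to keep (default all).
#' @return the subset \linkS4class{GenotypePanel}.
#' @export
subsetPanel <- function(panel, samples = NULL, variants = NULL) {
  d <- panel@dosage; m <- panel@missing; vm <- panel@variantMeta
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, colnames(d))
    d <- d[, variants, drop = FALSE]
    m <- m[, variants, drop = FALSE]
    vm <- vm[variants, , drop = FALSE]
  }
  GenotypePanel(d, vm, m)
}

## Hard-call dosages to 0/1/2 with round-half-to-even (base round()).
hard_calls <- function(panel) {
  hc <- round(panel@dosage)
  hc[panel@missing] <- NA
  hc
}

## Mean-impute missing dosages column-wise; columns with no observed value
## are an error for callers that need complete data.
mean_impute <- function(d) {
  nas <- which(colSums(is.na(d)) > 0)
  for (j in nas) {
    col <- d[, j]
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) stop("variant column ", j, " is fully missing")
    col[is.na(col)] <- mu
    d[, j] <- col
  }
  d
}
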