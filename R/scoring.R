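## Additive dosage-weighted polygenic score: PGS_i = sum_j w_j * G_ij over
## the harmonized, panel-oriented weights.

#' Compute a polygenic score for every sample
#'
#' Sums the panel-oriented weight times the ALT dosage across all used
#' harmonization entries. The sum is unnormalized (no division by the
#' number of variants). Missing dosages are handled per
#' \code{missing_policy}: \code{"mean"} (default) substitutes the variant's
#' mean observed dosage, \code{"zero"} substitutes 0, \code{"drop-variant"}
#' removes any variant with missingness from the score.
#'
#' @param harmonized a \linkS4class{HarmonizedScore}.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param missing_policy \code{"mean"}, \code{"zero"} or
#'   \code{"drop-variant"}.
#' @return a \linkS4class{PRSVector}.
#' @export
computePRS <- function(harmonized, panel,
                       missing_policy = c("mean", "zero", "drop-variant")) {
  missing_policy <- match.arg(missing_policy)
  e <- auditTable(harmonized)
  used <- e[e$action %in% USED_ACTIONS, , drop = FALSE]
  if (!nrow(used)) stop("empty score: no usable harmonized variants")
  j <- match(used$panel_key, variantKeys(panel))
  if (anyNA(j)) stop("harmonized entries reference variants absent from panel")
  d <- dosage(panel)[, j, drop = FALSE]
  w <- used$aligned_weight
  if (missing_policy == "drop-variant") {
    keep <- colSums(is.na(d)) == 0
    if (!any(keep)) stop("empty score: all variants have missingness")
    d <- d[, keep, drop = FALSE]
    w <- w[keep]
  } else if (missing_policy == "mean") {
    d <- mean_impute(d)
  } else {
    d[is.na(d)] <- 0
  }
  vals <- drop(d %*% w)
  names(vals) <- sampleIds(panel)
  new("PRSVector", pgsId = pgsId(harmonized), values = vals,
      zscores = numeric(0), nVariantsUsed = length(w),
      missingPolicy = missing_policy)
}

#' Z-score a polygenic score
#'
#' Centers and scales to mean 0, SD 1 (population SD, i.e. divisor n);
#' the raw values are retained alongside.
#'
#' @param prs a \linkS4class{PRSVector} with >= 2 samples.
#' @return the same \linkS4class{PRSVector} with \code{prsZScores()} filled.
#' @export
standardizePRS <- function(prs) {
  v <- prsValues(prs)
  if (length(v) < 2) stop("need at least 2 samples")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("degenerate score: zero variance")
  z <- (v - mean(v)) / s
  initialize(prs, zscores = z)
}

#' Write per-sample scores as TSV
#'
#' @param prs a \linkS4class{PRSVector}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePRS <- function(prs, path) {
  z <- prsZScores(prs)
  out <- data.frame(sample_id = names(prsValues(prs)),
                    score = unname(prsValues(prs)),
                    zscore = if (length(z)) unname(z) else NA_real_,
                    n_variants_used = prs@nVariantsUsed)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
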