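## Array-era quality control: sample call rate, heterozygosity outliers,
## variant call rate, Hardy-Weinberg exact test.

#' Per-sample call rate
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @return named numeric vector, fraction of non-missing genotypes per
#'   sample.
#' @export
sampleCallRate <- function(panel) {
  if (nVariants(panel) == 0) stop("panel has zero variants")
  1 - rowMeans(missingMask(panel))
}

#' Sample-level QC: call rate and heterozygosity outliers
#'
#' Removes samples with call rate below \code{call_rate_min} and samples
#' whose hard-called heterozygosity rate deviates from the panel mean by
#' more than \code{k_sd} standard deviations. With zero heterozygosity
#' spread no sample is a heterozygosity outlier.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param call_rate_min retain samples with call rate >= this (default 0.95).
#' @param k_sd heterozygosity cutoff in SD units (default 3).
#' @return list with \code{panel} (filtered) and \code{report}
#'   (\linkS4class{QCReport}).
#' @export
sampleQC <- function(panel, call_rate_min = 0.95, k_sd = 3) {
  cr <- sampleCallRate(panel)
  low_cr <- cr < call_rate_min
  kept <- subsetPanel(panel, samples = !low_cr)
  removed <- data.frame(sample_id = sampleIds(panel)[low_cr],
                        reason = rep("call_rate", sum(low_cr)),
                        stringsAsFactors = FALSE)
  het <- heterozygosityOutliers(kept, k_sd = k_sd)
  removed <- rbind(removed,
                   data.frame(sample_id = het$outliers,
                              reason = rep("heterozygosity",
                                           length(het$outliers)),
                              stringsAsFactors = FALSE))
  kept <- subsetPanel(kept, samples = !sampleIds(kept) %in% het$outliers)
  list(panel = kept,
       report = new("QCReport", samplesRemoved = removed,
                    variantsRemoved = data.frame(variant_key = character(),
                                                 reason = character()),
                    thresholds = list(sample_call_rate = call_rate_min,
                                      het_sd = k_sd)))
}

#' Heterozygosity outlier detection
#'
#' Heterozygosity rate per sample is the fraction of called hard-called
#' genotypes equal to 1 (dosages rounded half-to-even). Samples with
#' \code{|rate - mean| > k_sd * SD} are outliers.
#'
#' @param panel a \linkS4class{GenotypePanel} (>= 3 samples).
#' @param k_sd cutoff in SD units.
#' @return list with \code{rates} (named numeric) and \code{outliers}
#'   (sample ids).
#' @export
heterozygosityOutliers <- function(panel, k_sd = 3) {
  if (nSamples(panel) < 3) stop("need at least 3 samples")
  hc <- hard_calls(panel)
  called <- rowSums(!is.na(hc))
  if (any(called == 0)) stop("sample with no called genotypes")
  rates <- rowSums(hc == 1, na.rm = TRUE) / called
  s <- sd(rates)
  outliers <- if (s == 0) character(0) else
    names(rates)[abs(rates - mean(rates)) > k_sd * s]
  list(rates = rates, outliers = outliers)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions given genotype
#' counts at a biallelic site. Conditional on the allele totals, the
#' p-value is the summed probability of all heterozygote counts (same
#' parity) whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param nAA,nAa,naa genotype counts (\code{A} the reference-coded allele).
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("counts must be nonnegative")
  n <- nAA + nAa + naa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  # possible heterozygote counts share the parity of nA
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp)
  p <- p / sum(p)  # guard accumulated rounding; exact mass sums to 1
  obs <- p[match(nAa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

## vectorized over variant columns of a hard-call matrix
hwe_pvalues <- function(hc) {
  apply(hc, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Variant-level QC: call rate and Hardy-Weinberg equilibrium
#'
#' Retains variants with call rate >= \code{call_rate_min} and HWE exact
#' p-value >= \code{hwe_alpha}. HWE is computed on hard calls, by default
#' over all samples pooled; set \code{hwe_samples} to restrict (e.g. to
#' controls).
#'
#' @param panel a \linkS4class{GenotypePanel} (after sample QC).
#' @param hwe_alpha exclusion threshold on the HWE p-value (default 1e-4).
#' @param call_rate_min minimum variant call rate (default 0.98).
#' @param hwe_samples optional sample ids to compute HWE on.
#' @return list with \code{panel} (filtered) and \code{report}.
#' @export
variantQC <- function(panel, hwe_alpha = 1e-4, call_rate_min = 0.98,
                      hwe_samples = NULL) {
  cr <- 1 - colMeans(missingMask(panel))
  hc <- hard_calls(panel)
  if (!is.null(hwe_samples)) hc <- hc[hwe_samples, , drop = FALSE]
  hwe <- hwe_pvalues(hc)
  low_cr <- cr < call_rate_min
  bad_hwe <- !is.na(hwe) & hwe < hwe_alpha
  keys <- variantKeys(panel)
  removed <- rbind(
    data.frame(variant_key = keys[low_cr],
               reason = rep("call_rate", sum(low_cr)),
               stringsAsFactors = FALSE),
    data.frame(variant_key = keys[!low_cr & bad_hwe],
               reason = rep("hwe", sum(!low_cr & bad_hwe)),
               stringsAsFactors = FALSE))
  keep <- !(low_cr | bad_hwe)
  list(panel = subsetPanel(panel, variants = keep),
       report = new("QCReport",
                    samplesRemoved = data.frame(sample_id = character(),
                                                reason = character()),
                    variantsRemoved = removed,
                    thresholds = list(hwe_alpha = hwe_alpha,
                                      variant_call_rate = call_rate_min)))
}

#' Serialize a QCReport to TSV
#'
#' @param report a \linkS4class{QCReport}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeQCReport <- function(report, path) {
  s <- samplesRemoved(report)
  v <- variantsRemoved(report)
  out <- rbind(
    if (nrow(s)) data.frame(entity = "sample", key = s$sample_id,
                            reason = s$reason) else NULL,
    if (nrow(v)) data.frame(entity = "variant", key = v$variant_key,
                            reason = v$reason) else NULL,
    data.frame(entity = "threshold", key = names(report@thresholds),
               reason = as.character(unlist(report@thresholds))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
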