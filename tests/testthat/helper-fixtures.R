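## Builders and independent oracles used across the suite.

## Small panel from an explicit dosage matrix (samples x variants).
make_panel <- function(d, ref = NULL, alt = NULL, chrom = "1",
                       pos = NULL, ids = NULL) {
  m <- ncol(d)
  if (is.null(ref)) ref <- rep("G", m)
  if (is.null(alt)) alt <- rep("A", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(m))
  if (is.null(rownames(d))) rownames(d) <- paste0("s", seq_len(nrow(d)))
  chrom <- rep_len(chrom, m)
  GenotypePanel(d, data.frame(chrom = chrom, pos = pos, ref = ref,
                              alt = alt, id = ids,
                              stringsAsFactors = FALSE))
}

make_score <- function(weights, effect, other, chrom = "1", pos = NULL,
                       ids = NULL, pgs = "PGS_TEST") {
  m <- length(weights)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(m))
  ScoreSet(pgs, data.frame(variant_id = ids, chrom = chrom, pos = pos,
                           effect_allele = effect, other_allele = other,
                           weight = weights, stringsAsFactors = FALSE))
}

## Independent HWE oracle: unnormalized conditional probabilities built by
## the heterozygote-count recurrence (no factorials shared with the
## package's closed form), normalized by their sum.
hwe_oracle <- function(nAA, nAa, naa) {
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  probs <- numeric(length(hets))
  probs[length(hets)] <- 1
  if (length(hets) > 1) {
    for (i in rev(seq_len(length(hets) - 1))) {
      h <- hets[i + 1]                       # move from h to h - 2
      aa <- (nA - h) / 2; bb <- (na - h) / 2
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (aa + 1) * (bb + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

## Explicit double-loop PRS oracle over the harmonization audit.
prs_oracle <- function(harmonized, panel) {
  e <- auditTable(harmonized)
  e <- e[e$action %in% c("exact", "switched", "flipped", "flipped_switched",
                         "proxied"), , drop = FALSE]
  d <- dosage(panel)
  keys <- variantKeys(panel)
  out <- setNames(numeric(nrow(d)), rownames(d))
  for (i in seq_len(nrow(d))) {
    acc <- 0
    for (r in seq_len(nrow(e))) {
      j <- which(keys == e$panel_key[r])
      x <- d[i, j]
      if (is.na(x)) x <- mean(d[, j], na.rm = TRUE)
      acc <- acc + e$aligned_weight[r] * x
    }
    out[i] <- acc
  }
  out
}

## 2x2 table logistic fixture: exposed/unexposed cases and controls.
table2x2 <- function(case_exp, ctrl_exp, case_unexp, ctrl_unexp) {
  y <- c(rep(1, case_exp), rep(0, ctrl_exp), rep(1, case_unexp),
         rep(0, ctrl_unexp))
  x <- c(rep(1, case_exp + ctrl_exp), rep(0, case_unexp + ctrl_unexp))
  list(y = y, design = cbind(1, x))
}
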