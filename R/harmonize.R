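## Aligning published score variants and weights to the target panel's
## ALT-dosage orientation, with strand-flip handling, effect reversal on
## allele switches, and LD-proxy substitution for absent markers.

#' Classify a score variant's alleles against a panel variant
#'
#' Compares the score file's (effect, other) allele pair with the panel's
#' (ref, alt) pair. Palindromic pairs (A/T, C/G) are strand-unresolvable
#' and are classified \code{ambiguous_dropped} under the default policy.
#'
#' @param effect,other score-file alleles (single bases, must differ).
#' @param ref,alt panel alleles (single bases, must differ).
#' @param palindromic_policy \code{"drop"} (default) or
#'   \code{"assume-same-strand"}, under which palindromic pairs are matched
#'   without considering strand flips.
#' @return one of \code{"exact"}, \code{"switched"}, \code{"flipped"},
#'   \code{"flipped_switched"}, \code{"ambiguous_dropped"}, \code{"dropped"}.
#' @export
classifyAlleles <- function(effect, other, ref, alt,
                            palindromic_policy = c("drop",
                                                   "assume-same-strand")) {
  palindromic_policy <- match.arg(palindromic_policy)
  al <- c(effect, other, ref, alt)
  if (!all(al %in% VALID_BASES))
    stop("invalid allele character: ",
         paste(unique(al[!al %in% VALID_BASES]), collapse = ","))
  if (effect == other) stop("effect allele equals other allele")
  if (ref == alt) stop("ref equals alt")
  pal <- is_palindromic(effect, other)
  if (pal && palindromic_policy == "drop") return("ambiguous_dropped")
  if (effect == alt && other == ref) return("exact")
  if (effect == ref && other == alt) return("switched")
  if (!pal) {
    ce <- complementBase(effect); co <- complementBase(other)
    if (ce == alt && co == ref) return("flipped")
    if (ce == ref && co == alt) return("flipped_switched")
  }
  "dropped"
}

#' Orient a weight for the panel's ALT dosage
#'
#' Weights are unchanged for \code{exact}/\code{flipped} matches and
#' negated for \code{switched}/\code{flipped_switched} (the effect allele
#' is the panel REF, so the per-ALT effect reverses sign).
#'
#' @param weight per-effect-allele weight.
#' @param action a usable classification from \code{\link{classifyAlleles}}.
#' @return the panel-oriented weight.
#' @export
alignWeight <- function(weight, action) {
  switch(action,
         exact = ,
         flipped = weight,
         switched = ,
         flipped_switched = -weight,
         stop("alignWeight called with non-usable action: ", action))
}

#' LDReference: pairwise r-squared lookup
#'
#' Symmetric lookup of linkage-disequilibrium r-squared between variant
#' keys (\code{"chrom:pos"}), with a proxy search window in base pairs.
#'
#' @slot table \code{data.frame(key_a, key_b, r2)}.
#' @slot window search window in bp (each side).
#' @name LDReference-class
#' @aliases LDReference-class
#' @exportClass LDReference
setClass("LDReference",
  representation(table = "data.frame", window = "numeric"))

setValidity("LDReference", function(object) {
  t <- object@table
  if (!all(c("key_a", "key_b", "r2") %in% names(t)))
    return("table needs columns key_a, key_b, r2")
  if (nrow(t) && any(t$r2 < 0 | t$r2 > 1)) return("r2 outside [0,1]")
  TRUE
})

#' Construct an LDReference
#'
#' @param table \code{data.frame(key_a, key_b, r2)}; stored symmetrically.
#' @param window proxy search window in bp (default 500 kb each side).
#' @return an \linkS4class{LDReference}.
#' @export
LDReference <- function(table, window = 5e5) {
  new("LDReference", table = table, window = window)
}

#' Read an LD reference from TSV
#'
#' @param path TSV with columns \code{key_a}, \code{key_b}, \code{r2}.
#' @param window proxy search window in bp.
#' @return an \linkS4class{LDReference}.
#' @export
readLDReference <- function(path, window = 5e5) {
  LDReference(read.delim(path, stringsAsFactors = FALSE), window = window)
}

#' Compute an LD reference from the panel itself
#'
#' Pairwise squared Pearson correlation of dosages between panel variants
#' on the same chromosome within \code{window} bp. Quadratic in the number
#' of variants per chromosome; intended for imputed panels of modest width
#' or for testing.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param window window in bp (default 500 kb).
#' @return an \linkS4class{LDReference}.
#' @export
panelLDReference <- function(panel, window = 5e5) {
  vm <- variantMeta(panel)
  keys <- variantKeys(panel)
  d <- mean_impute(dosage(panel))
  rows <- list()
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(d[, idx, drop = FALSE]))^2
    pd <- abs(outer(vm$pos[idx], vm$pos[idx], "-"))
    sel <- which(upper.tri(r2) & pd <= window & is.finite(r2), arr.ind = TRUE)
    if (!nrow(sel)) next
    rows[[ch]] <- data.frame(key_a = keys[idx[sel[, 1]]],
                             key_b = keys[idx[sel[, 2]]],
                             r2 = r2[sel], stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key_a = character(), key_b = character(), r2 = numeric())
  rownames(tab) <- NULL
  LDReference(tab, window = window)
}

#' Look up r-squared between two variant keys
#'
#' @param ld an \linkS4class{LDReference}.
#' @param a,b variant keys.
#' @return r-squared, or \code{NA} if the pair is not covered
#'   (\code{r2(a, a) = 1} by definition).
#' @export
ldR2 <- function(ld, a, b) {
  if (a == b) return(1)
  t <- ld@table
  hit <- (t$key_a == a & t$key_b == b) | (t$key_a == b & t$key_b == a)
  if (!any(hit)) return(NA_real_)
  max(t$r2[hit])
}

#' Find an LD proxy for a score variant absent from the panel
#'
#' Among panel variants on the same chromosome within the reference's
#' search window having r-squared strictly greater than \code{r2_min} with
#' the score variant, picks the highest r-squared (ties: smallest position
#' difference, then lowest position). The proxy's alleles are re-classified
#' against the score variant's effect/other pair; candidates that do not
#' classify to a usable match are passed over.
#'
#' @param score_variant one-row slice of \code{scoreVariants()} output.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param ld_ref an \linkS4class{LDReference}.
#' @param r2_min proxy threshold, strict (default 0.8).
#' @param palindromic_policy passed to \code{\link{classifyAlleles}}.
#' @return list with \code{action}, \code{panel_key}, \code{aligned_weight},
#'   \code{proxy_r2}, \code{reason}.
#' @export
findProxy <- function(score_variant, panel, ld_ref, r2_min = 0.8,
                      palindromic_policy = "drop") {
  dropped <- function(reason)
    list(action = "dropped", panel_key = NA_character_,
         aligned_weight = NA_real_, proxy_r2 = NA_real_, reason = reason)
  if (is.null(ld_ref)) return(dropped("no_ld_data"))
  vm <- variantMeta(panel)
  keys <- variantKeys(panel)
  svkey <- variantKey(score_variant$chrom, score_variant$pos)
  cand <- which(vm$chrom == score_variant$chrom &
                abs(vm$pos - score_variant$pos) <= ld_ref@window)
  if (!length(cand)) return(dropped("no_candidate_in_window"))
  r2 <- vapply(keys[cand], function(k) ldR2(ld_ref, svkey, k), numeric(1))
  if (all(is.na(r2))) return(dropped("no_ld_data"))
  qual <- which(!is.na(r2) & r2 > r2_min)
  if (!length(qual)) return(dropped("no_proxy_above_r2_min"))
  ord <- qual[order(-r2[qual],
                    abs(vm$pos[cand[qual]] - score_variant$pos),
                    vm$pos[cand[qual]])]
  for (q in ord) {
    j <- cand[q]
    act <- if (is.na(score_variant$other_allele)) {
      if (score_variant$effect_allele == vm$alt[j]) "exact"
      else if (score_variant$effect_allele == vm$ref[j]) "switched"
      else "dropped"
    } else {
      classifyAlleles(score_variant$effect_allele,
                      score_variant$other_allele,
                      vm$ref[j], vm$alt[j],
                      palindromic_policy = palindromic_policy)
    }
    if (act %in% c("exact", "switched", "flipped", "flipped_switched"))
      return(list(action = "proxied", panel_key = keys[j],
                  aligned_weight = alignWeight(score_variant$weight, act),
                  proxy_r2 = unname(r2[q]), reason = paste0("proxy_", act)))
  }
  dropped("proxy_allele_mismatch")
}

#' Harmonize a ScoreSet against a GenotypePanel
#'
#' Maps every score variant to exactly one outcome: matched in place
#' (exact / switched / flipped / flipped_switched, with weights reversed on
#' switches), substituted by an LD proxy, or dropped (palindromic
#' ambiguity, allele mismatch, absent without proxy, or duplicate target).
#' Matching is by (chrom, pos); rsID against the panel's id column is the
#' fallback when the score file lacks positions. Deterministic given its
#' inputs.
#'
#' @param scoreset a \linkS4class{ScoreSet}.
#' @param panel a \linkS4class{GenotypePanel} (after QC).
#' @param ld_ref optional \linkS4class{LDReference} for proxy search.
#' @param r2_min proxy r-squared threshold, strict (default 0.8).
#' @param palindromic_policy \code{"drop"} or \code{"assume-same-strand"}.
#' @return a \linkS4class{HarmonizedScore}.
#' @export
harmonizeScoreSet <- function(scoreset, panel, ld_ref = NULL, r2_min = 0.8,
                              palindromic_policy = c("drop",
                                                     "assume-same-strand")) {
  palindromic_policy <- match.arg(palindromic_policy)
  sv <- scoreVariants(scoreset)
  vm <- variantMeta(panel)
  keys <- variantKeys(panel)
  n <- nrow(sv)
  out <- data.frame(variant_id = sv$variant_id,
                    action = character(n), panel_key = NA_character_,
                    aligned_weight = NA_real_, proxy_r2 = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  haspos <- !is.na(sv$chrom) & !is.na(sv$pos)
  j_by_pos <- ifelse(haspos,
                     match(variantKey(sv$chrom, sv$pos), keys),
                     NA_integer_)
  j_by_id <- match(sv$variant_id, vm$id)
  j <- ifelse(!is.na(j_by_pos), j_by_pos,
              ifelse(haspos, NA_integer_, j_by_id))
  used_keys <- character(0)

  for (i in seq_len(n)) {
    res <- if (is.na(j[i])) {
      findProxy(sv[i, ], panel, ld_ref, r2_min = r2_min,
                palindromic_policy = palindromic_policy)
    } else {
      jj <- j[i]
      act <- if (is.na(sv$other_allele[i])) {
        # flips unverifiable without both alleles: exact/switched only
        if (sv$effect_allele[i] == vm$alt[jj]) "exact"
        else if (sv$effect_allele[i] == vm$ref[jj]) "switched"
        else "dropped"
      } else {
        classifyAlleles(sv$effect_allele[i], sv$other_allele[i],
                        vm$ref[jj], vm$alt[jj],
                        palindromic_policy = palindromic_policy)
      }
      if (act %in% USED_ACTIONS0) {
        list(action = act, panel_key = keys[jj],
             aligned_weight = alignWeight(sv$weight[i], act),
             proxy_r2 = NA_real_, reason = NA_character_)
      } else {
        list(action = act, panel_key = NA_character_,
             aligned_weight = NA_real_, proxy_r2 = NA_real_,
             reason = if (act == "ambiguous_dropped") "palindromic"
                      else "allele_mismatch")
      }
    }
    if (res$action %in% USED_ACTIONS && res$panel_key %in% used_keys) {
      res <- list(action = "dropped", panel_key = NA_character_,
                  aligned_weight = NA_real_, proxy_r2 = NA_real_,
                  reason = "duplicate_target")
    }
    if (res$action %in% USED_ACTIONS) used_keys <- c(used_keys, res$panel_key)
    out$action[i] <- res$action
    out$panel_key[i] <- res$panel_key
    out$aligned_weight[i] <- res$aligned_weight
    out$proxy_r2[i] <- res$proxy_r2
    out$reason[i] <- res$reason
  }
  new("HarmonizedScore", pgsId = pgsId(scoreset), entries = out)
}

USED_ACTIONS0 <- c("exact", "switched", "flipped", "flipped_switched")

#' Write the harmonization audit as TSV
#'
#' @param harmonized a \linkS4class{HarmonizedScore}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAudit <- function(harmonized, path) {
  write.table(auditTable(harmonized), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
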