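## Fully seeded synthetic cohort generator: Balding-Nichols population
## structure, block-copy LD, calibrated covariates, and a logistic disease
## model with a planted per-SD score effect. Ground truth is returned
## alongside so harmonization, scoring and association can be tested
## against known answers.

#' Simulation configuration
#'
#' Defaults emulate a case-control replication cohort: 924 samples with a
#' 390/924 case fraction, biallelic SNP dosages under within-subpopulation
#' Hardy-Weinberg equilibrium, and covariates calibrated to the cohort's
#' descriptive table (age 57.7 +/- 12.4 y, 63.9\% male, SBP 132.6 +/- 19.7
#' mmHg, total cholesterol 200.7 +/- 44.6 mg/dl, 23.5\% T2DM, 65\%
#' smokers).
#'
#' @param n_samples,n_variants panel dimensions.
#' @param case_fraction target case fraction (default 390/924).
#' @param maf_range ancestral allele-frequency range, within (0, 0.5].
#' @param fst Balding-Nichols divergence parameter (0 = no structure).
#' @param n_subpops number of equally sized subpopulations.
#' @param ld_block_size variants per LD block (1 = independent variants).
#' @param ld_decay within-block haplotype copy probability in [0, 1).
#' @param n_causal number of causal variants for the planted score.
#' @param true_weights optional explicit causal weights (overrides
#'   \code{n_causal}).
#' @param per_sd_or planted odds ratio per SD of the true score.
#' @param covariate_params named list of covariate distribution parameters
#'   (see defaults in the function definition).
#' @param covariate_effects named list of log-OR covariate effects on
#'   disease (age is per year, centered at its mean).
#' @param jitter_sd SD of Gaussian dosage jitter mimicking imputation
#'   (clipped to [0, 2]; 0 = hard genotypes).
#' @param seed RNG seed; all generator output is reproducible from it.
#' @return validated configuration list (class \code{SimulationConfig}).
#' @export
simulationConfig <- function(n_samples = 924, n_variants = 1000,
                             case_fraction = 390 / 924,
                             maf_range = c(0.05, 0.5),
                             fst = 0, n_subpops = 1,
                             ld_block_size = 1, ld_decay = 0,
                             n_causal = 50, true_weights = NULL,
                             per_sd_or = 1,
                             covariate_params = list(),
                             covariate_effects = list(),
                             jitter_sd = 0, seed = 1) {
  cp <- utils::modifyList(list(
    age_mean = 57.7, age_sd = 12.4, male_frac = 0.639,
    weight_mean = 80, weight_sd = 14,
    sbp_mean = 132.6, sbp_sd = 19.7,
    chol_mean = 200.7, chol_sd = 44.6,
    t2dm_prev = 0.235, smoking_prev = 0.65), covariate_params)
  ce <- utils::modifyList(list(
    age = 0.03, sex = 0.5, t2dm = 0.4, smoking = 0.3,
    weight = 0, sbp = 0, total_chol = 0), covariate_effects)
  cfg <- list(n_samples = n_samples, n_variants = n_variants,
              case_fraction = case_fraction, maf_range = maf_range,
              fst = fst, n_subpops = n_subpops,
              ld_block_size = ld_block_size, ld_decay = ld_decay,
              n_causal = n_causal, true_weights = true_weights,
              per_sd_or = per_sd_or, covariate_params = cp,
              covariate_effects = ce, jitter_sd = jitter_sd, seed = seed)
  validateConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateConfig <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$n_variants >= 1,
            cfg$case_fraction > 0, cfg$case_fraction < 1,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$fst >= 0, cfg$fst < 1, cfg$n_subpops >= 1,
            cfg$ld_block_size >= 1, cfg$ld_decay >= 0, cfg$ld_decay < 1,
            cfg$per_sd_or > 0, cfg$jitter_sd >= 0)
  invisible(cfg)
}

#' Simulate a genotype panel with ground truth
#'
#' Ancestral allele frequencies are drawn uniformly in \code{maf_range}
#' (one per LD block; variants within a block share the block frequency so
#' the haplotype-copy LD model preserves per-site frequencies).
#' Subpopulation frequencies follow the Balding-Nichols beta model with
#' parameter \code{fst}; within a subpopulation, genotypes are the sum of
#' two independent haplotypes (Hardy-Weinberg). Within a block each
#' haplotype copies its previous allele with probability \code{ld_decay},
#' giving adjacent-pair genotype correlation \code{ld_decay} (r-squared
#' \code{ld_decay^2}) and no cross-block LD. Optional Gaussian jitter
#' mimics imputed dosages. Variant alleles are non-palindromic SNP pairs so
#' strand flips stay resolvable.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{panel} (\linkS4class{GenotypePanel}) and
#'   \code{truth} (causal table, true score and z-score, subpopulation
#'   labels, planted proxy pairs, corruption ledger).
#' @export
simulatePanel <- function(config) {
  validateConfig(config)
  set.seed(config$seed)
  n <- config$n_samples; m <- config$n_variants
  B <- config$ld_block_size
  block <- rep(seq_len(ceiling(m / B)), each = B)[seq_len(m)]
  nblocks <- max(block)
  p_anc <- runif(nblocks, config$maf_range[1], config$maf_range[2])

  subpop <- rep_len(seq_len(config$n_subpops), n)
  F <- config$fst
  # block x subpop frequency matrix
  pks <- matrix(p_anc, nblocks, config$n_subpops)
  if (F > 0 && config$n_subpops > 1) {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    for (k in seq_len(config$n_subpops))
      pks[, k] <- rbeta(nblocks, a, b)
    pks <- pmin(pmax(pks, 1e-4), 1 - 1e-4)
  }

  hap <- function() {
    h <- matrix(0L, n, m)
    for (bk in seq_len(nblocks)) {
      js <- which(block == bk)
      p_i <- pks[bk, subpop]           # per-sample frequency
      cur <- as.integer(runif(n) < p_i)
      h[, js[1]] <- cur
      for (s in js[-1]) {
        copy <- runif(n) < config$ld_decay
        fresh <- as.integer(runif(n) < p_i)
        cur <- ifelse(copy, cur, fresh)
        h[, s] <- cur
      }
    }
    h
  }
  g <- hap() + hap()
  storage.mode(g) <- "double"
  if (config$jitter_sd > 0)
    g <- pmin(pmax(g + rnorm(length(g), 0, config$jitter_sd), 0), 2)

  # non-palindromic ref/alt pairs
  refs <- sample(VALID_BASES, m, replace = TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(VALID_BASES, c(r, complementBase(r))), 1), character(1))
  vm <- data.frame(chrom = "1", pos = 1L + (seq_len(m) - 1L) * 5000L,
                   ref = refs, alt = unname(alts),
                   id = sprintf("rs%06d", seq_len(m)),
                   stringsAsFactors = FALSE)
  rownames(g) <- sprintf("S%04d", seq_len(n))
  panel <- GenotypePanel(g, vm)

  w <- config$true_weights
  if (is.null(w)) w <- rnorm(config$n_causal, 0, 1)
  ncausal <- length(w)
  causal_idx <- sort(sample.int(m, ncausal))
  causal <- data.frame(variant_id = vm$id[causal_idx],
                       key = variantKey(vm$chrom, vm$pos)[causal_idx],
                       chrom = vm$chrom[causal_idx], pos = vm$pos[causal_idx],
                       effect_allele = vm$alt[causal_idx],
                       other_allele = vm$ref[causal_idx],
                       weight = w, stringsAsFactors = FALSE)
  prs_true <- drop(g[, causal_idx, drop = FALSE] %*% w)
  s <- sqrt(mean((prs_true - mean(prs_true))^2))
  z_true <- if (s > 0) (prs_true - mean(prs_true)) / s else prs_true * 0
  truth <- list(causal = causal, prs_true = prs_true, z_true = z_true,
                subpop = setNames(subpop, rownames(g)),
                per_sd_or = config$per_sd_or,
                proxy_pairs = data.frame(dropped_key = character(),
                                         proxy_key = character(),
                                         r2 = numeric()),
                corruption = data.frame(variant_id = character(),
                                        action = character()))
  list(panel = panel, truth = truth)
}

#' Simulate phenotypes with a planted score effect
#'
#' Covariates are drawn from the configured calibration; case status
#' follows \code{Bernoulli(plogis(alpha + log(per_sd_or) * z_true + eta))}
#' where \code{eta} holds the covariate effects and the intercept
#' \code{alpha} is solved numerically so the expected case fraction equals
#' the configured target.
#'
#' @param panel panel from \code{\link{simulatePanel}}.
#' @param truth truth list from \code{\link{simulatePanel}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return phenotype \code{data.frame} (see \code{\link{readPhenotypes}}).
#' @export
simulatePhenotypes <- function(panel, truth, config) {
  validateConfig(config)
  set.seed(config$seed + 500000L)
  n <- nSamples(panel)
  cp <- config$covariate_params
  ce <- config$covariate_effects
  ph <- data.frame(
    sample_id = sampleIds(panel),
    case_status = NA_integer_,
    sex = rbinom(n, 1, cp$male_frac),
    age = rnorm(n, cp$age_mean, cp$age_sd),
    weight = rnorm(n, cp$weight_mean, cp$weight_sd),
    t2dm = rbinom(n, 1, cp$t2dm_prev),
    smoking = rbinom(n, 1, cp$smoking_prev),
    sbp = rnorm(n, cp$sbp_mean, cp$sbp_sd),
    total_chol = rnorm(n, cp$chol_mean, cp$chol_sd),
    stringsAsFactors = FALSE)
  ph$age <- pmax(ph$age, 18)
  eta <- log(config$per_sd_or) * truth$z_true +
    ce$age * (ph$age - cp$age_mean) + ce$sex * ph$sex +
    ce$t2dm * ph$t2dm + ce$smoking * ph$smoking +
    ce$weight * (ph$weight - cp$weight_mean) +
    ce$sbp * (ph$sbp - cp$sbp_mean) +
    ce$total_chol * (ph$total_chol - cp$chol_mean)
  f <- function(a) mean(plogis(a + eta)) - config$case_fraction
  if (f(-50) > 0 || f(50) < 0)
    stop("unattainable case fraction given covariate effects")
  alpha <- uniroot(f, c(-50, 50), tol = 1e-10)$root
  ph$case_status <- rbinom(n, 1, plogis(alpha + eta))
  ph
}

#' Emit a (possibly corrupted) scoring file with ground truth ledger
#'
#' Writes the planted causal score as a PGS-Catalog-style file. Selected
#' fractions of the causal variants are emitted in the opposite allele
#' orientation (\code{allele_switch}: effect/other exchanged with the
#' weight stated for the new effect allele, i.e. negated -- harmonization
#' must reverse it back), strand-complemented (\code{strand_flip}: both
#' alleles complemented, weight untouched), or removed from the panel with
#' an exact-duplicate proxy column planted one base pair away
#' (\code{drop_with_proxy}); the returned LD reference records the
#' dropped-to-proxy pair with r-squared 1.
#'
#' @param truth truth list from \code{\link{simulatePanel}}.
#' @param panel the matching \linkS4class{GenotypePanel}.
#' @param corruption named fractions \code{allele_switch},
#'   \code{strand_flip}, \code{drop_with_proxy}; must sum to at most 1.
#' @param path optional path to also write the scoring file.
#' @param pgsId score label (default \code{"PGS_SYNTH"}).
#' @param seed seed for the corruption draw.
#' @return list with \code{scoreset}, \code{panel} (possibly modified),
#'   \code{ld_ref}, \code{truth} (ledger and proxy pairs updated), and
#'   \code{path}.
#' @export
emitScoreFile <- function(truth, panel,
                          corruption = c(allele_switch = 0,
                                         strand_flip = 0,
                                         drop_with_proxy = 0),
                          path = NULL, pgsId = "PGS_SYNTH", seed = 1) {
  frac <- c(allele_switch = 0, strand_flip = 0, drop_with_proxy = 0)
  frac[names(corruption)] <- corruption
  if (sum(frac) > 1 + 1e-12) stop("corruption fractions sum above 1")
  set.seed(seed)
  ca <- truth$causal
  nc <- nrow(ca)
  n_sw <- round(frac["allele_switch"] * nc)
  n_fl <- round(frac["strand_flip"] * nc)
  n_dp <- min(round(frac["drop_with_proxy"] * nc), nc - n_sw - n_fl)
  pick <- sample.int(nc, n_sw + n_fl + n_dp)
  i_sw <- pick[seq_len(n_sw)]
  i_fl <- pick[n_sw + seq_len(n_fl)]
  i_dp <- pick[n_sw + n_fl + seq_len(n_dp)]

  out <- data.frame(variant_id = ca$variant_id, chrom = ca$chrom,
                    pos = ca$pos, effect_allele = ca$effect_allele,
                    other_allele = ca$other_allele, weight = ca$weight,
                    stringsAsFactors = FALSE)
  # switch: emit in the opposite orientation (effect <- other allele), so
  # the stated weight is the per-effect-allele weight of that allele
  out$effect_allele[i_sw] <- ca$other_allele[i_sw]
  out$other_allele[i_sw] <- ca$effect_allele[i_sw]
  out$weight[i_sw] <- -ca$weight[i_sw]
  # flip: same orientation, opposite strand
  out$effect_allele[i_fl] <- complementBase(ca$effect_allele[i_fl])
  out$other_allele[i_fl] <- complementBase(ca$other_allele[i_fl])

  ledger <- data.frame(
    variant_id = c(ca$variant_id[i_sw], ca$variant_id[i_fl],
                   ca$variant_id[i_dp]),
    action = c(rep("allele_switch", n_sw), rep("strand_flip", n_fl),
               rep("drop_with_proxy", n_dp)),
    stringsAsFactors = FALSE)

  proxy_pairs <- truth$proxy_pairs
  if (n_dp > 0) {
    vm <- variantMeta(panel)
    keys <- variantKeys(panel)
    d <- dosage(panel)
    mi <- missingMask(panel)
    drop_j <- match(ca$key[i_dp], keys)
    if (anyNA(drop_j)) stop("causal variant missing from panel")
    vm_proxy <- vm[drop_j, , drop = FALSE]
    vm_proxy$pos <- vm_proxy$pos + 1L
    vm_proxy$id <- paste0(vm_proxy$id, "_proxy")
    d2 <- cbind(d[, -drop_j, drop = FALSE], d[, drop_j, drop = FALSE])
    m2 <- cbind(mi[, -drop_j, drop = FALSE], mi[, drop_j, drop = FALSE])
    vm2 <- rbind(vm[-drop_j, , drop = FALSE], vm_proxy)
    ord <- order(vm2$chrom, vm2$pos)
    panel <- GenotypePanel(d2[, ord, drop = FALSE], vm2[ord, , drop = FALSE],
                           m2[, ord, drop = FALSE])
    proxy_pairs <- rbind(proxy_pairs, data.frame(
      dropped_key = ca$key[i_dp],
      proxy_key = variantKey(vm_proxy$chrom, vm_proxy$pos),
      r2 = 1, stringsAsFactors = FALSE))
  }
  ld_ref <- LDReference(data.frame(key_a = proxy_pairs$dropped_key,
                                   key_b = proxy_pairs$proxy_key,
                                   r2 = proxy_pairs$r2,
                                   stringsAsFactors = FALSE))
  truth$proxy_pairs <- proxy_pairs
  truth$corruption <- rbind(truth$corruption, ledger)

  scoreset <- ScoreSet(pgsId, out)
  if (!is.null(path)) writeScoreFile(scoreset, path)
  list(scoreset = scoreset, panel = panel, ld_ref = ld_ref, truth = truth,
       path = path)
}

#' Hudson's two-population Fst estimator
#'
#' Ratio-of-averages Hudson estimator over variants: per-variant numerator
#' \code{(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)} and denominator
#' \code{p1(1-p2) + p2(1-p1)}, with allele counts \code{n_k} = 2 x sample
#' size, summed before dividing.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param subpop per-sample labels with exactly two levels.
#' @return the Fst estimate.
#' @export
hudsonFst <- function(panel, subpop) {
  lev <- unique(subpop)
  if (length(lev) != 2) stop("Hudson estimator needs exactly two groups")
  d <- dosage(panel)
  g1 <- d[subpop == lev[1], , drop = FALSE]
  g2 <- d[subpop == lev[2], , drop = FALSE]
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  n1 <- 2 * nrow(g1); n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Draw an independent null score from a panel
#'
#' Samples causal variants and weights uncorrelated with any phenotype,
#' in the panel's ALT orientation; used to emit additional scoring files
#' that carry no disease signal.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param n_causal number of variants.
#' @param seed RNG seed.
#' @return causal table in the format of \code{simulatePanel()} truth.
#' @export
drawNullScore <- function(panel, n_causal, seed = 1) {
  set.seed(seed)
  vm <- variantMeta(panel)
  idx <- sort(sample.int(nrow(vm), min(n_causal, nrow(vm))))
  data.frame(variant_id = vm$id[idx],
             key = variantKey(vm$chrom, vm$pos)[idx],
             chrom = vm$chrom[idx], pos = vm$pos[idx],
             effect_allele = vm$alt[idx], other_allele = vm$ref[idx],
             weight = rnorm(length(idx)), stringsAsFactors = FALSE)
}
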