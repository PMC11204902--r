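test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simulationConfig(n_samples = 60, n_variants = 80, fst = 0.05,
                          n_subpops = 2, ld_block_size = 4, ld_decay = 0.5,
                          jitter_sd = 0.05, seed = 9)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(dosage(a$panel), dosage(b$panel))
  expect_identical(a$truth$causal, b$truth$causal)
  expect_identical(simulatePhenotypes(a$panel, a$truth, cfg),
                   simulatePhenotypes(b$panel, b$truth, cfg))
  # a different seed gives different data
  cfg2 <- simulationConfig(n_samples = 60, n_variants = 80, fst = 0.05,
                           n_subpops = 2, ld_block_size = 4, ld_decay = 0.5,
                           jitter_sd = 0.05, seed = 10)
  expect_false(identical(dosage(simulatePanel(cfg2)$panel),
                         dosage(a$panel)))
})

test_that("default settings reproduce the cohort's size and case fraction", {
  cfg <- simulationConfig(seed = 12)
  sim <- simulatePanel(cfg)
  expect_equal(nSamples(sim$panel), 924)
  ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
  expect_equal(nrow(ph), 924)
  expect_lt(abs(mean(ph$case_status) - 390 / 924), 0.05)
  expect_true(all(ph$case_status %in% 0:1))
})

test_that("covariates match their calibration at large n", {
  cfg <- simulationConfig(n_samples = 2000, n_variants = 50, seed = 13)
  sim <- simulatePanel(cfg)
  ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
  expect_lt(abs(mean(ph$age) - 57.7), 1.0)
  expect_lt(abs(sd(ph$age) - 12.4), 1.0)
  expect_lt(abs(mean(ph$sex) - 0.639), 0.04)
  expect_lt(abs(mean(ph$sbp) - 132.6), 1.5)
  expect_lt(abs(mean(ph$total_chol) - 200.7), 3.5)
  expect_lt(abs(mean(ph$t2dm) - 0.235), 0.035)
  expect_lt(abs(mean(ph$smoking) - 0.65), 0.04)
  expect_true(all(ph$age >= 18))
})

test_that("cases carry higher true scores and risk-factor burden", {
  cfg <- simulationConfig(n_samples = 2000, n_variants = 200, n_causal = 40,
                          per_sd_or = 1.8, seed = 14)
  sim <- simulatePanel(cfg)
  ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
  z <- sim$truth$z_true
  expect_gt(mean(z[ph$case_status == 1]) - mean(z[ph$case_status == 0]),
            0.2)
  expect_gt(mean(ph$age[ph$case_status == 1]),
            mean(ph$age[ph$case_status == 0]))
})

test_that("genotypes sit in Hardy-Weinberg proportions within a population", {
  cfg <- simulationConfig(n_samples = 500, n_variants = 300, seed = 15)
  sim <- simulatePanel(cfg)
  pv <- apply(dosage(sim$panel), 2, function(g)
    hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0)))
  # at most a few percent of variants below 0.01 under the null
  expect_lt(mean(pv < 0.01), 0.04)
  expect_gt(min(colMeans(dosage(sim$panel)) / 2), 0.01)
})

test_that("block-copy LD gives the stated adjacent correlation and no cross-block LD", {
  cfg <- simulationConfig(n_samples = 2000, n_variants = 400,
                          ld_block_size = 4, ld_decay = 0.95, seed = 16)
  sim <- simulatePanel(cfg)
  d <- dosage(sim$panel)
  within <- vapply(seq(1, 397, by = 4), function(j)
    cor(d[, j], d[, j + 1]), numeric(1))
  across <- vapply(seq(4, 396, by = 4), function(j)
    cor(d[, j], d[, j + 1]), numeric(1))
  expect_gt(mean(within), 0.85)          # target correlation 0.95
  expect_lt(mean(abs(across)), 0.1)      # block boundaries are independent
  expect_gt(mean(within^2), 0.5)
})

test_that("Balding-Nichols divergence lands near the target Fst", {
  cfg <- simulationConfig(n_samples = 600, n_variants = 2000, fst = 0.05,
                          n_subpops = 2, seed = 18)
  sim <- simulatePanel(cfg)
  fst <- hudsonFst(sim$panel, sim$truth$subpop)
  expect_gt(fst, 0.03)
  expect_lt(fst, 0.07)
  # no structure means Fst near zero
  cfg0 <- simulationConfig(n_samples = 600, n_variants = 2000, seed = 18)
  sim0 <- simulatePanel(cfg0)
  grp <- rep(1:2, length.out = 600)
  expect_lt(abs(hudsonFst(sim0$panel, grp)), 0.005)
})

test_that("emitted scoring files carry a faithful corruption ledger", {
  cfg <- simulationConfig(n_samples = 100, n_variants = 300, n_causal = 40,
                          seed = 19)
  sim <- simulatePanel(cfg)
  em <- emitScoreFile(sim$truth, sim$panel,
                      corruption = c(allele_switch = 0.25,
                                     strand_flip = 0.25,
                                     drop_with_proxy = 0.25), seed = 20)
  led <- em$truth$corruption
  expect_equal(unname(table(led$action)[c("allele_switch", "strand_flip",
                                          "drop_with_proxy")]),
               rep(10L, 3), ignore_attr = TRUE)
  sv <- scoreVariants(em$scoreset)
  ca <- sim$truth$causal
  for (id in led$variant_id[led$action == "allele_switch"]) {
    i <- match(id, sv$variant_id); j <- match(id, ca$variant_id)
    expect_identical(sv$effect_allele[i], ca$other_allele[j])
    expect_identical(sv$weight[i], -ca$weight[j])
  }
  for (id in led$variant_id[led$action == "strand_flip"]) {
    i <- match(id, sv$variant_id); j <- match(id, ca$variant_id)
    expect_identical(sv$effect_allele[i],
                     unname(complementBase(ca$effect_allele[j])))
    expect_identical(sv$weight[i], ca$weight[j])
  }
  dropped <- ca$key[match(led$variant_id[led$action == "drop_with_proxy"],
                          ca$variant_id)]
  expect_false(any(dropped %in% variantKeys(em$panel)))
  expect_equal(nrow(em$truth$proxy_pairs), 10)
  expect_true(all(em$truth$proxy_pairs$r2 == 1))
  expect_error(emitScoreFile(sim$truth, sim$panel,
                             corruption = c(allele_switch = 0.7,
                                            strand_flip = 0.7)),
               "sum above 1")
})

test_that("nine null scores rarely reach Bonferroni significance", {
  clean_runs <- 0L
  for (rep in 1:6) {
    cfg <- simulationConfig(n_samples = 250, n_variants = 150,
                            n_causal = 25, per_sd_or = 1, seed = 300 + rep)
    sim <- simulatePanel(cfg)
    ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
    pvals <- vapply(1:9, function(k) {
      truth_k <- drawNullScore(sim$panel, 25, seed = 1000 * rep + k)
      em <- emitScoreFile(list(causal = truth_k,
                               proxy_pairs = sim$truth$proxy_pairs,
                               corruption = sim$truth$corruption),
                          sim$panel, pgsId = sprintf("PGS%03d", k),
                          seed = 1000 * rep + k)
      prs <- computePRS(harmonizeScoreSet(em$scoreset, em$panel), em$panel)
      evaluatePRS(prs, ph, model = "model1")@pValue
    }, numeric(1))
    adj <- bonferroniAdjust(pvals)
    clean_runs <- clean_runs + !any(adj$significant)
  }
  expect_gte(clean_runs, 5L)
})
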