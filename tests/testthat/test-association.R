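test_that("the intercept-only fit has the closed-form log-likelihood", {
  y <- c(0, 0, 1, 1)
  f <- fitLogistic(y, matrix(1, 4, 1))
  expect_equal(f$log_likelihood, 4 * log(0.5), tolerance = 1e-8)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-6)
  y2 <- c(0, 1, 1, 1)
  f2 <- fitLogistic(y2, matrix(1, 4, 1))
  expect_equal(f2$log_likelihood, 3 * log(0.75) + log(0.25),
               tolerance = 1e-8)
  expect_error(fitLogistic(rep(1, 5), matrix(1, 5, 1)), "constant")
})

test_that("2x2-table fits match the closed-form log-odds-ratio MLE", {
  cells <- c(5, 10, 20, 40)
  grid <- expand.grid(a = cells, b = cells, c = cells, d = cells)
  set.seed(1)
  for (i in sample(nrow(grid), 40)) {
    g <- grid[i, ]
    fx <- table2x2(g$a, g$b, g$c, g$d)
    f <- fitLogistic(fx$y, fx$design)
    expect_equal(unname(f$coefficients[2]), log(g$a * g$d / (g$b * g$c)),
                 tolerance = 1e-6, label = paste(g, collapse = ","))
    expect_equal(unname(f$coefficients[1]), log(g$c / g$d), tolerance = 1e-6)
    expect_equal(unname(f$standard_errors[2]),
                 sqrt(1 / g$a + 1 / g$b + 1 / g$c + 1 / g$d),
                 tolerance = 1e-6)
    expect_true(f$converged)
  }
  # OR 4 spot check
  fx <- table2x2(20, 10, 10, 20)
  expect_equal(unname(fitLogistic(fx$y, fx$design)$coefficients[2]), log(4),
               tolerance = 1e-6)
})

test_that("complete separation is flagged as non-converged", {
  y <- rep(c(0, 1), each = 20)
  x <- c(rnorm(20, -3), rnorm(20, 3))
  f <- fitLogistic(y, cbind(1, x))
  expect_false(f$converged)
})

test_that("Nagelkerke R2 reproduces the worked example and its limits", {
  ll0 <- 4 * log(0.5)
  expect_equal(1 - exp((2 / 4) * (ll0 - (-1))), 0.5878, tolerance = 1e-4)
  expect_equal(nagelkerkeR2(-1, ll0, 4), 0.7837, tolerance = 1e-4)
  expect_equal(nagelkerkeR2(ll0, ll0, 4), 0)
  expect_equal(nagelkerkeR2(-1e-12, ll0, 4), 1, tolerance = 1e-9)
  expect_error(nagelkerkeR2(-5, -1, 4), "nested")
  expect_equal(adjustedPrsR2(0.502, 0.222), 0.280)
  expect_equal(adjustedPrsR2(0.244, 0.222), 0.022)
})

## Shared fixture: simulated cohort with a planted score effect.
assoc_fixture <- function(n = 1500, or = 1.5, seed = 40, ...) {
  cfg <- simulationConfig(n_samples = n, n_variants = 300, n_causal = 40,
                          per_sd_or = or, seed = seed, ...)
  sim <- simulatePanel(cfg)
  ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
  em <- emitScoreFile(sim$truth, sim$panel, seed = seed)
  h <- harmonizeScoreSet(em$scoreset, em$panel)
  prs <- standardizePRS(computePRS(h, em$panel))
  list(prs = prs, ph = ph, truth = sim$truth)
}

test_that("evaluatePRS recovers a planted per-SD odds ratio", {
  fx <- assoc_fixture()
  res <- evaluatePRS(fx$prs, fx$ph, model = "model1")
  expect_true(res@converged)
  expect_gt(res@orPerSd, 1.25)
  expect_lt(res@orPerSd, 1.75)
  expect_true(res@ciLow < res@orPerSd && res@orPerSd < res@ciHigh)
  expect_lt(res@pValue, 1e-6)
  expect_gt(res@adjustedPrsR2, 0.01)
  expect_equal(res@r2Full - res@r2Null, res@adjustedPrsR2, tolerance = 1e-12)
  # model2 adds covariates that carry no signal here: conclusions agree
  res2 <- evaluatePRS(fx$prs, fx$ph, model = "model2")
  expect_lt(abs(res2@orPerSd - res@orPerSd), 0.1)
})

test_that("the odds ratio and R2 are invariant to covariate rescaling", {
  fx <- assoc_fixture(n = 800, seed = 41)
  res <- evaluatePRS(fx$prs, fx$ph, model = "model1")
  ph2 <- fx$ph
  ph2$age <- ph2$age * 1000
  ph2$weight <- ph2$weight / 500
  res2 <- evaluatePRS(fx$prs, ph2, model = "model1")
  expect_equal(res2@orPerSd, res@orPerSd, tolerance = 1e-5)
  expect_equal(res2@adjustedPrsR2, res@adjustedPrsR2, tolerance = 1e-6)
  expect_equal(res2@pValue, res@pValue, tolerance = 1e-4)
})

test_that("a null score contributes almost no incremental R2", {
  fx <- assoc_fixture(n = 2000, or = 1, seed = 42)
  res <- evaluatePRS(fx$prs, fx$ph, model = "model1")
  expect_lt(res@adjustedPrsR2, 0.005)
  expect_gt(res@pValue, 1e-4)
})

test_that("per-SD and raw OR scales agree through the score SD", {
  fx <- assoc_fixture(n = 600, seed = 43)
  raw_prs <- initialize(fx$prs)  # values are the raw scores
  res <- evaluatePRS(raw_prs, fx$ph, model = "model1", or_scale = "per_sd")
  v <- prsValues(raw_prs)
  s <- sqrt(mean((v - mean(v))^2))
  expect_equal(log(res@orPerSd), log(res@orRaw) * s, tolerance = 1e-10)
})

test_that("Bonferroni uses a strict alpha/m threshold", {
  adj <- bonferroniAdjust(rep(0.009, 9))
  expect_equal(adj$threshold, 0.05 / 9, tolerance = 1e-12)
  expect_false(any(adj$significant))       # 0.009 > 0.005556
  adj2 <- bonferroniAdjust(c(2.41e-78, rep(0.02, 8)))
  expect_identical(adj2$significant, c(TRUE, rep(FALSE, 8)))
  # exactly at the threshold is not significant (strict inequality)
  adj3 <- bonferroniAdjust(c(0.01, rep(0.5, 4)))
  expect_false(adj3$significant[1])
  expect_error(bonferroniAdjust(numeric(0)), "empty")
  expect_error(bonferroniAdjust(c(0.1, 0)), "p-values")
})

test_that("flagBonferroni fills the slot across a family of results", {
  fx <- assoc_fixture(n = 600, seed = 44)
  res <- lapply(c("model1", "model2"), function(m)
    evaluatePRS(fx$prs, fx$ph, model = m))
  flagged <- flagBonferroni(res)
  expect_true(all(vapply(flagged, function(r)
    is.logical(r@bonferroniSignificant) && !is.na(r@bonferroniSignificant),
    logical(1))))
  df <- do.call(rbind, lapply(flagged, as.data.frame))
  expect_identical(df$model, c("model1", "model2"))
})

test_that("PC covariates absorb structure-driven confounding", {
  cfg <- simulationConfig(n_samples = 400, n_variants = 600, fst = 0.1,
                          n_subpops = 2, n_causal = 40, per_sd_or = 1,
                          seed = 45)
  sim <- simulatePanel(cfg)
  ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
  # confound: shift disease prevalence by subpopulation
  set.seed(46)
  flip <- sim$truth$subpop == 2 & runif(400) < 0.25
  ph$case_status[flip] <- 1L
  em <- emitScoreFile(sim$truth, sim$panel, seed = 45)
  prs <- standardizePRS(computePRS(
    harmonizeScoreSet(em$scoreset, em$panel), em$panel))
  pcs <- computePCs(normalizeGenotypes(em$panel))
  res_no <- evaluatePRS(prs, ph, model = "model1")
  res_pc <- evaluatePRS(prs, ph, pcs = pcs, model = "model1")
  expect_gte(nSignificant(pcs), 1)
  expect_lt(res_pc@adjustedPrsR2, res_no@adjustedPrsR2 + 0.01)
})

test_that("evaluatePRS joins on sample id and rejects tiny overlaps", {
  fx <- assoc_fixture(n = 100, seed = 47)
  ph_half <- fx$ph[1:50, ]
  expect_message(res <- evaluatePRS(fx$prs, ph_half, model = "model1"),
                 "after join")
  expect_equal(res@n, 50L)
  expect_error(evaluatePRS(fx$prs, fx$ph[1:5, ], model = "model1"),
               "too few")
})
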