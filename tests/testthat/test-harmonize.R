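test_that("allele classification covers every orientation", {
  expect_equal(classifyAlleles("A", "G", ref = "G", alt = "A"), "exact")
  expect_equal(classifyAlleles("G", "A", ref = "G", alt = "A"), "switched")
  expect_equal(classifyAlleles("A", "G", ref = "C", alt = "T"), "flipped")
  expect_equal(classifyAlleles("G", "A", ref = "C", alt = "T"),
               "flipped_switched")
  expect_equal(classifyAlleles("A", "T", ref = "A", alt = "T"),
               "ambiguous_dropped")
  expect_equal(classifyAlleles("C", "G", ref = "G", alt = "C"),
               "ambiguous_dropped")
  expect_equal(classifyAlleles("A", "C", ref = "C", alt = "T"), "dropped")
  expect_error(classifyAlleles("A", "N", "G", "A"), "invalid allele")
})

test_that("flip classification agrees with a complement-table oracle", {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pairs <- expand.grid(e = names(comp), o = names(comp), r = names(comp),
                       a = names(comp), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$e != pairs$o & pairs$r != pairs$a, ]
  for (i in seq_len(nrow(pairs))) {
    with(pairs[i, ], {
      got <- classifyAlleles(e, o, r, a)
      pal <- comp[e] == o
      if (pal) {
        expect_equal(got, "ambiguous_dropped")
      } else if (e == a && o == r) {
        expect_equal(got, "exact")
      } else if (e == r && o == a) {
        expect_equal(got, "switched")
      } else if (comp[e] == a && comp[o] == r) {
        expect_equal(got, "flipped")
      } else if (comp[e] == r && comp[o] == a) {
        expect_equal(got, "flipped_switched")
      } else {
        expect_equal(got, "dropped")
      }
    })
  }
})

test_that("weights reverse on switches and survive flips", {
  expect_equal(alignWeight(0.3, "switched"), -0.3)
  expect_equal(alignWeight(0.3, "exact"), 0.3)
  expect_equal(alignWeight(0.3, "flipped"), 0.3)
  expect_equal(alignWeight(-0.2, "flipped_switched"), 0.2)
  expect_error(alignWeight(0.3, "dropped"), "non-usable")
})

proxy_fixture <- function() {
  # panel variants at 1:1000..1:5000; the score variant sits at 1:1500
  d <- matrix(rbinom(40 * 5, 2, 0.4), 40, 5)
  panel <- make_panel(d, ref = rep("G", 5), alt = rep("A", 5),
                      pos = c(1000L, 2000L, 3000L, 4000L, 5000L))
  sv <- data.frame(variant_id = "rsX", chrom = "1", pos = 1500L,
                   effect_allele = "A", other_allele = "G", weight = 0.4,
                   stringsAsFactors = FALSE)
  list(panel = panel, sv = sv)
}

test_that("proxy search picks the best r2 with the stated tie-breaks", {
  fx <- proxy_fixture()
  ld <- LDReference(data.frame(
    key_a = "1:1500", key_b = c("1:1000", "1:2000", "1:3000"),
    r2 = c(0.85, 0.95, 0.9)))
  got <- findProxy(fx$sv, fx$panel, ld)
  expect_equal(got$action, "proxied")
  expect_equal(got$panel_key, "1:2000")
  expect_equal(got$proxy_r2, 0.95)
  expect_equal(got$aligned_weight, 0.4)

  # tie on r2: nearer position wins, then lower position
  ld2 <- LDReference(data.frame(
    key_a = "1:1500", key_b = c("1:1000", "1:5000"), r2 = c(0.9, 0.9)))
  expect_equal(findProxy(fx$sv, fx$panel, ld2)$panel_key, "1:1000")
  ld3 <- LDReference(data.frame(
    key_a = "1:1500", key_b = c("1:1000", "1:2000"), r2 = c(0.9, 0.9)))
  expect_equal(findProxy(fx$sv, fx$panel, ld3)$panel_key, "1:1000")
})

test_that("proxies below the threshold or outside coverage are dropped", {
  fx <- proxy_fixture()
  ld <- LDReference(data.frame(key_a = "1:1500", key_b = "1:1000",
                               r2 = 0.6))
  got <- findProxy(fx$sv, fx$panel, ld)
  expect_equal(got$action, "dropped")
  expect_equal(got$reason, "no_proxy_above_r2_min")
  # r2 exactly at the threshold: strict inequality drops it
  ld08 <- LDReference(data.frame(key_a = "1:1500", key_b = "1:1000",
                                 r2 = 0.8))
  expect_equal(findProxy(fx$sv, fx$panel, ld08)$action, "dropped")
  ldNA <- LDReference(data.frame(key_a = character(), key_b = character(),
                                 r2 = numeric()))
  expect_equal(findProxy(fx$sv, fx$panel, ldNA)$reason, "no_ld_data")
})

test_that("a fully present ALT-oriented score harmonizes to all-exact", {
  d <- matrix(rbinom(30 * 8, 2, 0.3), 30, 8)
  panel <- make_panel(d)
  ss <- make_score(rnorm(8), effect = rep("A", 8), other = rep("G", 8))
  h <- harmonizeScoreSet(ss, panel)
  expect_true(all(auditTable(h)$action == "exact"))
  expect_equal(nDropped(h), 0)
  expect_equal(auditTable(h)$aligned_weight, scoreVariants(ss)$weight)
})

test_that("a fully swapped score is all-switched with negated weights", {
  d <- matrix(rbinom(30 * 8, 2, 0.3), 30, 8)
  panel <- make_panel(d)
  w <- rnorm(8)
  ss <- make_score(w, effect = rep("G", 8), other = rep("A", 8))
  h <- harmonizeScoreSet(ss, panel)
  expect_true(all(auditTable(h)$action == "switched"))
  expect_equal(auditTable(h)$aligned_weight, -w)
})

test_that("planted exact proxies rescue dropped markers without PRS change", {
  cfg <- simulationConfig(n_samples = 120, n_variants = 200, n_causal = 30,
                          seed = 11)
  sim <- simulatePanel(cfg)
  clean <- emitScoreFile(sim$truth, sim$panel, seed = 2)
  h0 <- harmonizeScoreSet(clean$scoreset, clean$panel)
  prs0 <- prsValues(computePRS(h0, clean$panel))

  em <- emitScoreFile(sim$truth, sim$panel,
                      corruption = c(drop_with_proxy = 0.2), seed = 2)
  h <- harmonizeScoreSet(em$scoreset, em$panel, ld_ref = em$ld_ref)
  acts <- auditTable(h)$action
  expect_equal(sum(acts == "proxied"), round(0.2 * 30))
  expect_equal(sum(!acts %in% c("exact", "proxied")), 0)
  prs1 <- prsValues(computePRS(h, em$panel))
  expect_equal(prs1, prs0, tolerance = 1e-12)
})

test_that("harmonizing an equivalent re-oriented score file gives an identical PRS", {
  set.seed(14)
  d <- matrix(rbinom(50 * 10, 2, 0.35), 50, 10)
  panel <- make_panel(d)
  w <- rnorm(10)
  ss <- make_score(w, effect = rep("A", 10), other = rep("G", 10))
  # same score stated from the other allele's perspective
  ss_swapped <- make_score(-w, effect = rep("G", 10), other = rep("A", 10))
  p1 <- prsValues(computePRS(harmonizeScoreSet(ss, panel), panel))
  p2 <- prsValues(computePRS(harmonizeScoreSet(ss_swapped, panel), panel))
  expect_equal(p1, p2, tolerance = 1e-14)
  # swap without restating the weight: scores negate, so between-individual
  # contrasts are preserved up to sign
  ss_swap_only <- make_score(w, effect = rep("G", 10), other = rep("A", 10))
  p3 <- prsValues(computePRS(harmonizeScoreSet(ss_swap_only, panel), panel))
  expect_equal(p3, -p1, tolerance = 1e-14)
})

test_that("harmonization is idempotent and deterministic", {
  cfg <- simulationConfig(n_samples = 80, n_variants = 100, n_causal = 25,
                          seed = 5)
  sim <- simulatePanel(cfg)
  em <- emitScoreFile(sim$truth, sim$panel,
                      corruption = c(allele_switch = 0.4, strand_flip = 0.2),
                      seed = 3)
  h1 <- harmonizeScoreSet(em$scoreset, em$panel)
  h2 <- harmonizeScoreSet(em$scoreset, em$panel)
  expect_identical(auditTable(h1), auditTable(h2))
  # re-harmonizing the already-aligned score is the identity on weights
  e <- auditTable(h1)
  vm <- variantMeta(em$panel)
  j <- match(e$panel_key, variantKeys(em$panel))
  aligned <- ScoreSet("PGS_ALIGNED", data.frame(
    variant_id = e$variant_id, chrom = vm$chrom[j], pos = vm$pos[j],
    effect_allele = vm$alt[j], other_allele = vm$ref[j],
    weight = e$aligned_weight, stringsAsFactors = FALSE))
  e2 <- auditTable(harmonizeScoreSet(aligned, em$panel))
  expect_true(all(e2$action == "exact"))
  expect_identical(e2$aligned_weight, e$aligned_weight)
})

test_that("palindromic variants drop by default but can be forced through", {
  d <- matrix(rbinom(30, 2, 0.3), 30, 1)
  panel <- make_panel(d, ref = "A", alt = "T")
  ss <- make_score(0.5, effect = "T", other = "A")
  h <- harmonizeScoreSet(ss, panel)
  expect_equal(auditTable(h)$action, "ambiguous_dropped")
  expect_equal(auditTable(h)$reason, "palindromic")
  h2 <- harmonizeScoreSet(ss, panel,
                          palindromic_policy = "assume-same-strand")
  expect_equal(auditTable(h2)$action, "exact")
})

test_that("rsID matching is the fallback when positions are absent", {
  d <- matrix(rbinom(30 * 3, 2, 0.3), 30, 3)
  panel <- make_panel(d, ids = c("rs10", "rs20", "rs30"))
  ss <- ScoreSet("PGS_ID", data.frame(
    variant_id = c("rs20", "rs99"), chrom = NA_character_, pos = NA_integer_,
    effect_allele = "A", other_allele = "G", weight = c(0.2, 0.1),
    stringsAsFactors = FALSE))
  h <- harmonizeScoreSet(ss, panel)
  e <- auditTable(h)
  expect_equal(e$action, c("exact", "dropped"))
  expect_equal(e$panel_key[1], "1:2000")
})

test_that("missing other_allele restricts matching to exact/switched", {
  d <- matrix(rbinom(30 * 2, 2, 0.3), 30, 2)
  panel <- make_panel(d, ref = c("G", "C"), alt = c("A", "T"))
  ss <- ScoreSet("PGS_NOA", data.frame(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(1000L, 2000L),
    effect_allele = c("A", "G"),       # v2 "G" only matches by complement
    other_allele = NA_character_, weight = c(0.3, 0.4),
    stringsAsFactors = FALSE))
  e <- auditTable(harmonizeScoreSet(ss, panel))
  expect_equal(e$action, c("exact", "dropped"))
})
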