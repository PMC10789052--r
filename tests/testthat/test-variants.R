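test_that("site filter applies the PASS AND (MQ or inbreeding) rule", {
  s <- site_filter(data.frame(
    filter = c("PASS", "PASS", "VQSRTrancheSNP99.90", "PASS", "PASS"),
    mq = c(25, 15, 60, 15, NA),
    inbreeding = c(0, -0.4, 0, -0.1, -0.5)
  ))
  expect_equal(s$site_pass, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_match(s$site_reason[3], "VQSR")
  expect_match(s$site_reason[4], "MQ")
})

test_that("genotype filter thresholds are strict and hom-ref exempt", {
  calls <- data.frame(
    gt = c(1L, 1L, 1L, 1L, 0L, 1L),
    ad_alt = c(6L, 10L, 5L, 6L, 0L, 3L),
    dp = c(20L, 10L, 20L, 20L, 40L, 0L),
    gq = c(30L, 99L, 30L, 20L, 99L, 99L)
  )
  f <- genotype_filter(calls)
  expect_equal(f$gt_pass, c(TRUE,   # 30% alt, DP 20, GQ 30
                            FALSE,  # DP = 10 exactly fails
                            FALSE,  # 25% alt exactly fails
                            FALSE,  # GQ = 20 exactly fails
                            TRUE,   # hom-ref exempt from alt fraction
                            FALSE)) # DP 0
  expect_match(f$gt_reason[6], "DP")
})

test_that("allele statistics are recalculated per population after filters", {
  subjects <- data.frame(subject = paste0("S", 1:5), population = "EUR")
  calls <- data.frame(
    site_id = "v1", subject = paste0("S", 1:5),
    gt = c(2L, 0L, 0L, 0L, 0L), gt_pass = TRUE
  )
  st <- recalc_stats(calls, subjects)
  expect_equal(st[st$population == "EUR", c("ac", "an", "af")],
               data.frame(ac = 2L, an = 10L, af = 0.2),
               ignore_attr = TRUE)

  # 755 passing subjects with 3 het carriers
  subjects2 <- data.frame(subject = paste0("S", 1:755), population = "EUR")
  calls2 <- data.frame(site_id = "v2", subject = subjects2$subject,
                       gt = c(rep(1L, 3), rep(0L, 752)), gt_pass = TRUE)
  st2 <- recalc_stats(calls2, subjects2)
  expect_equal(st2$an, 1510L)
  expect_equal(st2$ac, 3L)
  expect_equal(st2$af, 0.001987, tolerance = 1e-3)

  # all genotypes filtered: undefined, flagged
  calls3 <- data.frame(site_id = "v3", subject = subjects$subject,
                       gt = 1L, gt_pass = FALSE)
  st3 <- recalc_stats(calls3, subjects)
  expect_false(any(st3$defined))
  expect_true(all(is.na(st3$af)))
})

test_that("variant classes follow the novelty, rarity and coverage rules", {
  case <- data.frame(site_id = c("a", "b", "c"), population = "EUR",
                     ac = 3L, an = 1500L, af = 0.002, defined = TRUE)
  ctrl <- data.frame(site_id = c("a", "b", "c"), population = "EUR",
                     ac = c(0L, 15L, 250L), an = c(18978L, 18978L, 18978L),
                     coverage = c(45, 50, 50))
  cls <- classify_variants(case, ctrl)$class
  expect_equal(cls, c("novel", "rare", "common"))

  # absent control with poor coverage is discarded
  ctrl2 <- ctrl
  ctrl2$ac[1] <- 0L
  ctrl2$coverage[1] <- 12
  expect_equal(classify_variants(case, ctrl2)$class[1], "discard")

  # classification is total over random case/control pairs
  set.seed(44)
  caser <- data.frame(site_id = paste0("s", 1:50), population = "EUR",
                      ac = 3L, an = 1500L, af = 0.002, defined = TRUE)
  ctrlr <- data.frame(site_id = paste0("s", 1:50), population = "EUR",
                      ac = rbinom(50, 20, 0.3) * rbinom(50, 1, 0.6),
                      an = 2000L, coverage = runif(50, 5, 80))
  clsr <- classify_variants(caser, ctrlr)$class
  expect_true(all(clsr %in% c("novel", "rare", "common", "discard")))
  expect_length(clsr, 50)
})

test_that("C-score transform is the phred of the percentile rank", {
  expect_equal(round(cscore_from_rank(0.05), 2), 13.01)
  expect_equal(cscore_from_rank(0.01), 20)
  expect_equal(cscore_from_rank(1), 0)
  grid <- c(1e-6, 1e-3, 0.01, 0.05, 0.2, 0.5, 1)
  expect_equal(rank_from_cscore(cscore_from_rank(grid)), grid)
  expect_error(cscore_from_rank(0), "0, 1")
  expect_error(cscore_from_rank(1.5), "0, 1")
  expect_error(rank_from_cscore(-1), ">= 0")
})

test_that("deleteriousness selection is strict and per-population", {
  tbl <- mm_variant_table()
  expect_equal(nrow(tbl), 9)
  kept <- select_deleterious(tbl, 13.01)
  expect_equal(nrow(kept), 9)
  expect_equal(unname(attr(kept, "counts")["overall"]), 9)
  top1 <- select_deleterious(tbl, 20)
  expect_equal(sum(top1$population == "EUR"), 2)
  expect_equal(sum(top1$population == "MEX"), 4)
  expect_equal(nrow(select_deleterious(tbl, 100)), 0)
})

test_that("association builds the 2x2 tables and flags infinite OR", {
  # novel variant: case AC 3/1510 vs control 0/18978
  a <- associate(3, 1510, 0, 18978, mode = "allele")
  expect_true(a$or_infinite)
  expect_true(is.infinite(a$or))
  expect_gt(a$or_haldane, 1)

  # identical case/control proportions: OR exactly 1
  b <- associate(5, 100, 50, 1000, mode = "allele", sided = "two")
  expect_equal(b$or, 1)
  expect_gt(b$p, 0.9)

  # symmetry: swapping case and control inverts the OR
  d1 <- associate(8, 100, 4, 200, mode = "allele", sided = "two")
  d2 <- associate(4, 200, 8, 100, mode = "allele", sided = "two")
  expect_equal(d1$or, 1 / d2$or)
  expect_equal(d1$p, d2$p)

  expect_error(associate(0, 0, 5, 100, mode = "allele"), "degenerate")
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  set.seed(71)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    a1 <- associate(tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ]),
                    mode = "allele", sided = "one")
    expect_equal(a1$p, fisher_oracle(tab, "one"), tolerance = 1e-12)
    a2 <- associate(tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ]),
                    mode = "allele", sided = "two")
    expect_equal(a2$p, fisher_oracle(tab, "two"), tolerance = 1e-12)
  }
})

test_that("the filter cascade is order-stable", {
  coh <- sim_cohort(sim_config(seed = 31, cohort_n_cases = 40, n_sites = 25))
  sites <- site_filter(coh$sites)
  pass <- setNames(sites$site_pass, sites$site_id)

  # site filter then genotype filter
  c1 <- coh$calls[pass[coh$calls$site_id], ]
  c1 <- genotype_filter(c1)
  kept1 <- c1[c1$gt_pass, c("site_id", "subject")]

  # genotype filter then site filter
  c2 <- genotype_filter(coh$calls)
  c2 <- c2[pass[c2$site_id] & c2$gt_pass, c("site_id", "subject")]

  expect_equal(kept1[order(kept1$site_id, kept1$subject), ],
               c2[order(c2$site_id, c2$subject), ],
               ignore_attr = TRUE)
})

test_that("the full cascade recovers planted causal variants as novel", {
  cfg <- sim_config(seed = 33, cohort_n_cases = 150, n_sites = 40,
                    n_causal_sites = 5, causal_af = 0.03)
  coh <- sim_cohort(cfg)
  scores <- data.frame(
    site_id = coh$sites$site_id,
    cscore = ifelse(coh$sites$site_id %in% coh$truth$causal_sites, 25, 5)
  )
  res <- prioritize_variants(coh, coh$controls, scores,
                             cscore_threshold = 13.01)
  expect_true(all(res$site_id %in% coh$truth$causal_sites))
  expect_true(all(res$class == "novel"))
  expect_true(all(res$or_infinite))
  # most planted variants carried by >= 1 subject per population are found
  expect_gt(length(unique(res$site_id)), 2)
})
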