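test_that("annotation generator honours its contract and is deterministic", {
  cfg <- sim_config(seed = 1, n_genes = 50)
  genes <- sim_annotation(cfg)
  expect_equal(nrow(genes), 50)
  expect_setequal(unique(genes$strand), c("+", "-"))
  expect_true(all(genes$end - genes$start >= 2500))
  # non-overlap including 10 kb flanks
  expect_true(all(genes$start[-1] - genes$end[-50] >= 20000))
  expect_identical(genes, sim_annotation(sim_config(seed = 1, n_genes = 50)))
  expect_false(identical(genes,
                         sim_annotation(sim_config(seed = 2, n_genes = 50))))

  empty <- sim_annotation(sim_config(seed = 1, n_genes = 0))
  expect_equal(nrow(empty), 0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(empty, f)
  expect_equal(nrow(read_bed12(f)), 0)

  expect_error(sim_annotation(sim_config(seed = 1, n_genes = 100,
                                         genome_length = 1e5)),
               "cannot place")
})

test_that("BED12 round trip preserves the gene model", {
  genes <- sim_annotation(sim_config(seed = 4, n_genes = 12))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(genes, f)
  back <- read_bed12(f)
  for (col in c("gene_id", "chrom", "strand", "exon_sizes", "exon_starts")) {
    expect_equal(back[[col]], genes[[col]])
  }
  for (col in c("start", "end", "thick_start", "thick_end")) {
    expect_equal(as.numeric(back[[col]]), as.numeric(genes[[col]]))
  }
})

test_that("ChIP generator conserves the library and plants its effects", {
  cfg <- sim_config(seed = 5, n_genes = 60, library_size = 80000)
  genes <- sim_annotation(cfg)
  chip <- sim_chip(genes, cfg, "WT", 1)
  expect_equal(nrow(chip$fragments), cfg$library_size)
  expect_identical(chip$fragments,
                   sim_chip(genes, cfg, "WT", 1)$fragments)

  # occupancy_fold = 1 => WT and KO expected densities identical
  cfg1 <- sim_config(seed = 5, n_genes = 60, library_size = 80000,
                     occupancy_fold = 1)
  t_wt <- sim_chip(genes, cfg1, "WT", 1)$truth
  t_ko <- sim_chip(genes, cfg1, "KO", 1)$truth
  expect_equal(t_wt$expected_count, t_ko$expected_count)
  expect_equal(t_wt$promoter_density, t_ko$promoter_density)
})

test_that("planted 2-fold occupancy is realized within Poisson error", {
  # KO / WT realized counts over affected genes, across 20 seeds; the
  # multinomial library renormalization makes the exact expectation
  # 2 / (1 + affected_fraction * (fold - 1)) ~ 1.905 for 5% affected genes
  ratios <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 400 + s, n_genes = 100, library_size = 2e5,
                      occupancy_fold = 2)
    genes <- sim_annotation(cfg)
    regs <- derive_regions(genes)
    wt <- sim_chip(genes, cfg, "WT", 1)
    ko <- sim_chip(genes, cfg, "KO", 1)
    rc <- count_regions(list(WT = wt$fragments, KO = ko$fragments), regs)
    tot <- rc$counts$pi_body + rc$counts$promoter
    aff <- ko$truth$affected
    sum(tot[aff, "KO"]) / sum(tot[aff, "WT"])
  }, numeric(1))
  aff_frac <- mean(sim_chip(sim_annotation(sim_config(seed = 401,
                                                      n_genes = 100)),
                            sim_config(seed = 401, n_genes = 100),
                            "KO", 1)$truth$affected)
  expected_ratio <- 2 / (1 + aff_frac * (2 - 1))
  expect_true(abs(mean(ratios) - expected_ratio) < 0.05)
  expect_true(all(ratios > 1.7 & ratios < 2.1))
})

test_that("count generator matches its NB contract", {
  # near-zero dispersion behaves like Poisson: variance ~ mean
  cfg <- sim_config(seed = 11, n_genes = 100, n_samples_per_group = 25,
                    nb_dispersion = 1e-8, de_fraction = 0)
  sim <- sim_counts(cfg)
  m <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, var)
  keep <- m > 50
  expect_true(abs(median(v[keep] / m[keep]) - 1) < 0.25)

  expect_equal(sum(sim_counts(sim_config(seed = 3, n_genes = 50,
                                         de_fraction = 0))$truth$is_de), 0)

  sim2 <- sim_counts(sim_config(seed = 3, n_genes = 50, de_fraction = 0.2))
  anchor <- sim2$truth[sim2$truth$transcript_id == "Rn7sk", ]
  expect_equal(anchor$base_mean, anchor$ko_mean)
  expect_identical(sim2$counts$counts,
                   sim_counts(sim_config(seed = 3, n_genes = 50,
                                         de_fraction = 0.2))$counts$counts)
})

test_that("cohort generator plants causal alleles and quality structure", {
  cfg <- sim_config(seed = 9, cohort_n_cases = 80, n_sites = 40,
                    n_causal_sites = 0, causal_af = 0)
  expect_length(sim_cohort(cfg)$truth$causal_sites, 0)

  cfg2 <- sim_config(seed = 9, cohort_n_cases = 80, n_sites = 40,
                     genotype_fail_rate = 0)
  coh <- sim_cohort(cfg2)
  calls <- genotype_filter(coh$calls)
  stats <- recalc_stats(calls, coh$subjects)
  an_tot <- tapply(stats$an, stats$site_id, sum)
  expect_true(all(an_tot == 2 * cfg2$cohort_n_cases))

  # planted causal variants: control AC 0 with >= 30X coverage => novel
  ctrl <- coh$controls
  causal_ctrl <- ctrl[ctrl$site_id %in% coh$truth$causal_sites, ]
  expect_true(all(causal_ctrl$ac == 0))
  expect_true(all(causal_ctrl$coverage >= 30))
  cls <- classify_variants(stats, ctrl)
  causal_cls <- cls$class[cls$site_id %in% coh$truth$causal_sites &
                            cls$ac > 0]
  expect_true(all(causal_cls == "novel"))
})

test_that("litter generator renormalizes genotype fractions across lethality", {
  # lethality 0: KO fraction at weaning ~ the expected Mendelian 25%
  lit0 <- sim_litters(sim_config(seed = 21, litter_n = 4000, lethality = 0))
  f0 <- with(lit0$table, survived[genotype == "ko"] / sum(survived))
  expect_true(abs(f0 - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000))

  # lethality 0.6: closed-form weaning fraction 0.25*0.4/(0.75 + 0.25*0.4)
  lit6 <- sim_litters(sim_config(seed = 22, litter_n = 4000, lethality = 0.6))
  f6 <- with(lit6$table, survived[genotype == "ko"] / sum(survived))
  f_expect <- 0.25 * 0.4 / (0.75 + 0.25 * 0.4)
  expect_true(abs(f6 - f_expect) < 3 * sqrt(f_expect * (1 - f_expect) / 3400))

  # conservation and zero penetrance
  expect_equal(sum(lit6$table$conceived), 4000)
  expect_true(all(lit6$table$survived <= lit6$table$conceived))
  lp <- sim_litters(sim_config(seed = 23, litter_n = 1000, penetrance = 0,
                               wt_phenotype_rate = 0))
  expect_equal(sum(lp$table$phenotype), 0)
})

test_that("cohort VCF writer and reader round-trip genotype fields", {
  coh <- sim_cohort(sim_config(seed = 13, cohort_n_cases = 15, n_sites = 8))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(coh, f)
  back <- read_cohort_vcf(f, coh$subjects)
  ord <- function(d) {
    d <- d[order(d$site_id, d$subject), c("gt", "ad_ref", "ad_alt", "dp", "gq")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back$calls), ord(coh$calls))
  expect_equal(back$sites$filter, coh$sites$filter)
  expect_equal(back$sites$mq, coh$sites$mq, tolerance = 0.01)
})
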