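test_that("fragment midpoints are assigned to region windows", {
  g <- make_gene(start = 10000, end = 15000, strand = "+")
  regs <- derive_regions(g)
  rc <- count_regions(frags_at(10000 - 50), regs)
  expect_equal(unname(rc$counts$promoter[1, 1]), 1L)
  expect_equal(unname(rc$counts$gene_body[1, 1]), 0L)

  # uniform 1-fragment-per-bp coverage: counts proportional to lengths
  frs <- frags_at(seq(10000 - 10500, 15000 + 10500))
  rc2 <- count_regions(frs, regs)
  for (r in c("promoter", "gene_body", "tes_region", "upstream")) {
    expect_equal(unname(rc2$counts[[r]][1, 1]),
                 regs$length[regs$region == r])
  }
})

test_that("region counting agrees with a naive per-fragment oracle", {
  genes <- sim_annotation(sim_config(seed = 14, n_genes = 8))
  regs <- derive_regions(genes)
  set.seed(31)
  mids <- round(runif(500, 0, max(genes$end) + 15000))
  frs <- frags_at(mids)
  rc <- count_regions(frs, regs)
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    naive <- sum(mids >= r$start & mids < r$end)
    if (r$empty) naive <- 0L
    expect_equal(unname(rc$counts[[r$region]][r$gene_id, 1]), naive)
  }
})

test_that("FPKM arithmetic, guards and scale invariance hold", {
  expect_equal(fpkm(50, 500, 1e7), 10)
  expect_equal(fpkm(0, 500, 1e7), 0)
  expect_equal(fpkm(100, 500, 1e7), fpkm(200, 500, 2e7))
  expect_error(fpkm(1, 0, 1e6), "region_length")
  expect_error(fpkm(1, 500, 0), "total_mapped")
})

test_that("pausing index matches its defining formula and limits", {
  expect_equal(pausing_index(40, 4, L1 = 500, L2 = 2000), 40)
  # global count scaling leaves PI unchanged
  expect_equal(pausing_index(40 * 7, 4 * 7, L2 = 2000),
               pausing_index(40, 4, L2 = 2000))
  # constant density: standard PI = L2/L1, density-mode PI = 1
  dens <- 0.5
  f_p <- fpkm(dens * 500, 500, 1e6)
  f_b <- fpkm(dens * 2000, 2000, 1e6)
  expect_equal(pausing_index(f_p, f_b, L2 = 2000), 2000 / 500)
  expect_equal(pausing_index(f_p, f_b, L2 = 2000, mode = "density"), 1)
  # undefined exactly when the body FPKM is zero
  expect_true(is.na(pausing_index(10, 0, L2 = 2000)))
  expect_false(is.na(pausing_index(0, 10, L2 = 2000)))
  expect_error(pausing_index(-1, 5, L2 = 2000), "non-negative")
})

test_that("empirical density PI approaches 1 when pausing is absent", {
  cfg <- sim_config(seed = 16, n_genes = 80, library_size = 3e5,
                    pausing_level = 0, background_fraction = 0.02)
  genes <- sim_annotation(cfg)
  chip <- sim_chip(genes, cfg, "WT", 1)
  rc <- count_regions(list(S = chip$fragments), derive_regions(genes))
  pt <- pausing_table(rc, mode = "density")
  expect_true(abs(median(pt$pi, na.rm = TRUE) - 1) < 0.1)
})

test_that("pausing comparison handles nulls, point effects and degeneracy", {
  pi_wt <- matrix(c(2, 2, 2, 5, 5, 5), nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), paste0("WT_", 1:3)))
  pt_wt <- structure(list(pi = pi_wt), class = "pausing_table")
  pt_ko <- structure(list(pi = {
    m <- pi_wt
    colnames(m) <- paste0("KO_", 1:3)
    m
  }), class = "pausing_table")
  cp <- compare_pausing(pt_wt, pt_ko)
  expect_true(all(cp$table$p == 1))

  # PI doubled in all KO replicates with zero within-pair variance
  pt_ko2 <- structure(list(pi = {
    m <- pi_wt * 2
    colnames(m) <- paste0("KO_", 1:3)
    m
  }), class = "pausing_table")
  cp2 <- compare_pausing(pt_wt, pt_ko2)
  expect_true(all(cp2$table$p < 1e-10))

  expect_error(compare_pausing(
    structure(list(pi = pi_wt[, 1, drop = FALSE]), class = "pausing_table"),
    structure(list(pi = pi_wt[, 1, drop = FALSE]), class = "pausing_table")),
    "replicate pairs")

  # undefined PI in one sample excludes the gene with a message
  pi_na <- pi_wt
  pi_na[1, 2] <- NA
  expect_message(cp3 <- compare_pausing(
    structure(list(pi = pi_na), class = "pausing_table"), pt_ko),
    "excluded")
  expect_equal(cp3$table$gene_id, "b")
  expect_equal(cp3$excluded, "a")
})

test_that("pausing comparison keeps nominal type-I error under the null", {
  fr <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 300 + s, n_genes = 250, library_size = 2e5,
                      occupancy_fold = 1)
    genes <- sim_annotation(cfg)
    regs <- derive_regions(genes)
    ex <- sim_chip_experiment(genes, cfg)
    cp <- compare_pausing(pausing_table(count_regions(ex$samples[1:3], regs)),
                          pausing_table(count_regions(ex$samples[4:6], regs)))
    mean(cp$table$p < 0.05)
  }, numeric(1))
  expect_true(abs(mean(fr) - 0.05) < 0.02)
})

test_that("track scaling is per-bp per 10 million reads, and round-trips", {
  tr <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 250),
                   value = c(3, 3))
  expect_equal(scale_track(tr, 1e7)$value, c(3, 3))
  expect_equal(scale_track(tr, 2e7)$value, c(1.5, 1.5))
  expect_error(scale_track(tr, 0), "positive")

  f <- withr::local_tempfile(fileext = ".bedGraph")
  tr$value <- c(1.234567, 8.7654321)
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$value, tr$value, tolerance = 1e-6)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
})
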