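test_that("zero imputation is seeded, local and distribution-matched", {
  set.seed(3)
  mat <- matrix(rpois(600, 12) + 1, ncol = 6)
  expect_identical(impute_zeros(mat, seed = 1), mat)  # no zeros: unchanged

  mat[sample(length(mat), 150)] <- 0
  i1 <- impute_zeros(mat, seed = 5)
  i2 <- impute_zeros(mat, seed = 5)
  expect_identical(i1, i2)
  expect_false(identical(i1, impute_zeros(mat, seed = 6)))
  expect_identical(i1[mat > 0], mat[mat > 0])
  expect_true(all(i1[mat == 0] >= 0))

  # imputed mean matches the lowest-20% pool within 3 SE over many draws
  big <- matrix(c(rep(0, 1e4), rpois(2000, 15) + 1), ncol = 100)
  nz <- big[big > 0]
  pool <- nz[nz <= quantile(nz, 0.2)]
  imp <- impute_zeros(big, seed = 11)
  drawn <- imp[big == 0]
  # truncation at zero shifts the mean up slightly; bound accounts for it
  trunc_mean <- mean(pool) + sd(pool) *
    dnorm((0 - mean(pool)) / sd(pool)) /
    (1 - pnorm((0 - mean(pool)) / sd(pool)))
  expect_lt(abs(mean(drawn) - trunc_mean),
            3 * sd(pool) / sqrt(length(drawn)) + 0.05)

  expect_error(impute_zeros(matrix(0, 3, 3), 1), "all-zero")
})

test_that("bait normalization divides by the run's bait count", {
  mat <- rbind(p1 = c(10, 5), BAIT = c(10, 10))
  colnames(mat) <- c("r1", "r2")
  norm <- bait_normalize(mat)
  expect_equal(unname(norm["p1", ]), c(1.0, 0.5))
  expect_equal(unname(norm["BAIT", ]), c(1, 1))

  # scaling a whole run leaves normalized values unchanged
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 7
  expect_equal(bait_normalize(mat2), norm)

  bad <- rbind(p1 = c(1, 1), BAIT = c(5, 0))
  colnames(bad) <- c("r1", "r2")
  expect_error(bait_normalize(bad), "r2")

  # bait-free control runs are scaled by the mean bait of the bait runs
  withctl <- rbind(p1 = c(10, 20, 3), BAIT = c(10, 30, 0))
  colnames(withctl) <- c("b1", "b2", "ctl")
  n2 <- bait_normalize(withctl, bait_cols = c("b1", "b2"))
  expect_equal(unname(n2["p1", "ctl"]), 3 / 20)
  # idempotent at 1 on the bait row
  expect_equal(unname(bait_normalize(n2, bait_cols = 1:2)["BAIT", 1:2]),
               c(1, 1))
})

test_that("interactor calls require both p and ratio thresholds", {
  # construct preys with known ratio/p structure: 4 bait + 4 control runs
  set.seed(9)
  strong <- c(30, 31, 29, 30, 10, 10, 11, 10)     # ratio 3, tiny p
  weak_ratio <- c(14, 14.2, 13.8, 14, 10, 10, 10.1, 9.9)  # ratio 1.4, tiny p
  flat <- rep(10, 8)
  norm <- rbind(strong = strong, weak = weak_ratio, flat = flat)
  colnames(norm) <- c(paste0("b", 1:4), paste0("c", 1:4))
  raw <- norm  # all quantified
  res <- call_interactors(norm, raw, 1:4, 5:8)
  expect_true(res[res$prey == "strong", "high_confidence"])
  expect_false(res[res$prey == "weak", "high_confidence"])  # ratio <= 1.5
  expect_lt(res[res$prey == "weak", "p"], 0.05)
  expect_false(res[res$prey == "flat", "high_confidence"])

  # quantification rule: prey seen in < 3 runs of both conditions dropped
  raw2 <- raw
  raw2["strong", c(1, 2, 6, 7, 8)] <- 0
  res2 <- call_interactors(norm, raw2, 1:4, 5:8)
  expect_false(res2[res2$prey == "strong", "kept"])
  expect_false(res2[res2$prey == "strong", "high_confidence"])

  expect_error(call_interactors(norm, raw, 1:2, 5:8), ">= 3 replicates")
})

test_that("differential interactions need FDR < 0.05 and fold beyond 2", {
  set.seed(13)
  base <- matrix(rpois(800, 20), ncol = 8)
  rownames(base) <- sprintf("p%03d", 1:100)
  colnames(base) <- c(paste0("wt", 1:4), paste0("mut", 1:4))
  # identical conditions: nothing significant
  res0 <- compare_baits(base, base, 1:4, 5:8)
  expect_equal(sum(res0$significant), 0)

  # fold 1.8 with tight replicates: p small but fold below the threshold
  m <- rbind(f18 = c(rep(18, 4), rep(10, 4)) + rnorm(8, 0, 0.05),
             f4 = c(rep(40, 4), rep(10, 4)) + rnorm(8, 0, 0.5))
  colnames(m) <- colnames(base)
  res <- compare_baits(m, m, 1:4, 5:8)
  expect_false(res[res$prey == "f18", "significant"])
  expect_lt(res[res$prey == "f18", "fdr"], 0.05)
  expect_true(res[res$prey == "f4", "significant"])
})

test_that("the scoring pipeline recovers planted interactors", {
  sp <- sim_spectral(sim_config(seed = 5))
  imp <- impute_zeros(sp$matrix, seed = 9)
  norm <- bait_normalize(imp, bait_cols = 1:8, rescale = "mean_bait")
  ci <- call_interactors(norm, sp$matrix,
                         bait_cols = 1:4, control_cols = 9:12)
  tr <- sp$truth
  sens <- mean(ci$high_confidence[match(tr$prey[tr$interactor], ci$prey)])
  fpr <- mean(ci$high_confidence[match(tr$prey[!tr$interactor], ci$prey)])
  expect_gt(sens, 0.6)
  expect_lt(fpr, 0.05)

  # with no planted WT/mutant difference the differential test stays null
  sp0 <- sim_spectral(sim_config(seed = 6), differential_fraction = 0)
  imp0 <- impute_zeros(sp0$matrix, seed = 9)
  norm0 <- bait_normalize(imp0, bait_cols = 1:8, rescale = "mean_bait")
  res_null <- compare_baits(norm0, sp0$matrix, 1:4, 5:8)
  expect_lt(mean(res_null$significant), 0.05)
})
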