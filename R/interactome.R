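#' Impute spectral-count zeros
#'
#' Zeros (dropout non-observations) are replaced by draws from a normal
#' distribution whose mean and standard deviation match the lowest 20% of
#' the observed non-zero spectral counts, truncated at zero (counts cannot
#' be negative). Non-zero entries are untouched; imputation is seeded and
#' deterministic.
#'
#' @param mat Numeric spectral-count matrix (preys x runs).
#' @param seed Integer seed.
#' @return The matrix with zeros imputed.
#' @export
impute_zeros <- function(mat, seed = 1L) {
  nz <- mat[mat > 0]
  if (length(nz) == 0L) stop("all-zero spectral matrix", call. = FALSE)
  if (length(nz) < 5L) {
    stop("need >= 5 non-zero values to define the lowest-20% pool",
         call. = FALSE)
  }
  pool <- nz[nz <= quantile(nz, 0.2)]
  m <- mean(pool)
  s <- max(sd(pool), .Machine$double.eps)
  zeros <- which(mat == 0)
  if (length(zeros)) {
    draws <- with_seed(seed, {
      # inverse-CDF sampling from N(m, s) truncated at 0
      lo <- pnorm(0, m, s)
      qnorm(runif(length(zeros), lo, 1), m, s)
    })
    mat[zeros] <- draws
  }
  mat
}

#' Normalize spectral counts by the bait
#'
#' Divides every prey's count by the bait's spectral count in the same run,
#' making purification efficiencies comparable; the bait row becomes 1 in
#' every bait-containing run. Empty-vector control runs contain no bait, so
#' when `bait_cols` is given, runs outside it are divided by the mean bait
#' count of the bait runs instead — placing controls on the same
#' per-unit-bait scale rather than erroring. Without `bait_cols` every run
#' must have a positive bait count.
#'
#' @param mat Spectral-count matrix including the bait row.
#' @param bait Bait row name (default `"BAIT"`).
#' @param bait_cols Optional columns (names or indices) of bait-containing
#'   runs; remaining runs are scaled by the mean bait count of these.
#' @param rescale `"unit"` (default) leaves values in per-unit-bait form;
#'   `"mean_bait"` multiplies back by the mean bait count so values stay in
#'   spectral-count units (the bait row becomes the mean bait count), which
#'   keeps count-scale constants such as the `s0` stabilizer of
#'   [compare_baits()] meaningful.
#' @return The normalized matrix.
#' @export
bait_normalize <- function(mat, bait = "BAIT", bait_cols = NULL,
                           rescale = c("unit", "mean_bait")) {
  rescale <- match.arg(rescale)
  if (!bait %in% rownames(mat)) {
    stop("bait row '", bait, "' not found", call. = FALSE)
  }
  b <- mat[bait, ]
  denom <- b
  if (is.null(bait_cols)) {
    if (any(b <= 0)) {
      bad <- colnames(mat)[b <= 0] %||% which(b <= 0)
      stop("bait count is not positive in run(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    bb <- b[bait_cols]
    if (any(bb <= 0)) {
      bad <- colnames(mat)[bait_cols][bb <= 0] %||% which(bb <= 0)
      stop("bait count is not positive in bait run(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    is_bait_run <- if (is.character(bait_cols)) {
      colnames(mat) %in% bait_cols
    } else {
      seq_len(ncol(mat)) %in% bait_cols
    }
    denom[!is_bait_run] <- mean(bb)
  }
  out <- sweep(mat, 2, denom, "/")
  if (rescale == "mean_bait") {
    out <- out * mean(if (is.null(bait_cols)) b else b[bait_cols])
  }
  out
}

# preys quantified (non-zero) in >= min_quantified runs of either condition
keep_quantified <- function(raw, cols_a, cols_b, min_quantified = 3L) {
  qa <- rowSums(raw[, cols_a, drop = FALSE] > 0)
  qb <- rowSums(raw[, cols_b, drop = FALSE] > 0)
  qa >= min_quantified | qb >= min_quantified
}

#' Call high-confidence interactors against a control purification
#'
#' Preys quantified in at least `min_quantified` runs of either condition
#' are tested bait vs control with a two-tailed t test on the (imputed,
#' bait-normalized) values; a prey is a high-confidence interactor iff its
#' p value is below 0.05 and its mean spectral-count ratio over control
#' exceeds 1.5.
#'
#' @param norm Imputed, bait-normalized matrix.
#' @param raw The pre-imputation count matrix (for the quantification rule).
#' @param bait_cols,control_cols Column names or indices per condition
#'   (>= 3 replicates each).
#' @param min_quantified Quantification rule (default 3, "three out of
#'   four").
#' @param p_threshold,ratio_threshold Call thresholds (0.05 and 1.5).
#' @return Data frame: `prey`, `ratio`, `p`, `high_confidence`, `kept`.
#' @export
call_interactors <- function(norm, raw, bait_cols, control_cols,
                             min_quantified = 3L, p_threshold = 0.05,
                             ratio_threshold = 1.5) {
  if (length(bait_cols) < 3L || length(control_cols) < 3L) {
    stop("need >= 3 replicates per condition", call. = FALSE)
  }
  kept <- keep_quantified(raw, bait_cols, control_cols, min_quantified)
  a <- norm[, bait_cols, drop = FALSE]
  b <- norm[, control_cols, drop = FALSE]
  ratio <- rowMeans(a) / rowMeans(b)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (sd(a[i, ]) == 0 && sd(b[i, ]) == 0) {
      if (mean(a[i, ]) == mean(b[i, ])) 1 else 0
    } else {
      t.test(a[i, ], b[i, ])$p.value
    }
  }, numeric(1))
  data.frame(
    prey = rownames(norm),
    ratio = ratio, p = p,
    high_confidence = kept & p < p_threshold & ratio > ratio_threshold,
    kept = kept,
    stringsAsFactors = FALSE
  )
}

#' Differential interaction between two bait variants
#'
#' Two-tailed t statistic per prey with an additive zero-correction
#' stabilizer `s0` in the denominator (`t = (m1 - m2) / (se + s0)`),
#' Benjamini-Hochberg adjusted; a prey is significantly differential iff
#' FDR < 0.05 and the mean fold change exceeds 2 in either direction.
#'
#' @param norm Imputed, bait-normalized matrix.
#' @param raw Pre-imputation counts (quantification rule).
#' @param wt_cols,mut_cols Columns of the two bait conditions (>= 3 each).
#' @param s0 Additive stabilizer on the t denominator (default 0.1).
#' @param fdr_threshold,fold_threshold Call thresholds (0.05 and 2).
#' @param min_quantified Quantification rule (default 3).
#' @return Data frame: `prey`, `fold` (WT/mutant), `t`, `p`, `fdr`,
#'   `significant`, `kept`.
#' @export
compare_baits <- function(norm, raw, wt_cols, mut_cols, s0 = 0.1,
                          fdr_threshold = 0.05, fold_threshold = 2,
                          min_quantified = 3L) {
  if (length(wt_cols) < 3L || length(mut_cols) < 3L) {
    stop("need >= 3 replicates per condition", call. = FALSE)
  }
  kept <- keep_quantified(raw, wt_cols, mut_cols, min_quantified)
  a <- norm[, wt_cols, drop = FALSE]
  b <- norm[, mut_cols, drop = FALSE]
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var)
  v2 <- apply(b, 1, stats::var)
  n1 <- ncol(a)
  n2 <- ncol(b)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_stat <- (m1 - m2) / (se + s0)
  # Welch-Satterthwaite df from the unmoderated standard error
  df <- (v1 / n1 + v2 / n2)^2 /
    (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  df[!is.finite(df) | df <= 0] <- n1 + n2 - 2
  p <- 2 * pt(-abs(t_stat), df)
  fdr <- bh_fdr(p)
  fold <- m1 / m2
  data.frame(
    prey = rownames(norm),
    fold = fold, t = t_stat, p = p, fdr = fdr,
    significant = kept & fdr < fdr_threshold &
      (fold > fold_threshold | fold < 1 / fold_threshold),
    kept = kept,
    stringsAsFactors = FALSE
  )
}
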