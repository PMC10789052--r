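#' Differential Pol II occupancy between groups
#'
#' Tests one region type (e.g. promoter, gene body or TES window) for
#' differential fragment density between paired WT and KO replicates:
#'
#' 1. genes lacking signal in the KO group (a zero count in any KO
#'    replicate for the tested region) are filtered out;
#' 2. counts are normalized with edgeR's trimmed-mean-of-M (TMM) factors
#'    against the per-sample total mapped fragment counts;
#' 3. transformed to log2 counts per million with `limma::voom`;
#' 4. tested with the moderated t statistic of a paired design
#'    (`~ pair + group`);
#' 5. Benjamini-Hochberg adjusted, significant at `FDR < fdr`, direction by
#'    the sign of the KO-vs-WT log2 fold change.
#'
#' @param rc_wt,rc_ko `region_counts` objects with the same genes; columns
#'   are replicate-paired by position.
#' @param region Region name to test (must exist in both objects).
#' @param fdr Significance threshold on the adjusted p value (default 0.1).
#' @return Data frame of class `occupancy_diff`: `gene_id`, `log2fc`, `p`,
#'   `q`, `significant`, `direction` (`up`/`down`/`ns`), with attributes
#'   `norm_factors` and `filtered` (gene ids dropped by the KO-signal
#'   filter).
#' @export
differential_occupancy <- function(rc_wt, rc_ko, region, fdr = 0.1) {
  stopifnot(region %in% names(rc_wt$counts), region %in% names(rc_ko$counts))
  W <- rc_wt$counts[[region]]
  K <- rc_ko$counts[[region]]
  if (ncol(W) < 2L || ncol(W) != ncol(K)) {
    stop("need >= 2 replicate pairs with equal group sizes", call. = FALSE)
  }
  stopifnot(identical(rownames(W), rownames(K)))
  keep <- rowSums(K == 0) == 0
  filtered <- rownames(W)[!keep]
  empty <- data.frame(gene_id = character(0), log2fc = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("all genes filtered out (no KO signal in region '", region, "')")
    attr(empty, "filtered") <- filtered
    class(empty) <- c("occupancy_diff", "data.frame")
    return(empty)
  }
  Y <- cbind(W[keep, , drop = FALSE], K[keep, , drop = FALSE])
  n <- ncol(W)
  lib <- c(rc_wt$lib_sizes, rc_ko$lib_sizes)
  dge <- edgeR::DGEList(counts = Y, lib.size = as.numeric(lib))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  pair <- factor(rep(seq_len(n), 2))
  group <- factor(rep(c("WT", "KO"), each = n), levels = c("WT", "KO"))
  design <- model.matrix(~ pair + group)
  v <- limma::voom(dge, design)
  fit <- limma::lmFit(v, design)
  coef <- "groupKO"
  if (max(fit$sigma, na.rm = TRUE) < 1e-10 &&
      max(abs(fit$coefficients[, coef]), na.rm = TRUE) < 1e-10) {
    # degenerate identical-group input: no evidence of change anywhere
    log2fc <- fit$coefficients[, coef]
    p <- rep(1, nrow(Y))
  } else {
    fit <- limma::eBayes(fit)
    log2fc <- fit$coefficients[, coef]
    p <- fit$p.value[, coef]
  }
  q <- bh_fdr(p)
  out <- data.frame(
    gene_id = rownames(Y),
    log2fc = log2fc, p = p, q = q,
    significant = q < fdr,
    direction = ifelse(q < fdr, ifelse(log2fc > 0, "up", "down"), "ns"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "norm_factors") <- setNames(dge$samples$norm.factors,
                                        colnames(Y))
  attr(out, "filtered") <- filtered
  class(out) <- c("occupancy_diff", "data.frame")
  out
}

#' Summarize a differential-occupancy result
#'
#' @param diff An `occupancy_diff` data frame (or any data frame with
#'   `significant` and `log2fc` columns).
#' @return List: `n_significant`, `n_increased`, `n_decreased`.
#' @export
summarize_occupancy <- function(diff) {
  sig <- diff[diff$significant, , drop = FALSE]
  list(
    n_significant = nrow(sig),
    n_increased = sum(sig$log2fc > 0),
    n_decreased = sum(sig$log2fc < 0)
  )
}
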