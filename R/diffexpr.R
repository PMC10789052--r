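#' Filter transcripts by counts per million
#'
#' Keeps transcripts whose mean CPM across all samples is at least
#' `threshold` (strictly-less-than-threshold transcripts are removed). The
#' anchor transcript is always retained; if the anchor itself fails the
#' filter an error is raised, since it would be unusable for normalization.
#'
#' @param cm A [count_matrix()].
#' @param threshold CPM threshold (default 1).
#' @return The filtered `count_matrix`.
#' @export
cpm_filter <- function(cm, threshold = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  cpm <- sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
  keep <- rowMeans(cpm) >= threshold
  if (!keep[cm$anchor]) {
    stop("anchor transcript '", cm$anchor, "' fails the CPM filter",
         call. = FALSE)
  }
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm$gene_map <- cm$gene_map[cm$gene_map$transcript_id %in%
                               rownames(cm$counts), , drop = FALSE]
  cm
}

#' Anchor-gene normalization factors
#'
#' Implements the anchor (Pol III-transcribed gene, e.g. *Rn7sk*) count
#' normalization: for each sample the factor is the ratio of that sample's
#' anchor log2 CPM to the mean anchor log2 CPM across all samples,
#'
#' `f_s = log2CPM_s(anchor) / mean_s'(log2CPM_s'(anchor))`,
#'
#' and downstream analyses use the effective library size
#' `lib_size * f_s`. A sample where the anchor is relatively more abundant
#' gets a larger factor and hence smaller normalized expression values. The
#' factors average 1 when the anchor's relative abundance is identical
#' across samples. The ratio is of the log2 values themselves, not the log of a
#' ratio; it is ill-defined when any anchor log2 CPM is <= 0 (CPM <= 1),
#' which raises an error.
#'
#' @param cm A [count_matrix()].
#' @return List of class `anchor_factors`: `f` (named per-sample factors),
#'   `effective_lib` (lib size x factor), `anchor_log2cpm`.
#' @export
anchor_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  a <- cm$counts[cm$anchor, ]
  if (any(a <= 0)) {
    stop("anchor count must be > 0 in every sample", call. = FALSE)
  }
  log2cpm <- log2(a / cm$lib_sizes * 1e6)
  if (any(log2cpm <= 0)) {
    stop("anchor log2 CPM <= 0 in at least one sample; ",
         "the ratio-of-log2 normalization is ill-defined", call. = FALSE)
  }
  f <- log2cpm / mean(log2cpm)
  structure(list(f = f, effective_lib = cm$lib_sizes * f,
                 anchor_log2cpm = log2cpm),
            class = "anchor_factors")
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per-transcript NB generalized linear model with a group effect and
#' anchor-derived effective library sizes as offsets, tested with edgeR's
#' likelihood-ratio test (`glmFit`/`glmLRT`; dispersion from
#' `estimateDisp`). The anchor factors enter as edgeR normalization factors,
#' i.e. the effective library size of sample s is `lib_size_s * f_s`.
#'
#' @param cm A (filtered) [count_matrix()] with two group levels.
#' @param factors An [anchor_normalize()] result; `NULL` uses unit factors.
#' @param fdr Significance threshold on the BH-adjusted p (default 0.05).
#' @return Data frame of class `de_result`: `transcript_id`, `gene_id`,
#'   `log2fc` (second group vs first), `p`, `q`, `direction`
#'   (`up`/`down`/`ns`), `dispersion`.
#' @export
fit_nb_lrt <- function(cm, factors = NULL, fdr = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  if (nlevels(cm$groups) != 2L || min(table(cm$groups)) < 2L) {
    stop("need two groups with >= 2 samples each", call. = FALSE)
  }
  f <- if (is.null(factors)) rep(1, ncol(cm$counts)) else factors$f
  # order group levels so the reference is the first label encountered
  # (conventionally WT), making log2fc = second vs first
  grp <- factor(cm$groups, levels = unique(as.character(cm$groups)))
  dge <- edgeR::DGEList(counts = cm$counts,
                        lib.size = as.numeric(cm$lib_sizes),
                        norm.factors = as.numeric(f),
                        group = grp)
  design <- model.matrix(~ grp)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  tab <- lrt$table
  q <- bh_fdr(tab$PValue)
  gmap <- setNames(cm$gene_map$gene_id, cm$gene_map$transcript_id)
  out <- data.frame(
    transcript_id = rownames(cm$counts),
    gene_id = unname(gmap[rownames(cm$counts)]),
    log2fc = tab$logFC,
    p = tab$PValue,
    q = q,
    direction = ifelse(q < fdr, ifelse(tab$logFC > 0, "up", "down"), "ns"),
    dispersion = dge$tagwise.dispersion %||% dge$common.dispersion,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR control with enforced monotonicity (via
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Vector of q values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Gene-level summary of a differential-expression result
#'
#' Collapses significant transcripts to unique up-regulated, down-regulated
#' and both-direction gene sets, and reports the percentage of significant
#' transcripts in each direction (one decimal).
#'
#' @param de A `de_result` data frame (needs `transcript_id`, `gene_id`,
#'   `direction`).
#' @param gene_map Optional transcript -> gene data frame overriding the
#'   `gene_id` column.
#' @return List of class `gene_summary`: `up_genes`, `down_genes`,
#'   `both_genes`, `union_size`, `n_transcripts` (significant), `pct_up`,
#'   `pct_down`.
#' @export
summarize_genes <- function(de, gene_map = NULL) {
  if (!is.null(gene_map)) {
    gmap <- setNames(gene_map$gene_id, gene_map$transcript_id)
    unmapped <- setdiff(de$transcript_id[de$direction != "ns"], names(gmap))
    if (length(unmapped)) {
      stop("significant transcripts without a gene mapping: ",
           paste(head(unmapped, 5), collapse = ", "), call. = FALSE)
    }
    de$gene_id <- unname(gmap[de$transcript_id])
  }
  if (anyNA(de$gene_id[de$direction != "ns"])) {
    bad <- de$transcript_id[de$direction != "ns" & is.na(de$gene_id)]
    stop("significant transcripts without a gene mapping: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  up <- unique(de$gene_id[de$direction == "up"])
  down <- unique(de$gene_id[de$direction == "down"])
  both <- intersect(up, down)
  n_up_tx <- sum(de$direction == "up")
  n_down_tx <- sum(de$direction == "down")
  n_sig <- n_up_tx + n_down_tx
  structure(list(
    up_genes = up, down_genes = down, both_genes = both,
    union_size = length(union(up, down)),
    n_transcripts = n_sig,
    pct_up = if (n_sig) round(100 * n_up_tx / n_sig, 1) else NA_real_,
    pct_down = if (n_sig) round(100 * n_down_tx / n_sig, 1) else NA_real_
  ), class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat("gene_summary:", x$n_transcripts, "significant transcripts;",
      length(x$up_genes), "up /", length(x$down_genes), "down genes,",
      length(x$both_genes), "in both; union", x$union_size, "\n")
  cat(sprintf("  %.1f%% up, %.1f%% down among significant transcripts\n",
              x$pct_up, x$pct_down))
  invisible(x)
}
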