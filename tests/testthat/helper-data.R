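# shared fixture builders (all in code; nothing on disk)

# a bare gene model row without simulating a whole annotation
make_gene <- function(gene_id = "g1", start = 10000, end = 15000,
                      strand = "+", chrom = "chr1") {
  L <- end - start
  ex_sizes <- c(400, 400, L - floor(0.6 * L) - 0)  # 3 exons
  # simple 3-exon layout: first at 0, last ending at L
  s1 <- 0
  s2 <- floor(L * 0.4)
  s3 <- L - 500
  out <- data.frame(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand,
    thick_start = start + 200, thick_end = start + s3 + 250,
    exon_sizes = paste(c(400, 400, 500), collapse = ","),
    exon_starts = paste(c(s1, s2, s3), collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_model", "data.frame")
  out
}

# fragments with midpoints exactly at `mids` (fragment length 200)
frags_at <- function(mids, chrom = "chr1") {
  data.frame(chrom = chrom, start = mids - 100, end = mids + 100,
             stringsAsFactors = FALSE)
}

# count_matrix with explicit counts and an anchor row
make_cm <- function(counts, anchor = "anch", groups = NULL) {
  if (is.null(groups)) {
    groups <- rep(c("WT", "KO"), each = ncol(counts) / 2)
  }
  gene_map <- data.frame(transcript_id = rownames(counts),
                         gene_id = paste0("G_", rownames(counts)),
                         stringsAsFactors = FALSE)
  count_matrix(counts, gene_map, groups, anchor)
}

# brute-force BH step-up oracle, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # q of the i-th smallest p: min over j >= i of p_(j) * n / j
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# exhaustive hypergeometric enumeration oracle for Fisher's exact test
fisher_oracle <- function(tab, sided = c("one", "two")) {
  sided <- match.arg(sided)
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # case margin
  n <- sum(tab[2, ])   # control margin
  k <- sum(tab[, 1])   # first-column margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  if (sided == "one") {
    sum(probs[(lo:hi) >= a])
  } else {
    p_obs <- probs[a - lo + 1]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}
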