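#' Region scheme around TSS and TES
#'
#' Strand-aware window definitions, in transcript orientation, used for all
#' Pol II occupancy quantification. Offsets are relative to the transcription
#' start site (TSS) or end site (TES):
#'
#' * `promoter`: TSS-400 .. TSS+100 (always 500 bp)
#' * `gene_body`: TSS+100 .. TES-100
#' * `tes_region`: TES-100 .. TES+2000 (always 2,100 bp)
#' * `enhancer`: TSS-5000 .. TSS-400
#' * `upstream`: TSS-10000 .. TSS
#' * `downstream`: TSS .. TSS+10000
#' * `pi_body`: TSS+100 .. TES+2000 (the pausing-index gene-body window)
#'
#' @return Data frame with columns `region`, `from_anchor`, `from`,
#'   `to_anchor`, `to`.
#' @export
region_scheme <- function() {
  data.frame(
    region = c("promoter", "gene_body", "tes_region", "enhancer",
               "upstream", "downstream", "pi_body"),
    from_anchor = c("tss", "tss", "tes", "tss", "tss", "tss", "tss"),
    from = c(-400, 100, -100, -5000, -10000, 0, 100),
    to_anchor = c("tss", "tes", "tes", "tss", "tss", "tss", "tes"),
    to = c(100, -100, 2000, -400, 0, 10000, 2000),
    stringsAsFactors = FALSE
  )
}

#' Derive genomic region windows for each gene
#'
#' Offsets are applied in transcription orientation and then mapped to
#' genome coordinates (0-based half-open), so the promoter is always exactly
#' 500 bp on either strand. A region whose end does not exceed its start
#' (e.g. the gene body of a gene shorter than 200 bp) is flagged `empty`
#' rather than raising an error; windows running off the chromosome start
#' are clipped and flagged.
#'
#' @param genes A `gene_model` data frame ([sim_annotation()] or
#'   [read_bed12()]).
#' @param scheme A scheme data frame; defaults to [region_scheme()].
#' @return Data frame: `gene_id`, `region`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `empty`, `clipped`.
#' @examples
#' genes <- sim_annotation(sim_config(seed = 1, n_genes = 5))
#' regs <- derive_regions(genes)
#' all(regs$length[regs$region == "promoter"] == 500)
#' @export
derive_regions <- function(genes, scheme = region_scheme()) {
  n <- nrow(genes)
  k <- nrow(scheme)
  if (n == 0L) {
    return(data.frame(gene_id = character(0), region = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      length = numeric(0), empty = logical(0),
                      clipped = logical(0), stringsAsFactors = FALSE))
  }
  L <- rep(genes$end - genes$start, k)
  gi <- rep(seq_len(n), k)
  ri <- rep(seq_len(k), each = n)
  from_t <- ifelse(scheme$from_anchor[ri] == "tss", scheme$from[ri],
                   L + scheme$from[ri])
  to_t <- ifelse(scheme$to_anchor[ri] == "tss", scheme$to[ri],
                 L + scheme$to[ri])
  plus <- genes$strand[gi] == "+"
  g_start <- ifelse(plus, genes$start[gi] + from_t, genes$end[gi] - to_t)
  g_end <- ifelse(plus, genes$start[gi] + to_t, genes$end[gi] - from_t)
  empty <- to_t <= from_t
  clipped <- g_start < 0 & !empty
  g_start <- pmax(g_start, 0)
  g_end <- pmax(g_end, g_start)
  out <- data.frame(
    gene_id = genes$gene_id[gi],
    region = scheme$region[ri],
    chrom = genes$chrom[gi],
    start = g_start, end = g_end,
    strand = genes$strand[gi],
    length = ifelse(empty, 0, g_end - g_start),
    empty = empty, clipped = clipped,
    stringsAsFactors = FALSE
  )
  out[order(match(out$gene_id, genes$gene_id), match(out$region,
                                                     scheme$region)), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write derived regions as BED6
#'
#' @param regions Output of [derive_regions()].
#' @param path Output file; empty regions are skipped.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  r <- regions[!regions$empty, , drop = FALSE]
  bed <- data.frame(r$chrom, r$start, r$end,
                    paste(r$gene_id, r$region, sep = "|"), 0L, r$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# exon intervals of one gene in genome coordinates (0-based half-open)
exon_intervals <- function(gene) {
  sizes <- as.numeric(strsplit(gene$exon_sizes, ",")[[1]])
  starts <- as.numeric(strsplit(gene$exon_starts, ",")[[1]])
  data.frame(start = gene$start + starts, end = gene$start + starts + sizes)
}

# assemble per-category interval sets across all genes for peak annotation
peak_category_ranges <- function(genes, scheme = region_scheme()) {
  regs <- derive_regions(genes, scheme)
  pick <- function(name) {
    r <- regs[regs$region == name & !regs$empty, , drop = FALSE]
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               gene = r$gene_id, stringsAsFactors = FALSE)
  }
  cats <- list()
  cats$promoter <- pick("promoter")
  exon_list <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exon_intervals(g)
    cds <- c(g$thick_start, g$thick_end)
    # exon pieces split by CDS bounds into UTR and coding parts
    clip <- function(a, b) {
      s <- pmax(ex$start, a); e <- pmin(ex$end, b)
      keep <- s < e
      data.frame(start = s[keep], end = e[keep])
    }
    left <- clip(g$start, cds[1])    # exonic, 5' of CDS in genome coords
    right <- clip(cds[2], g$end)     # exonic, 3' of CDS in genome coords
    coding <- clip(cds[1], cds[2])
    utr5 <- if (g$strand == "+") left else right
    utr3 <- if (g$strand == "+") right else left
    mk <- function(d, cat) {
      if (nrow(d) == 0) return(NULL)
      data.frame(chrom = g$chrom, start = d$start, end = d$end,
                 gene = g$gene_id, cat = cat, stringsAsFactors = FALSE)
    }
    rbind(mk(utr5, "utr5"), mk(utr3, "utr3"), mk(coding, "exon"))
  })
  exon_df <- do.call(rbind, exon_list)
  for (cat in c("utr5", "utr3", "exon")) {
    d <- exon_df[exon_df$cat == cat, c("chrom", "start", "end", "gene")]
    cats[[cat]] <- d
  }
  gene_span <- data.frame(chrom = genes$chrom, start = genes$start,
                          end = genes$end, gene = genes$gene_id,
                          stringsAsFactors = FALSE)
  cats$intron <- gene_span  # resolved after exonic categories by priority
  cats$tes_downstream <- pick("tes_region")
  cats$enhancer <- pick("enhancer")
  cats
}

peak_categories <- function() {
  c("promoter", "utr5", "utr3", "exon", "intron", "tes_downstream",
    "enhancer", "intergenic")
}

#' Annotate peaks with a gene-region category
#'
#' Each peak is assigned exactly one of `promoter`, `utr5`, `utr3`, `exon`,
#' `intron`, `tes_downstream`, `enhancer`, `intergenic` by the membership of
#' its midpoint, with the fixed priority order promoter > 5'UTR > 3'UTR >
#' exon > intron > TES/downstream > enhancer > intergenic. When the midpoint
#' falls in windows of several genes at equal priority, the gene with the
#' nearest TSS wins. Peaks on chromosomes absent from the annotation are
#' labelled `intergenic` with a warning.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes A `gene_model` data frame.
#' @return `peaks` with added `category` and `gene_id` columns (`gene_id` is
#'   `NA` for intergenic peaks).
#' @export
annotate_peaks <- function(peaks, genes) {
  if (nrow(peaks) == 0L) {
    peaks$category <- character(0)
    peaks$gene_id <- character(0)
    return(peaks)
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  category <- rep("intergenic", nrow(peaks))
  gene_hit <- rep(NA_character_, nrow(peaks))
  if (nrow(genes) > 0L) {
    unknown <- !(peaks$chrom %in% genes$chrom)
    if (any(unknown)) {
      warning(sum(unknown), " peak(s) on chromosomes absent from the ",
              "annotation; labelled intergenic")
    }
    cats <- peak_category_ranges(genes)
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    names(tss) <- genes$gene_id
    prio <- setNames(seq_along(peak_categories()), peak_categories())
    peak_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
    best_prio <- rep(Inf, nrow(peaks))
    best_dist <- rep(Inf, nrow(peaks))
    for (cat in names(cats)) {
      d <- cats[[cat]]
      if (is.null(d) || nrow(d) == 0) next
      gr <- GenomicRanges::GRanges(
        d$chrom, IRanges::IRanges(start = d$start + 1L, end = d$end))
      hits <- suppressWarnings(GenomicRanges::findOverlaps(peak_gr, gr))
      if (length(hits) == 0) next
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      dist <- abs(mid[q] - tss[d$gene[s]])
      p <- prio[[cat]]
      better <- p < best_prio[q] | (p == best_prio[q] & dist < best_dist[q])
      # resolve duplicates per query: iterate hits in order, keep improving
      for (j in which(better)) {
        i <- q[j]
        if (p < best_prio[i] || (p == best_prio[i] && dist[j] < best_dist[i])) {
          best_prio[i] <- p
          best_dist[i] <- dist[j]
          category[i] <- cat
          gene_hit[i] <- d$gene[s[j]]
        }
      }
    }
  }
  peaks$category <- category
  peaks$gene_id <- gene_hit
  peaks
}

#' Tabulate peak counts by gene-region category
#'
#' @inheritParams annotate_peaks
#' @return Named integer vector over all eight categories (zeros included);
#'   sums to `nrow(peaks)`.
#' @export
peak_distribution <- function(peaks, genes) {
  ann <- annotate_peaks(peaks, genes)
  tab <- table(factor(ann$category, levels = peak_categories()))
  out <- as.integer(tab)
  names(out) <- peak_categories()
  out
}
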