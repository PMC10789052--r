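#' Metagene occupancy profile
#'
#' Bins normalized fragment coverage over each gene from TSS-`flank` to
#' TES+`flank`, in transcription orientation: both flanks in fixed
#' `flank_bin`-bp bins (20 each at the defaults) and the gene body rescaled
#' to `body_bins` equal fractional bins, for 100 bins in total. Bin values
#' are FPKM-like (fragments per kb of bin per million mapped); the profile
#' is the across-gene mean with its standard error. Genes with a body
#' shorter than `body_bins` bp are excluded and reported.
#'
#' @param genes A `gene_model` data frame.
#' @param fragments Fragment data frame (`chrom`, `start`, `end`).
#' @param total_mapped Library size; defaults to `nrow(fragments)`.
#' @param flank Flank size in bp (default 2000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param body_bins Number of scaled gene-body bins (default 60).
#' @return List of class `metagene_profile`: `mean`, `se` (length
#'   `2 * flank/flank_bin + body_bins`), `n_genes`, `excluded`.
#' @export
metagene <- function(genes, fragments, total_mapped = nrow(fragments),
                     flank = 2000, flank_bin = 100, body_bins = 60) {
  n_flank <- flank / flank_bin
  n_bins <- as.integer(2 * n_flank + body_bins)
  L <- genes$end - genes$start
  eligible <- L >= body_bins
  excluded <- genes$gene_id[!eligible]
  if (length(excluded)) {
    message(length(excluded), " gene(s) shorter than ", body_bins,
            " bp excluded from the metagene profile")
  }
  genes <- genes[eligible, , drop = FALSE]
  L <- L[eligible]
  if (nrow(genes) == 0L) {
    stop("no genes eligible for the metagene profile", call. = FALSE)
  }
  win_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - flank, 0) + 1L,
                     end = genes$end + flank)
  )
  mid <- floor((fragments$start + fragments$end) / 2)
  mid_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mid_gr, win_gr))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  plus <- genes$strand[g] == "+"
  # transcript-orientation offset from the start of the upstream flank
  d <- ifelse(plus,
              mid[q] - (genes$start[g] - flank),
              (genes$end[g] + flank - 1) - mid[q])
  bin <- integer(length(d))
  up <- d < flank
  body <- d >= flank & d < flank + L[g]
  down <- d >= flank + L[g]
  bin[up] <- d[up] %/% flank_bin + 1L
  bin[body] <- n_flank + 1L +
    floor((d[body] - flank) / L[g][body] * body_bins)
  bin[down] <- n_flank + body_bins +
    (d[down] - flank - L[g][down]) %/% flank_bin + 1L
  bin <- pmin(pmax(bin, 1L), n_bins)

  tab <- table(factor(g, levels = seq_len(nrow(genes))),
               factor(bin, levels = seq_len(n_bins)))
  cnt <- matrix(as.numeric(tab), nrow(genes), n_bins)
  width <- matrix(flank_bin, nrow(genes), n_bins)
  width[, (n_flank + 1):(n_flank + body_bins)] <- L / body_bins
  val <- cnt * 1e9 / (width * total_mapped)
  structure(list(
    mean = colMeans(val),
    se = apply(val, 2, sd) / sqrt(nrow(val)),
    n_genes = nrow(genes),
    excluded = excluded,
    bins = n_bins
  ), class = "metagene_profile")
}

#' TSS-centred binned peak-count profile
#'
#' Counts peak (or fragment) midpoints in `bins` fixed-width bins centred on
#' the TSS, summed over genes and oriented by strand. With the defaults (51
#' bins of 400 bp) the centre bin (bin 26) spans TSS-200 .. TSS+200, so the
#' profile covers TSS +/- 10.2 kb.
#'
#' @param genes A `gene_model` data frame.
#' @param peaks Data frame `chrom`, `start`, `end` of peaks or fragments.
#' @param bins Number of bins (odd; default 51).
#' @param bin_width Bin width in bp (default 400).
#' @return Integer vector of length `bins`.
#' @export
tss_profile <- function(genes, peaks, bins = 51L, bin_width = 400L) {
  stopifnot(bins %% 2 == 1)
  if (nrow(genes) == 0L) stop("no genes supplied", call. = FALSE)
  out <- integer(bins)
  if (nrow(peaks) == 0L) return(out)
  half_span <- (bins / 2) * bin_width
  mid <- floor((peaks$start + peaks$end) / 2)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  win_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(tss - half_span, 0) + 1L,
                     end = tss + half_span)
  )
  mid_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mid_gr, win_gr))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  rel <- ifelse(genes$strand[g] == "+", mid[q] - tss[g], tss[g] - mid[q])
  centre <- (bins + 1L) %/% 2L
  bin <- centre + floor((rel + bin_width / 2) / bin_width)
  bin <- bin[bin >= 1 & bin <= bins]
  tab <- tabulate(bin, nbins = bins)
  as.integer(tab)
}
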