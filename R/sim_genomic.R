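#' Simulate a gene annotation
#'
#' Places non-overlapping genes on a single chromosome, on both strands,
#' with at least 10 kb between neighbouring genes so that every derived
#' region window (up to +/- 10 kb around TSS/TES) is gene-specific. Gene
#' bodies are at least 2,500 bp, so no region of the default scheme is
#' degenerate. Each gene receives 2-8 exons and CDS bounds strictly inside
#' the first and last exon, so 5'/3' UTRs exist for peak annotation.
#'
#' @param config A [sim_config()].
#' @return A `gene_model` data frame (0-based half-open coordinates) with
#'   columns `gene_id`, `chrom`, `start`, `end`, `strand`, `thick_start`,
#'   `thick_end`, `exon_sizes`, `exon_starts` (BED12 block encoding).
#' @examples
#' genes <- sim_annotation(sim_config(seed = 1, n_genes = 10))
#' nrow(genes)
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(empty_gene_model())
  }
  with_seed(derive_seed(config$seed, "annotation"), {
    len <- round(runif(n, 2500, 8000))
    gap <- round(runif(n, 21000, 26000))
    start <- 10000 + cumsum(c(0, (len + gap)[-n]))
    end <- start + len
    if (end[n] + 10000 > config$genome_length) {
      stop("cannot place ", n, " genes plus 10 kb flanks in a genome of ",
           config$genome_length, " bp", call. = FALSE)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (n >= 2L && length(unique(strand)) == 1L) {
      strand[1L] <- setdiff(c("+", "-"), strand[1L])
    }
    blocks <- lapply(len, sim_exon_blocks)
    exon_sizes <- vapply(blocks, function(b) paste(b$sizes, collapse = ","),
                         character(1))
    exon_starts <- vapply(blocks, function(b) paste(b$starts, collapse = ","),
                          character(1))
    thick_start <- start + vapply(blocks, `[[`, numeric(1), "cds_from")
    thick_end <- start + vapply(blocks, `[[`, numeric(1), "cds_to")
    out <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = "chr1",
      start = start,
      end = end,
      strand = strand,
      thick_start = thick_start,
      thick_end = thick_end,
      exon_sizes = exon_sizes,
      exon_starts = exon_starts,
      stringsAsFactors = FALSE
    )
    class(out) <- c("gene_model", "data.frame")
    out
  })
}

empty_gene_model <- function() {
  out <- data.frame(
    gene_id = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), strand = character(0),
    thick_start = numeric(0), thick_end = numeric(0),
    exon_sizes = character(0), exon_starts = character(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_model", "data.frame")
  out
}

# exon block layout for one gene of length L (gene-relative, BED12 style):
# first block starts at 0 and last block ends at L.
sim_exon_blocks <- function(L) {
  k <- sample(2:8, 1L)
  sizes <- round(runif(k, 100, 500))
  while (sum(sizes) > 0.6 * L) sizes <- ceiling(sizes / 2)
  introns <- runif(k - 1L)
  introns <- introns / sum(introns) * (L - sum(sizes))
  introns <- floor(introns)
  starts <- cumsum(c(0, (sizes[-k] + introns)))
  # absorb rounding slack into the final exon so the last block ends at L
  sizes[k] <- L - starts[k]
  list(sizes = sizes, starts = starts,
       cds_from = starts[1L] + ceiling(sizes[1L] / 2),
       cds_to = starts[k] + floor(sizes[k] / 2))
}

#' Write / read gene models as BED12
#'
#' Coordinates are written as-is (the package already uses the 0-based
#' half-open BED convention internally).
#'
#' @param genes A `gene_model` data frame.
#' @param path Output file.
#' @return `write_bed12` returns `path` invisibly; `read_bed12` returns a
#'   `gene_model` data frame.
#' @export
write_bed12 <- function(genes, path) {
  n <- nrow(genes)
  block_count <- if (n) {
    vapply(strsplit(genes$exon_sizes, ","), length, integer(1))
  } else {
    integer(0)
  }
  bed <- data.frame(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = rep(0L, n), strand = genes$strand,
    thickStart = genes$thick_start, thickEnd = genes$thick_end,
    itemRgb = rep("0", n), blockCount = block_count,
    blockSizes = genes$exon_sizes, blockStarts = genes$exon_starts,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  if (file.size(path) == 0) {
    return(empty_gene_model())
  }
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  exon_sizes <- vapply(seq_along(gr), function(i) {
    paste(IRanges::width(blocks[[i]]), collapse = ",")
  }, character(1))
  exon_starts <- vapply(seq_along(gr), function(i) {
    paste(IRanges::start(blocks[[i]]) - 1L, collapse = ",")
  }, character(1))
  out <- data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    thick_start = GenomicRanges::start(gr$thick) - 1L,
    thick_end = GenomicRanges::end(gr$thick),
    exon_sizes = exon_sizes,
    exon_starts = exon_starts,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_model", "data.frame")
  out
}

#' Simulate ChIP fragments for one sample
#'
#' Fragments are drawn from a per-gene mixture of a TSS-proximal component
#' (the promoter window, TSS-400..TSS+100, with density `(1 + pausing_level)`
#' times the body density) and a uniform component over the transcribed
#' region plus 2 kb of termination read-through (TSS+100..TES+2000), plus a
#' uniform intergenic background. In the KO group the expected fragment
#' count of affected genes is multiplied by `occupancy_fold`. Fragment
#' counts per sample sum exactly to `library_size`.
#'
#' Gene baseline weights and the affected-gene subset are derived from the
#' config seed alone, so they are identical in all samples of both groups.
#'
#' @param genes Gene model from [sim_annotation()].
#' @param config A [sim_config()].
#' @param group `"WT"` or `"KO"`.
#' @param replicate Replicate index (changes only the sampling stream).
#' @return A list with `fragments` (data frame `chrom`, `start`, `end`;
#'   fixed length `config$fragment_length`) and `truth` (per-gene expected
#'   counts and densities, affected flag and applied fold).
#' @export
sim_chip <- function(genes, config, group = c("WT", "KO"), replicate = 1L) {
  stopifnot(inherits(config, "sim_config"), nrow(genes) > 0)
  group <- match.arg(group)
  n <- nrow(genes)
  L <- genes$end - genes$start

  gs <- derive_seed(config$seed, "chip-genes")
  gene_pars <- with_seed(gs, {
    w <- rlnorm(n, meanlog = 0, sdlog = 0.5)
    n_aff <- round(config$affected_fraction * n)
    aff <- rep(FALSE, n)
    if (n_aff > 0) aff[sample.int(n, n_aff)] <- TRUE
    list(w = w, affected = aff)
  })
  w <- gene_pars$w
  fold <- ifelse(gene_pars$affected & group == "KO", config$occupancy_fold, 1)
  w_eff <- w * fold

  n_bg <- round(config$background_fraction * config$library_size)
  n_gene_total <- config$library_size - n_bg
  share <- w_eff / sum(w_eff)
  expected <- n_gene_total * share

  # promoter window carries (1 + pausing_level) x body density over 500 bp;
  # body component spans TSS+100 .. TES+2000 (length L + 1900)
  p_prom <- ((1 + config$pausing_level) * 500) /
    ((1 + config$pausing_level) * 500 + (L + 1900))

  ss <- derive_seed(config$seed, paste0("chip-", group, "-", replicate))
  frags <- with_seed(ss, {
    counts <- as.vector(rmultinom(1, n_gene_total, share))
    n_prom <- rbinom(n, counts, p_prom)
    n_body <- counts - n_prom
    gene_idx <- c(rep(seq_len(n), n_prom), rep(seq_len(n), n_body))
    in_prom <- c(rep(TRUE, sum(n_prom)), rep(FALSE, sum(n_body)))
    # transcript-coordinate offsets relative to TSS
    off <- numeric(length(gene_idx))
    off[in_prom] <- runif(sum(n_prom), -400, 100)
    off[!in_prom] <- runif(sum(n_body), 100, L[gene_idx[!in_prom]] + 2000)
    plus <- genes$strand[gene_idx] == "+"
    mid <- ifelse(plus,
                  genes$start[gene_idx] + off,
                  genes$end[gene_idx] - off)
    mid <- c(mid, runif(n_bg, 0, config$genome_length))
    mid <- floor(mid)
    half <- config$fragment_length %/% 2L
    start <- pmax(0, mid - half)
    data.frame(chrom = "chr1", start = start,
               end = start + config$fragment_length,
               stringsAsFactors = FALSE)[order(start), ]
  })
  rownames(frags) <- NULL

  truth <- data.frame(
    gene_id = genes$gene_id,
    group = group,
    replicate = as.integer(replicate),
    affected = gene_pars$affected,
    fold = fold,
    expected_count = expected,
    promoter_density = expected * p_prom / 500,
    body_density = expected * (1 - p_prom) / (L + 1900),
    stringsAsFactors = FALSE
  )
  list(fragments = frags, truth = truth)
}

#' Simulate a full paired ChIP experiment
#'
#' Runs [sim_chip()] for `n_samples_per_group` replicates of each group.
#'
#' @inheritParams sim_chip
#' @return A list with `samples` (named list of fragment data frames,
#'   `WT_1..`, `KO_1..`) and `truth` (row-bound per-sample truth tables).
#' @export
sim_chip_experiment <- function(genes, config) {
  groups <- rep(c("WT", "KO"), each = config$n_samples_per_group)
  reps <- rep(seq_len(config$n_samples_per_group), 2)
  out <- Map(function(g, r) sim_chip(genes, config, g, r), groups, reps)
  names(out) <- paste0(groups, "_", reps)
  list(
    samples = lapply(out, `[[`, "fragments"),
    truth = do.call(rbind, c(lapply(out, `[[`, "truth"),
                             make.row.names = FALSE))
  )
}

#' Write / read ChIP fragments as BED
#'
#' @param fragments Data frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @return `write_fragments_bed` returns `path` invisibly;
#'   `read_fragments_bed` a fragment data frame.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    ".", 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             stringsAsFactors = FALSE)
}
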