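#' Count ChIP fragments in gene region windows
#'
#' A fragment is assigned to a region if and only if its midpoint lies in
#' the region (half-open); one fragment may count toward several region
#' types of the same gene, since region types are analysed independently.
#'
#' @param samples Named list of fragment data frames (`chrom`, `start`,
#'   `end`), one per sample; a single data frame is treated as one sample.
#' @param regions Output of [derive_regions()].
#' @param lib_sizes Optional named per-sample total mapped fragment counts;
#'   defaults to the number of fragments supplied per sample.
#' @return An object of class `region_counts`: `counts` (list, one
#'   gene x sample integer matrix per region type), `lengths` (gene x region
#'   matrix of window lengths), `lib_sizes`, `gene_ids`.
#' @export
count_regions <- function(samples, regions, lib_sizes = NULL) {
  if (is.data.frame(samples)) samples <- list(S1 = samples)
  if (is.null(names(samples))) {
    names(samples) <- paste0("S", seq_along(samples))
  }
  gene_ids <- unique(regions$gene_id)
  region_names <- unique(regions$region)
  if (nrow(regions) == 0L || length(gene_ids) == 0L) {
    return(structure(list(counts = list(),
                          lengths = matrix(numeric(0), 0, 0),
                          lib_sizes = vapply(samples, nrow, numeric(1)),
                          gene_ids = character(0)),
                     class = "region_counts"))
  }
  nonempty <- regions[!regions$empty, , drop = FALSE]
  reg_gr <- GenomicRanges::GRanges(
    nonempty$chrom,
    IRanges::IRanges(start = nonempty$start + 1L, end = nonempty$end)
  )
  lib <- lib_sizes %||% vapply(samples, nrow, numeric(1))
  if (is.null(names(lib))) names(lib) <- names(samples)

  counts <- lapply(region_names, function(r) {
    m <- matrix(0L, length(gene_ids), length(samples),
                dimnames = list(gene_ids, names(samples)))
    m
  })
  names(counts) <- region_names
  for (s in names(samples)) {
    fr <- samples[[s]]
    mid <- floor((fr$start + fr$end) / 2)
    mid_gr <- GenomicRanges::GRanges(
      fr$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
    n_over <- suppressWarnings(GenomicRanges::countOverlaps(reg_gr, mid_gr))
    for (r in region_names) {
      sel <- nonempty$region == r
      counts[[r]][nonempty$gene_id[sel], s] <- n_over[sel]
    }
  }
  lengths <- matrix(0, length(gene_ids), length(region_names),
                    dimnames = list(gene_ids, region_names))
  lengths[cbind(match(regions$gene_id, gene_ids),
                match(regions$region, region_names))] <- regions$length
  structure(list(counts = counts, lengths = lengths, lib_sizes = lib,
                 gene_ids = gene_ids),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat("region_counts:", length(x$gene_ids), "genes x",
      length(x$lib_sizes), "samples;",
      paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count * 1e9 / (region_length * total_mapped)`.
#'
#' @param count Fragment count(s).
#' @param region_length Region length(s) in bp; must be > 0.
#' @param total_mapped Total mapped fragments in the library; must be > 0.
#' @return FPKM value(s).
#' @examples
#' fpkm(50, 500, 1e7)  # 10
#' @export
fpkm <- function(count, region_length, total_mapped) {
  if (any(region_length <= 0)) {
    stop("region_length must be positive", call. = FALSE)
  }
  if (any(total_mapped <= 0)) {
    stop("total_mapped must be positive", call. = FALSE)
  }
  count * 1e9 / (region_length * total_mapped)
}

#' Pausing index
#'
#' The standard form divides each FPKM (already length-normalized) by the
#' region length again:
#' `PI = (promoter_fpkm / L1) / (pi_body_fpkm / L2)`,
#' with `L1 = 500` bp (the promoter) and `L2` the variable gene-body window
#' length. Because FPKM is itself per-kilobase, this double normalization
#' makes equal signal *densities* give `PI = L2 / L1`; `mode = "density"`
#' instead returns the plain density ratio `promoter_fpkm / pi_body_fpkm`,
#' which is 1 for equal densities. Both are scale-invariant in the counts.
#' PI is undefined (`NA`) exactly when the gene-body FPKM is zero.
#'
#' @param promoter_fpkm,pi_body_fpkm Region FPKMs (non-negative).
#' @param L1 Promoter length, 500 bp.
#' @param L2 Gene-body window length(s) in bp.
#' @param mode `"standard"` (default) or `"density"`.
#' @return PI value(s); `NA` where the body FPKM is 0.
#' @examples
#' pausing_index(40, 4, L2 = 2000)  # 40
#' @export
pausing_index <- function(promoter_fpkm, pi_body_fpkm, L1 = 500, L2,
                          mode = c("standard", "density")) {
  mode <- match.arg(mode)
  if (any(promoter_fpkm < 0, na.rm = TRUE) ||
      any(pi_body_fpkm < 0, na.rm = TRUE)) {
    stop("FPKM inputs must be non-negative", call. = FALSE)
  }
  if (any(L2 <= 0)) stop("L2 must be positive", call. = FALSE)
  pi_val <- if (mode == "standard") {
    (promoter_fpkm / L1) / (pi_body_fpkm / L2)
  } else {
    promoter_fpkm / pi_body_fpkm
  }
  pi_val[pi_body_fpkm == 0] <- NA_real_
  pi_val
}

#' Per-gene, per-sample pausing-index table
#'
#' Computes promoter and `pi_body` FPKMs from a [count_regions()] result and
#' applies [pausing_index()].
#'
#' @param rc A `region_counts` object containing `promoter` and `pi_body`.
#' @param mode Passed to [pausing_index()].
#' @return List of class `pausing_table`: `pi` (gene x sample matrix, `NA`
#'   where undefined), `promoter_fpkm`, `pi_body_fpkm`, `L1`, `L2`.
#' @export
pausing_table <- function(rc, mode = c("standard", "density")) {
  mode <- match.arg(mode)
  stopifnot(all(c("promoter", "pi_body") %in% names(rc$counts)))
  L2 <- rc$lengths[, "pi_body"]
  lib <- rc$lib_sizes
  prom <- sweep(rc$counts$promoter, 2, lib,
                function(ct, n) fpkm(ct, 500, n))
  body <- rc$counts$pi_body * 1e9 / outer(L2, lib)
  pi_mat <- matrix(
    pausing_index(as.vector(prom), as.vector(body), L1 = 500,
                  L2 = rep(L2, ncol(prom)), mode = mode),
    nrow = nrow(prom), dimnames = dimnames(prom)
  )
  structure(list(pi = pi_mat, promoter_fpkm = prom, pi_body_fpkm = body,
                 L1 = 500, L2 = L2, mode = mode),
            class = "pausing_table")
}

#' Compare pausing indices between two groups
#'
#' Per-gene paired two-sided t test of PI across replicate pairs, followed
#' by Benjamini-Hochberg correction, plus the per-sample empirical PI
#' distribution (proportion of genes at or below each PI). Genes whose PI is
#' undefined in any sample are excluded and reported.
#'
#' @param pt_wt,pt_ko `pausing_table` objects with matching genes; columns
#'   are paired by position.
#' @return List of class `pausing_comparison`: `table` (gene, mean PI per
#'   group, mean paired difference, t, p, q), `excluded` (gene ids),
#'   `distributions` (long data frame sample/PI/cumulative fraction).
#' @export
compare_pausing <- function(pt_wt, pt_ko) {
  if (ncol(pt_wt$pi) < 2L || ncol(pt_wt$pi) != ncol(pt_ko$pi)) {
    stop("need >= 2 replicate pairs with matching column counts",
         call. = FALSE)
  }
  stopifnot(identical(rownames(pt_wt$pi), rownames(pt_ko$pi)))
  ok <- rowSums(is.na(pt_wt$pi)) == 0 & rowSums(is.na(pt_ko$pi)) == 0
  excluded <- rownames(pt_wt$pi)[!ok]
  if (length(excluded)) {
    message(length(excluded), " gene(s) excluded: PI undefined in >= 1 sample")
  }
  W <- pt_wt$pi[ok, , drop = FALSE]
  K <- pt_ko$pi[ok, , drop = FALSE]
  D <- K - W
  n <- ncol(D)
  m <- rowMeans(D)
  s <- apply(D, 1, sd)
  t_stat <- ifelse(s == 0 & m == 0, 0, m / (s / sqrt(n)))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  p[s == 0 & m == 0] <- 1
  p[s == 0 & m != 0] <- 0
  tab <- data.frame(
    gene_id = rownames(W),
    pi_wt = rowMeans(W), pi_ko = rowMeans(K),
    mean_diff = m, t = t_stat, p = p, q = bh_fdr(p),
    stringsAsFactors = FALSE
  )
  all_pi <- cbind(W, K)
  dist <- do.call(rbind, lapply(colnames(all_pi), function(s) {
    v <- sort(all_pi[, s])
    data.frame(sample = s, pi = v,
               fraction = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, excluded = excluded, distributions = dist),
            class = "pausing_comparison")
}

#' Scale a per-base coverage track
#'
#' Scales coverage values to read count per base pair per 10 million mapped
#' reads: `value * 1e7 / total_mapped`.
#'
#' @param track Data frame `chrom`, `start`, `end`, `value` (bedGraph-like,
#'   0-based half-open).
#' @param total_mapped Total mapped fragments; must be > 0.
#' @return The track with scaled `value`.
#' @export
scale_track <- function(track, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be positive", call. = FALSE)
  track$value <- track$value * 1e7 / total_mapped
  track
}

#' Write / read bedGraph tracks
#'
#' @param track Data frame `chrom`, `start`, `end`, `value`.
#' @param path File path.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph` a
#'   track data frame.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE
  )
}
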