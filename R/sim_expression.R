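#' Transcript count-matrix container
#'
#' Holds raw transcript-by-sample counts together with the transcript-to-gene
#' map, sample group labels, library sizes and the identity of the anchor
#' transcript (a Pol III-transcribed gene such as *Rn7sk*, whose cellular
#' abundance is independent of the Pol II pool and therefore usable as an
#' internal normalization control).
#'
#' @param counts Integer matrix, transcripts x samples, with dimnames.
#' @param gene_map Data frame with columns `transcript_id`, `gene_id`
#'   covering every row of `counts`.
#' @param groups Factor or character of group labels, one per sample.
#' @param anchor Transcript id of the anchor; must be a row of `counts` with
#'   count > 0 in every sample.
#' @param lib_sizes Optional per-sample library sizes; defaults to column
#'   sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_map, groups, anchor,
                         lib_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  missing_tx <- setdiff(rownames(counts), gene_map$transcript_id)
  if (length(missing_tx)) {
    stop("transcripts missing from gene_map: ",
         paste(head(missing_tx, 5), collapse = ", "), call. = FALSE)
  }
  if (!anchor %in% rownames(counts)) {
    stop("anchor transcript '", anchor, "' not in counts", call. = FALSE)
  }
  if (any(counts[anchor, ] <= 0)) {
    stop("anchor transcript must have count > 0 in every sample",
         call. = FALSE)
  }
  groups <- factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("one group label per sample required", call. = FALSE)
  }
  structure(list(counts = counts, gene_map = gene_map, groups = groups,
                 anchor = anchor, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples; anchor:", x$anchor, "\n")
  invisible(x)
}

#' Simulate a transcript count matrix
#'
#' Negative-binomial counts (`Var = mu + phi * mu^2`) with lognormal
#' baseline means, a designated anchor transcript with identical mean in
#' both groups, and `de_fraction` of transcripts whose group-2 (KO) mean is
#' scaled by `2^log2fc_effect` (up and down split evenly). Roughly 15% of
#' genes carry two transcript isoforms.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth` (per-
#'   transcript base mean, KO mean, DE flag, direction and true log2 FC).
#' @examples
#' sim <- sim_counts(sim_config(seed = 3, n_genes = 100))
#' sim$counts
#' @export
sim_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$n_samples_per_group >= 2L)
  n_tx <- config$n_genes
  ns <- config$n_samples_per_group
  with_seed(derive_seed(config$seed, "rnaseq"), {
    # ~15% of genes contribute a second isoform
    gene_of <- cumsum(c(1, runif(n_tx - 1) > 0.15))
    tx_id <- sprintf("tx%05d", seq_len(n_tx))
    gene_id <- sprintf("gene%05d", gene_of)

    base_mean <- rlnorm(n_tx, meanlog = log(150), sdlog = 1)
    n_de <- round(config$de_fraction * n_tx)
    de <- rep(FALSE, n_tx)
    if (n_de > 0) de[sample.int(n_tx, n_de)] <- TRUE
    direction <- integer(n_tx)
    direction[de] <- rep_len(c(1L, -1L), n_de)
    ko_mean <- base_mean * 2^(direction * config$log2fc_effect)

    tx_id <- c(tx_id, "Rn7sk")
    gene_id <- c(gene_id, "Rn7sk")
    base_mean <- c(base_mean, config$anchor_count_mean)
    ko_mean <- c(ko_mean, config$anchor_count_mean)
    de <- c(de, FALSE)
    direction <- c(direction, 0L)

    size <- 1 / max(config$nb_dispersion, 1e-8)
    draw <- function(mu) {
      matrix(rnbinom(length(mu) * ns, mu = rep(mu, ns), size = size),
             ncol = ns)
    }
    counts <- cbind(draw(base_mean), draw(ko_mean))
    rownames(counts) <- tx_id
    colnames(counts) <- c(paste0("WT_", seq_len(ns)),
                          paste0("KO_", seq_len(ns)))
    counts["Rn7sk", ] <- pmax(counts["Rn7sk", ], 1L)  # anchor must be usable
    storage.mode(counts) <- "integer"

    cm <- count_matrix(
      counts,
      gene_map = data.frame(transcript_id = tx_id, gene_id = gene_id,
                            stringsAsFactors = FALSE),
      groups = rep(c("WT", "KO"), each = ns),
      anchor = "Rn7sk"
    )
    truth <- data.frame(
      transcript_id = tx_id, gene_id = gene_id,
      base_mean = base_mean, ko_mean = ko_mean,
      is_de = de, direction = direction,
      true_log2fc = direction * config$log2fc_effect,
      stringsAsFactors = FALSE
    )
    list(counts = cm, truth = truth)
  })
}

#' Simulate an AP-MS spectral-count matrix
#'
#' Bait-affinity purifications in three conditions: bait-WT, bait-mutant and
#' empty-vector control, each with `n_runs` replicate runs. A planted subset
#' of preys is enriched in bait runs over control (true interactors); a
#' further subset differs between WT and mutant bait. Low-abundance values
#' drop out to zero, emulating spectral-count sparsity.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param n_prey Number of prey proteins.
#' @param n_runs Replicate runs per condition.
#' @param interactor_fraction Fraction of preys enriched in bait runs.
#' @param differential_fraction Fraction of interactors changed in the
#'   mutant bait.
#' @param dropout_rate Zero-inflation probability for sub-median counts.
#' @return List with `matrix` (preys + `BAIT` row x runs), `conditions`
#'   (per-run labels: `bait_wt`, `bait_mut`, `control`), `bait` (row name),
#'   and `truth`.
#' @export
sim_spectral <- function(config, n_prey = 200L, n_runs = 4L,
                         interactor_fraction = 0.2,
                         differential_fraction = 0.1,
                         dropout_rate = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "apms"), {
    conditions <- rep(c("bait_wt", "bait_mut", "control"), each = n_runs)
    base <- rlnorm(n_prey, log(8), 0.8)
    inter <- runif(n_prey) < interactor_fraction
    diff <- inter & (runif(n_prey) < differential_fraction / interactor_fraction)
    mu <- matrix(rep(base, length(conditions)), ncol = length(conditions))
    mu[inter, conditions != "control"] <- mu[inter, conditions != "control"] * 4
    mu[diff, conditions == "bait_mut"] <- mu[diff, conditions == "bait_mut"] / 3
    counts <- matrix(rpois(length(mu), mu), ncol = ncol(mu))
    drop <- matrix(runif(length(counts)) < dropout_rate, ncol = ncol(counts)) &
      counts < median(counts)
    counts[drop] <- 0L
    bait <- rpois(length(conditions), 300)
    bait[conditions == "control"] <- 0L
    mat <- rbind(counts, bait)
    rownames(mat) <- c(sprintf("prey%03d", seq_len(n_prey)), "BAIT")
    colnames(mat) <- paste0(conditions, "_", rep(seq_len(n_runs), 3))
    list(
      matrix = mat,
      conditions = conditions,
      bait = "BAIT",
      truth = data.frame(prey = rownames(mat)[seq_len(n_prey)],
                         interactor = inter, differential = diff,
                         stringsAsFactors = FALSE)
    )
  })
}
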