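#' Simulation configuration
#'
#' One object carries every knob the synthetic-data generators use, so a
#' single seed reproduces a whole study bit-for-bit. Defaults describe the
#' scaled-down study conditions used throughout the package's tests: 2,000
#' genes, three biological replicate pairs, one million fragments or reads
#' per sample, a 2-fold knockout occupancy effect planted on 5% of genes, a
#' 2-fold (log2) expression effect on 5% of transcripts, 60% homozygous-null
#' lethality and 27.7% phenotype penetrance among surviving homozygotes.
#'
#' @param seed Integer root seed. Each generator derives its own stream from
#'   it, so outputs are a pure function of the config.
#' @param n_genes Number of genes (and transcripts, before isoform
#'   duplication) to simulate.
#' @param genome_length Genome size in bp; `NULL` sizes it to fit all genes
#'   plus 10-kb flanks.
#' @param n_samples_per_group Biological replicates per group (>= 2 for any
#'   differential analysis).
#' @param library_size ChIP fragments per sample; fragment counts per sample
#'   sum to exactly this value.
#' @param pausing_level Per-gene promoter enrichment: promoter fragment
#'   density is `(1 + pausing_level)` times gene-body density, so 0 means no
#'   pausing.
#' @param occupancy_fold Fold change applied to the expected fragment count
#'   of affected genes in the KO group.
#' @param affected_fraction Fraction of genes carrying `occupancy_fold`.
#' @param background_fraction Fraction of the library placed uniformly over
#'   the genome as intergenic background.
#' @param fragment_length Fixed sonication fragment length in bp.
#' @param de_fraction Fraction of transcripts differentially expressed
#'   between groups.
#' @param log2fc_effect Planted log2 fold change magnitude for DE
#'   transcripts (direction is split evenly).
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   `Var = mu + phi * mu^2`.
#' @param anchor_count_mean Mean count of the Pol III-transcribed anchor
#'   transcript (identical in both groups by construction).
#' @param cohort_n_cases,cohort_n_controls Subjects in the simulated case
#'   cohort and in the population behind the control allele-count table.
#' @param n_sites Variant sites in the simulated cohort.
#' @param n_causal_sites Planted case-enriched sites (case AF =
#'   `causal_af`, control AF = 0).
#' @param causal_af Case allele frequency of planted causal variants.
#' @param genotype_fail_rate Fraction of genotype calls given failing
#'   quality fields (low DP or GQ).
#' @param litter_n Total conceptuses drawn from heterozygote intercrosses.
#' @param lethality Probability that a homozygous-null conceptus dies before
#'   weaning.
#' @param penetrance Phenotype probability among surviving homozygous-null
#'   offspring.
#' @param wt_phenotype_rate Background phenotype rate in wild-type and
#'   heterozygous offspring.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 50)
#' cfg$n_genes
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       genome_length = NULL,
                       n_samples_per_group = 3L,
                       library_size = 1e6,
                       pausing_level = 2,
                       occupancy_fold = 2,
                       affected_fraction = 0.05,
                       background_fraction = 0.1,
                       fragment_length = 200L,
                       de_fraction = 0.05,
                       log2fc_effect = 2,
                       nb_dispersion = 0.05,
                       anchor_count_mean = 5e4,
                       cohort_n_cases = 100L,
                       cohort_n_controls = 1000L,
                       n_sites = 60L,
                       n_causal_sites = 5L,
                       causal_af = 0.02,
                       genotype_fail_rate = 0.02,
                       litter_n = 2000L,
                       lethality = 0.6,
                       penetrance = 0.277,
                       wt_phenotype_rate = 0.037) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    genome_length = genome_length,
    n_samples_per_group = as.integer(n_samples_per_group),
    library_size = as.integer(library_size),
    pausing_level = pausing_level,
    occupancy_fold = occupancy_fold,
    affected_fraction = affected_fraction,
    background_fraction = background_fraction,
    fragment_length = as.integer(fragment_length),
    de_fraction = de_fraction,
    log2fc_effect = log2fc_effect,
    nb_dispersion = nb_dispersion,
    anchor_count_mean = anchor_count_mean,
    cohort_n_cases = as.integer(cohort_n_cases),
    cohort_n_controls = as.integer(cohort_n_controls),
    n_sites = as.integer(n_sites),
    n_causal_sites = as.integer(n_causal_sites),
    causal_af = causal_af,
    genotype_fail_rate = genotype_fail_rate,
    litter_n = as.integer(litter_n),
    lethality = lethality,
    penetrance = penetrance,
    wt_phenotype_rate = wt_phenotype_rate
  )
  if (is.null(cfg$genome_length)) {
    cfg$genome_length <- cfg$n_genes * 36000 + 100000
  }
  cfg$genome_length <- as.numeric(cfg$genome_length)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c("affected_fraction", "background_fraction", "de_fraction",
             "causal_af", "genotype_fail_rate", "lethality", "penetrance",
             "wt_phenotype_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a fraction in [0, 1]", f), call. = FALSE)
    }
  }
  counts <- c("n_samples_per_group", "library_size", "fragment_length",
              "cohort_n_cases", "cohort_n_controls", "n_sites", "litter_n")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("'%s' must be a positive integer", f), call. = FALSE)
    }
  }
  if (cfg$n_genes < 0) stop("'n_genes' must be non-negative", call. = FALSE)
  if (cfg$n_causal_sites < 0 || cfg$n_causal_sites > cfg$n_sites) {
    stop("'n_causal_sites' must lie in [0, n_sites]", call. = FALSE)
  }
  if (cfg$pausing_level < 0) stop("'pausing_level' must be >= 0", call. = FALSE)
  if (cfg$occupancy_fold <= 0) stop("'occupancy_fold' must be > 0", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("'nb_dispersion' must be > 0", call. = FALSE)
  if (cfg$anchor_count_mean <= 0) {
    stop("'anchor_count_mean' must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      x$n_samples_per_group, "replicates/group, seed", x$seed, "\n")
  invisible(x)
}
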