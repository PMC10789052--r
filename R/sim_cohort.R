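#' Simulate a case cohort with a control allele-count table
#'
#' Diploid genotypes for `cohort_n_cases` subjects (split between two
#' populations, `EUR` and `MEX`) at `n_sites` variant sites, with per-call
#' AD/DP/GQ quality fields and per-site VQSR filter status, mapping quality
#' and inbreeding coefficient. `n_causal_sites` planted variants have case
#' allele frequency `causal_af` and control allele count 0 with adequate
#' (>= 30X) control coverage, so they classify as novel downstream. The
#' control population is emitted as an allele-count table (AC/AN/coverage
#' per population), the form in which public control cohorts such as gnomAD
#' are consumed. A `genotype_fail_rate` fraction of calls receives failing
#' quality fields.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `sites` (site annotations), `calls`
#'   (long per-subject genotype calls: `site_id`, `subject`, `gt` in 0:2,
#'   `ad_ref`, `ad_alt`, `dp`, `gq`), `subjects` (subject -> population),
#'   `controls` (site x population AC/AN/coverage), and `truth` (planted
#'   causal site ids and parameters).
#' @export
sim_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$cohort_n_cases >= 1L, config$cohort_n_controls >= 1L)
  with_seed(derive_seed(config$seed, "cohort"), {
    n_sub <- config$cohort_n_cases
    n_sites <- config$n_sites
    n_causal <- config$n_causal_sites
    pops <- rep(c("EUR", "MEX"), length.out = n_sub)
    subjects <- data.frame(
      subject = sprintf("S%04d", seq_len(n_sub)),
      population = pops, stringsAsFactors = FALSE
    )

    pos <- sort(sample.int(5e6, n_sites))
    causal <- rep(FALSE, n_sites)
    if (n_causal > 0) causal[sample.int(n_sites, n_causal)] <- TRUE
    ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    # ~8% of sites fail VQSR; MQ mostly high, a few rescued by inbreeding
    filter <- ifelse(runif(n_sites) < 0.08, "VQSRTrancheSNP99.90", "PASS")
    mq <- rnorm(n_sites, 60, 3)
    low_mq <- runif(n_sites) < 0.05
    mq[low_mq] <- runif(sum(low_mq), 10, 20)
    inbreeding <- rnorm(n_sites, 0, 0.05)
    inbreeding[low_mq] <- ifelse(runif(sum(low_mq)) < 0.5, -0.4,
                                 inbreeding[low_mq])
    case_af <- ifelse(causal, config$causal_af, runif(n_sites, 0.001, 0.05))
    sites <- data.frame(
      site_id = sprintf("chr16:%d:%s:%s", pos, ref, alt),
      chrom = "chr16", pos = pos, ref = ref, alt = alt,
      filter = filter, mq = mq, inbreeding = inbreeding,
      stringsAsFactors = FALSE
    )

    gt <- matrix(rbinom(n_sites * n_sub, 2, rep(case_af, n_sub)),
                 nrow = n_sites)
    dp <- matrix(rpois(n_sites * n_sub, 60), nrow = n_sites)
    alt_p <- matrix(c(0.005, 0.5, 0.995)[gt + 1L], nrow = n_sites)
    ad_alt <- matrix(rbinom(length(dp), as.vector(dp), as.vector(alt_p)),
                     nrow = n_sites)
    gq <- matrix(99L, n_sites, n_sub)
    fail <- matrix(runif(n_sites * n_sub) < config$genotype_fail_rate,
                   nrow = n_sites)
    # failing calls get either shallow depth or poor genotype quality
    fail_dp <- fail & matrix(runif(n_sites * n_sub) < 0.5, nrow = n_sites)
    dp[fail_dp] <- sample(1:10, sum(fail_dp), replace = TRUE)
    ad_alt[fail_dp] <- pmin(ad_alt[fail_dp], dp[fail_dp])
    gq[fail & !fail_dp] <- sample(1:20, sum(fail & !fail_dp), replace = TRUE)

    calls <- data.frame(
      site_id = rep(sites$site_id, n_sub),
      subject = rep(subjects$subject, each = n_sites),
      gt = as.vector(gt),
      ad_ref = as.vector(dp - ad_alt),
      ad_alt = as.vector(ad_alt),
      dp = as.vector(dp),
      gq = as.vector(gq),
      stringsAsFactors = FALSE
    )

    an_ctrl <- 2L * config$cohort_n_controls
    ctrl_af <- ifelse(causal, 0, pmax(0, case_af + rnorm(n_sites, 0, 0.002)))
    controls <- do.call(rbind, lapply(c("EUR", "MEX"), function(p) {
      data.frame(
        site_id = sites$site_id, population = p,
        ac = round(ctrl_af * an_ctrl), an = an_ctrl,
        coverage = ifelse(causal, runif(n_sites, 40, 60),
                          ifelse(runif(n_sites) < 0.05,
                                 runif(n_sites, 10, 29),
                                 runif(n_sites, 35, 80))),
        stringsAsFactors = FALSE
      )
    }))
    structure(list(
      sites = sites, calls = calls, subjects = subjects, controls = controls,
      truth = list(causal_sites = sites$site_id[causal],
                   causal_af = config$causal_af)
    ), class = "sim_cohort")
  })
}

#' Simulate heterozygote-intercross litters
#'
#' Conceptus genotypes are drawn 1:2:1 (wild-type : heterozygous :
#' homozygous-null) from het x het crosses. Homozygous-null conceptuses die
#' before weaning with probability `lethality`; survivors develop the
#' phenotype with probability `penetrance` (homozygous-null) or
#' `wt_phenotype_rate` (other genotypes).
#'
#' @param config A [sim_config()].
#' @return List with `table` (per-genotype conceived / survived / phenotype
#'   counts) and `truth` (planted rates).
#' @examples
#' sim_litters(sim_config(seed = 2, litter_n = 400))$table
#' @export
sim_litters <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$litter_n >= 1L)
  with_seed(derive_seed(config$seed, "litters"), {
    conceived <- as.vector(rmultinom(1, config$litter_n,
                                     c(wt = 0.25, het = 0.5, ko = 0.25)))
    names(conceived) <- c("wt", "het", "ko")
    died <- c(wt = 0L, het = 0L,
              ko = rbinom(1, conceived[["ko"]], config$lethality))
    survived <- conceived - died
    pen <- c(wt = config$wt_phenotype_rate, het = config$wt_phenotype_rate,
             ko = config$penetrance)
    phenotype <- vapply(names(survived), function(g) {
      rbinom(1, survived[[g]], pen[[g]])
    }, integer(1))
    list(
      table = data.frame(
        genotype = names(conceived),
        conceived = conceived, survived = as.integer(survived),
        phenotype = as.integer(phenotype),
        row.names = NULL, stringsAsFactors = FALSE
      ),
      truth = list(lethality = config$lethality,
                   penetrance = config$penetrance,
                   wt_phenotype_rate = config$wt_phenotype_rate)
    )
  })
}

#' Write a simulated cohort as minimal VCF 4.2
#'
#' Emits site annotations (`FILTER`, `INFO MQ`, `InbreedingCoeff`) and
#' per-subject `GT:AD:DP:GQ` genotype fields. Read back with
#' [read_cohort_vcf()].
#'
#' @param cohort A [sim_cohort()] result (or a list with the same shape).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  sites <- cohort$sites
  calls <- cohort$calls
  subjects <- cohort$subjects$subject
  gt_str <- c("0/0", "0/1", "1/1")
  calls$fmt <- sprintf("%s:%d,%d:%d:%d", gt_str[calls$gt + 1L],
                       calls$ad_ref, calls$ad_alt, calls$dp, calls$gq)
  fmt <- matrix(calls$fmt[order(match(calls$subject, subjects),
                                match(calls$site_id, sites$site_id))],
                nrow = nrow(sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=InbreedingCoeff,Number=1,Type=Float,Description=\"Inbreeding coefficient\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90,Description=\"VQSR tranche\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt, ".",
    sites$filter,
    sprintf("MQ=%.2f;InbreedingCoeff=%.3f", sites$mq, sites$inbreeding),
    "GT:AD:DP:GQ",
    apply(fmt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF
#'
#' Parses a VCF with `GT:AD:DP:GQ` genotype fields and `MQ` /
#' `InbreedingCoeff` INFO keys (via `vcfR`) into the same sites/calls
#' structure that [sim_cohort()] produces.
#'
#' @param path VCF file.
#' @param subjects Optional data frame `subject`, `population`; defaults to
#'   a single `ALL` population.
#' @return A list with `sites`, `calls` and `subjects`.
#' @export
read_cohort_vcf <- function(path, subjects = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    out <- rep(NA_real_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- as.numeric(sub(paste0(key, "="), "", m))
    out
  }
  sites <- data.frame(
    site_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                     sprintf("%s:%s:%s:%s", fix$CHROM, fix$POS, fix$REF,
                             fix$ALT),
                     fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, filter = fix$FILTER,
    mq = info_num("MQ"), inbreeding = info_num("InbreedingCoeff"),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, "GT")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  ns <- ncol(gt)
  ad_alt <- as.integer(sub("^[0-9]+,", "", ad))
  ad_ref <- as.integer(sub(",[0-9]+$", "", ad))
  calls <- data.frame(
    site_id = rep(sites$site_id, ns),
    subject = rep(colnames(gt), each = nrow(gt)),
    gt = vapply(strsplit(as.vector(gt), "[/|]"),
                function(a) sum(a == "1"), integer(1)),
    ad_ref = ad_ref, ad_alt = ad_alt,
    dp = as.integer(dp), gq = as.integer(gq),
    stringsAsFactors = FALSE
  )
  if (is.null(subjects)) {
    subjects <- data.frame(subject = colnames(gt), population = "ALL",
                           stringsAsFactors = FALSE)
  }
  list(sites = sites, calls = calls, subjects = subjects)
}
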