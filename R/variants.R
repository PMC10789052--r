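#' Site-level variant quality filter
#'
#' A site passes iff its VQSR status is `PASS` AND (mapping quality > 20 OR
#' inbreeding coefficient < -0.3). Missing annotations fail the clause they
#' belong to (conservative).
#'
#' @param sites Data frame with `filter`, `mq`, `inbreeding` columns.
#' @return `sites` with logical `site_pass` and character `site_reason`.
#' @examples
#' site_filter(data.frame(filter = "PASS", mq = 15, inbreeding = -0.4))
#' @export
site_filter <- function(sites) {
  vqsr_ok <- !is.na(sites$filter) & sites$filter == "PASS"
  mq_ok <- !is.na(sites$mq) & sites$mq > 20
  inb_ok <- !is.na(sites$inbreeding) & sites$inbreeding < -0.3
  pass <- vqsr_ok & (mq_ok | inb_ok)
  reason <- rep("", nrow(sites))
  reason[!vqsr_ok] <- "non-PASS VQSR"
  reason[vqsr_ok & !(mq_ok | inb_ok)] <- "MQ <= 20 and inbreeding >= -0.3"
  sites$site_pass <- pass
  sites$site_reason <- reason
  sites
}

#' Genotype-level quality filter
#'
#' A call passes iff read depth DP > 10, genotype quality GQ > 20 and — for
#' calls carrying an alternate allele — alternate allele depth fraction
#' AD_alt/DP > 25% (all thresholds strict). Zero-depth calls fail with a
#' divide-guard reason. Hom-ref calls are exempt from the alternate-depth
#' clause, otherwise no reference genotype could ever pass and allele
#' numbers could not be recalculated.
#'
#' @param calls Data frame with `gt`, `ad_alt`, `dp`, `gq`.
#' @return `calls` with logical `gt_pass` and character `gt_reason`.
#' @export
genotype_filter <- function(calls) {
  dp_ok <- !is.na(calls$dp) & calls$dp > 10
  gq_ok <- !is.na(calls$gq) & calls$gq > 20
  zero_dp <- is.na(calls$dp) | calls$dp == 0
  frac <- ifelse(zero_dp, NA_real_, calls$ad_alt / calls$dp)
  alt_ok <- calls$gt == 0 | (!is.na(frac) & frac > 0.25)
  pass <- dp_ok & gq_ok & alt_ok
  reason <- rep("", nrow(calls))
  reason[!dp_ok] <- "DP <= 10"
  reason[dp_ok & !gq_ok] <- "GQ <= 20"
  reason[dp_ok & gq_ok & !alt_ok] <- "alt fraction <= 25%"
  reason[zero_dp] <- "DP = 0 (alt fraction undefined)"
  calls$gt_pass <- pass
  calls$gt_reason <- reason
  calls
}

#' Recalculate cohort allele statistics after filtering
#'
#' For each site and population: AN = 2 x (subjects with a passing genotype
#' call), AC = alternate alleles among those calls, AF = AC/AN. Sites where
#' every genotype is filtered get `NA` statistics with `defined = FALSE`.
#'
#' @param calls Filtered calls (output of [genotype_filter()], or any data
#'   frame with `site_id`, `subject`, `gt`, `gt_pass`).
#' @param subjects Data frame `subject`, `population`.
#' @param site_pass Optional named logical (by site id) from [site_filter()];
#'   failing sites are dropped.
#' @return Data frame `site_id`, `population`, `ac`, `an`, `af`, `defined`.
#' @export
recalc_stats <- function(calls, subjects, site_pass = NULL) {
  calls$population <- subjects$population[match(calls$subject,
                                                subjects$subject)]
  if (!is.null(site_pass)) {
    calls <- calls[site_pass[calls$site_id] %in% TRUE, , drop = FALSE]
  }
  site_ids <- unique(calls$site_id)
  pops <- unique(subjects$population)
  grid <- expand.grid(site_id = site_ids, population = pops,
                      stringsAsFactors = FALSE)
  ok <- calls[calls$gt_pass, , drop = FALSE]
  key <- function(d) paste(d$site_id, d$population)
  an <- tapply(ok$gt, key(ok), length) * 2L
  ac <- tapply(ok$gt, key(ok), sum)
  grid$an <- as.integer(an[key(grid)])
  grid$ac <- as.integer(ac[key(grid)])
  grid$an[is.na(grid$an)] <- 0L
  grid$ac[is.na(grid$ac)] <- 0L
  grid$defined <- grid$an > 0L
  grid$af <- ifelse(grid$defined, grid$ac / grid$an, NA_real_)
  grid[order(match(grid$site_id, site_ids), grid$population), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid[, c("site_id", "population", "ac", "an", "af", "defined")]
}

#' Classify variants as novel / rare / common / discard
#'
#' Using a control-population allele-count record: a variant absent from the
#' controls (record missing or control AF = 0) is `novel` provided the
#' control locus was sequenced at >= 30X coverage, and `discard` otherwise
#' (the locus is considered poor quality); an observed control variant is
#' `rare` when its control AF < 0.01 and `common` when >= 0.01.
#'
#' @param case_stats Data frame from [recalc_stats()] (one row per
#'   site/population).
#' @param controls Data frame `site_id`, `population`, `ac`, `an`,
#'   `coverage`.
#' @return `case_stats` with `control_ac`, `control_an`, `control_af`,
#'   `control_coverage` and `class` columns.
#' @export
classify_variants <- function(case_stats, controls) {
  key <- function(d) paste(d$site_id, d$population)
  idx <- match(key(case_stats), key(controls))
  ctrl_ac <- controls$ac[idx]
  ctrl_an <- controls$an[idx]
  cov <- controls$coverage[idx]
  ctrl_af <- ifelse(!is.na(ctrl_an) & ctrl_an > 0, ctrl_ac / ctrl_an,
                    NA_real_)
  absent <- is.na(idx) | is.na(ctrl_af) | ctrl_af == 0
  cls <- ifelse(absent,
                ifelse(!is.na(cov) & cov >= 30, "novel", "discard"),
                ifelse(ctrl_af < 0.01, "rare", "common"))
  case_stats$control_ac <- ctrl_ac
  case_stats$control_an <- ctrl_an
  case_stats$control_af <- ctrl_af
  case_stats$control_coverage <- cov
  case_stats$class <- cls
  case_stats
}

#' CADD-style Phred score from a percentile rank, and back
#'
#' `cscore_from_rank(r) = -10 * log10(r)` for a deleteriousness rank
#' fraction `r` in `(0, 1]` (r = 0.05, the top 5%, gives 13.01; r = 0.01
#' gives 20). `rank_from_cscore` is the exact inverse.
#'
#' @param r Rank fraction(s) in `(0, 1]`.
#' @param phred Phred-scaled score(s) >= 0.
#' @return Numeric vector.
#' @examples
#' cscore_from_rank(0.05)
#' rank_from_cscore(20)
#' @export
cscore_from_rank <- function(r) {
  if (any(r <= 0 | r > 1)) {
    stop("rank fraction must lie in (0, 1]", call. = FALSE)
  }
  -10 * log10(r)
}

#' @rdname cscore_from_rank
#' @export
rank_from_cscore <- function(phred) {
  if (any(phred < 0)) stop("phred score must be >= 0", call. = FALSE)
  10^(-phred / 10)
}

#' Select deleterious variants by C-score
#'
#' Keeps variants with C-score strictly above `threshold` (13.01 marks the
#' top 5% of deleteriousness, 20 the top 1%) and tabulates them per
#' population.
#'
#' @param variants Data frame with `cscore` and (optionally) `population`.
#' @param threshold Strict lower bound (default 13.01).
#' @return The retained subset, with attribute `counts` (named counts per
#'   population plus `overall`).
#' @export
select_deleterious <- function(variants, threshold = 13.01) {
  keep <- variants[!is.na(variants$cscore) & variants$cscore > threshold, ,
                   drop = FALSE]
  counts <- c(overall = nrow(keep))
  if ("population" %in% names(keep) && nrow(keep)) {
    counts <- c(counts, table(keep$population))
  }
  attr(keep, "counts") <- counts
  keep
}

#' Case-control association for one variant
#'
#' Builds a 2x2 table from case and control allele statistics and performs a
#' Fisher exact test. `mode = "allele"` contrasts alternate vs reference
#' allele counts (`[AC, AN-AC]` in cases vs controls); `mode = "carrier"`
#' contrasts subjects carrying >= 1 alternate allele vs non-carriers (when
#' carrier counts are not supplied they are approximated by AC carriers
#' among AN/2 subjects, i.e. all carriers heterozygous — the usual situation
#' for rare variants). The default alternative is one-sided case enrichment.
#' The raw cross-product odds ratio `ad/bc` is reported with an infinity
#' flag when a control cell is zero, together with the Haldane-Anscombe
#' (+0.5) corrected OR.
#'
#' @param case_ac,case_an Case alternate allele count and allele number.
#' @param control_ac,control_an Control allele count and number.
#' @param mode `"carrier"` (default) or `"allele"`.
#' @param sided `"one"` (case enrichment; default) or `"two"`.
#' @param case_carriers,case_n,control_carriers,control_n Optional exact
#'   carrier counts and subject totals for carrier mode.
#' @return List of class `association`: `or` (raw, may be `Inf`),
#'   `or_infinite`, `or_haldane`, `p`, `mode`, `sided`, `table`.
#' @export
associate <- function(case_ac, case_an, control_ac, control_an,
                      mode = c("carrier", "allele"),
                      sided = c("one", "two"),
                      case_carriers = NULL, case_n = NULL,
                      control_carriers = NULL, control_n = NULL) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  if (mode == "allele") {
    tab <- matrix(c(case_ac, case_an - case_ac,
                    control_ac, control_an - control_ac),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("case", "control"),
                                  c("alt", "ref")))
  } else {
    cc <- case_carriers %||% case_ac
    cn <- case_n %||% (case_an / 2)
    kc <- control_carriers %||% control_ac
    kn <- control_n %||% (control_an / 2)
    tab <- matrix(round(c(cc, cn - cc, kc, kn - kc)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("case", "control"),
                                  c("carrier", "non-carrier")))
  }
  if (any(tab < 0)) stop("negative cell in 2x2 table", call. = FALSE)
  if (any(rowSums(tab) == 0) || all(tab[, 1] == 0) && all(tab[, 2] == 0)) {
    stop("degenerate 2x2 table margin", call. = FALSE)
  }
  alternative <- if (sided == "one") "greater" else "two.sided"
  p <- fisher.test(tab, alternative = alternative)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  inf_flag <- (c_ == 0 || b == 0) && a > 0
  or_raw <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  structure(list(or = or_raw, or_infinite = inf_flag, or_haldane = or_h,
                 p = p, mode = mode, sided = sided, table = tab),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  or_txt <- if (x$or_infinite) "Inf" else sprintf("%.3g", x$or)
  cat(sprintf("association (%s, %s-sided): OR = %s (Haldane %.3g), p = %.4g\n",
              x$mode, x$sided, or_txt, x$or_haldane, x$p))
  invisible(x)
}

#' Full rare-variant prioritization cascade
#'
#' Runs site and genotype quality filters, recalculates per-population
#' allele statistics, classifies variants against the control table, joins
#' deleteriousness scores, restricts to novel/rare variants with C-score
#' above the threshold, and attaches odds ratios and Fisher p values.
#'
#' @param cohort List with `sites`, `calls`, `subjects` (e.g. from
#'   [sim_cohort()] or [read_cohort_vcf()]).
#' @param controls Control allele-count table (`site_id`, `population`,
#'   `ac`, `an`, `coverage`).
#' @param scores Data frame `site_id`, `cscore`.
#' @param cscore_threshold Strict C-score cutoff (default 13.01, top 5%).
#' @param mode,sided Passed to [associate()].
#' @return Data frame (one row per variant x population with case AC > 0):
#'   allele statistics, control statistics, class, C-score, OR (raw and
#'   Haldane), Fisher p.
#' @export
prioritize_variants <- function(cohort, controls, scores,
                                cscore_threshold = 13.01,
                                mode = "carrier", sided = "one") {
  sites <- site_filter(cohort$sites)
  calls <- genotype_filter(cohort$calls)
  site_pass <- setNames(sites$site_pass, sites$site_id)
  stats <- recalc_stats(calls, cohort$subjects, site_pass = site_pass)
  stats <- stats[stats$defined & stats$ac > 0, , drop = FALSE]
  stats <- classify_variants(stats, controls)
  stats$cscore <- scores$cscore[match(stats$site_id, scores$site_id)]
  stats <- stats[stats$class %in% c("novel", "rare"), , drop = FALSE]
  stats <- select_deleterious(stats, cscore_threshold)
  if (nrow(stats) == 0L) return(stats)
  assoc <- lapply(seq_len(nrow(stats)), function(i) {
    associate(stats$ac[i], stats$an[i],
              ifelse(is.na(stats$control_ac[i]), 0, stats$control_ac[i]),
              ifelse(is.na(stats$control_an[i]),
                     max(stats$control_an, na.rm = TRUE),
                     stats$control_an[i]),
              mode = mode, sided = sided)
  })
  stats$or <- vapply(assoc, function(a) a$or, numeric(1))
  stats$or_infinite <- vapply(assoc, function(a) a$or_infinite, logical(1))
  stats$or_haldane <- vapply(assoc, function(a) a$or_haldane, numeric(1))
  stats$p <- vapply(assoc, function(a) a$p, numeric(1))
  rownames(stats) <- NULL
  stats
}

#' Bundled myelomeningocele ARMC5 variant table
#'
#' Rare deleterious ARMC5 coding variants ascertained in a North-American
#' myelomeningocele case cohort (European-descent and Mexican-American
#' subjects) with matched gnomAD control allele counts (non-Finnish European
#' and Ad Mixed American populations) and CADD Phred deleteriousness scores.
#' Useful as a worked desk-scale example for [select_deleterious()] and
#' [associate()]. The `control_coverage` column is synthetic fill (all loci
#' adequately covered); `published_p` is carried for reference only and is
#' not reproducible from its allele counts under either Fisher
#' construction.
#'
#' @return Data frame with columns `site_id`, `population`,
#'   `protein_change`, `ac`, `an`, `af`, `control_ac`, `control_an`,
#'   `control_af`, `control_coverage`, `cscore`, `published_or`,
#'   `published_p`.
#' @export
mm_variant_table <- function() {
  path <- system.file("extdata", "mm_armc5_variants.tsv", package = "polpool")
  read.delim(path, stringsAsFactors = FALSE)
}
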