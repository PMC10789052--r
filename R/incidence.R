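#' Mendelian genotype expectation for a cross
#'
#' @param cross One of `"het_x_het"`, `"het_x_wt"`, `"wt_x_wt"`.
#' @return Named fractions `wt`, `het`, `ko` summing to 1.
#' @examples
#' mendelian_expectation("het_x_het")["ko"]  # 0.25
#' @export
mendelian_expectation <- function(cross = c("het_x_het", "het_x_wt",
                                            "wt_x_wt")) {
  cross <- match.arg(cross)
  switch(cross,
         het_x_het = c(wt = 0.25, het = 0.50, ko = 0.25),
         het_x_wt = c(wt = 0.50, het = 0.50, ko = 0.00),
         wt_x_wt = c(wt = 1.00, het = 0.00, ko = 0.00))
}

#' Embryonic/perinatal lethality from expected vs observed fractions
#'
#' The headline accounting: `(expected - observed) / expected`, e.g. an
#' expected 25% knockout fraction observed at 10% gives (15/25) = 60%. Note
#' this quantity ignores the renormalization of genotype fractions among
#' survivors; see [estimate_lethality()] for the consistent inversion.
#'
#' @param expected Expected genotype fraction, in `(0, 1]`.
#' @param observed Observed fraction at census; values above `expected`
#'   trigger a warning (no clamping).
#' @return Lethality fraction.
#' @examples
#' lethality(0.25, 0.10)  # 0.6
#' @export
lethality <- function(expected, observed) {
  if (any(expected <= 0 | expected > 1)) {
    stop("expected fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(observed < 0 | observed > 1)) {
    stop("observed fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(observed > expected)) {
    warning("observed fraction exceeds expected; lethality is negative")
  }
  (expected - observed) / expected
}

#' Consistent lethality estimate from a survivor census
#'
#' When a fraction `l` of the expected-`e` genotype dies before census, the
#' genotype's observed fraction among survivors is
#' `f = e (1 - l) / (1 - e l)`; this inverts that relationship:
#' `l = (e - f) / (e (1 - f))`. Use this to recover a planted lethality from
#' [sim_litters()] output.
#'
#' @param observed Observed genotype fraction among survivors.
#' @param expected Expected Mendelian fraction (default 0.25).
#' @return Lethality estimate.
#' @examples
#' estimate_lethality(0.25 * 0.4 / (0.75 + 0.25 * 0.4))  # 0.6
#' @export
estimate_lethality <- function(observed, expected = 0.25) {
  if (any(expected <= 0 | expected > 1)) {
    stop("expected fraction must lie in (0, 1]", call. = FALSE)
  }
  (expected - observed) / (expected * (1 - observed))
}

#' Combined incidence accounting across lethality
#'
#' Converts a phenotype rate among weaned survivors into a rate among all
#' conceived knockouts (`survivor_rate * (1 - lethality)`) and adds the
#' prenatal phenotype rate for the combined incidence. Components are
#' rounded to one decimal (percent) and the combined figure to a whole
#' percent by default, matching the usual presentation; exact values are
#' kept alongside.
#'
#' @param prenatal_rate Phenotype fraction among all KO fetuses.
#' @param survivor_rate Phenotype fraction among weaned KO survivors.
#' @param lethality Fraction of KO conceptuses lost before weaning.
#' @param component_digits,combined_digits Rounding (in percent) for the
#'   component and combined figures.
#' @return List of class `cross_account`: `survivor_pct` (phenotype among
#'   all KO contributed by survivors), `prenatal_pct`, `combined_pct`,
#'   and their unrounded counterparts (`*_exact`, fractions).
#' @examples
#' acc <- incidence_account(0.146, 0.277, 0.60)
#' acc$survivor_pct   # 11.1
#' acc$combined_pct   # 26
#' @export
incidence_account <- function(prenatal_rate, survivor_rate, lethality,
                              component_digits = 1, combined_digits = 0) {
  for (v in c(prenatal_rate, survivor_rate, lethality)) {
    if (v < 0 || v > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  survivor_exact <- survivor_rate * (1 - lethality)
  combined_exact <- prenatal_rate + survivor_exact
  prenatal_pct <- round(100 * prenatal_rate, component_digits)
  survivor_pct <- round(100 * survivor_exact, component_digits)
  combined_pct <- round(prenatal_pct + survivor_pct, combined_digits)
  structure(list(
    prenatal_pct = prenatal_pct,
    survivor_pct = survivor_pct,
    combined_pct = combined_pct,
    prenatal_exact = prenatal_rate,
    survivor_exact = survivor_exact,
    combined_exact = combined_exact,
    lethality = lethality
  ), class = "cross_account")
}

#' @export
print.cross_account <- function(x, ...) {
  cat(sprintf(
    "incidence account: %.1f%% prenatal + %.1f%% in survivors = %g%% combined (lethality %.0f%%)\n",
    x$prenatal_pct, x$survivor_pct, x$combined_pct, 100 * x$lethality))
  invisible(x)
}

#' Chi-squared test of incidence proportions
#'
#' Pearson chi-squared on a 2 x k table of (affected, unaffected) counts,
#' without continuity correction by default (Yates available via `correct`).
#'
#' @param tab Matrix or data frame coercible to a 2 x k count table.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List: `statistic`, `df`, `p`.
#' @examples
#' chi2_prop(rbind(c(10, 90), c(50, 50)))$statistic  # 38.095...
#' @export
chi2_prop <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stop("zero margin in incidence table", call. = FALSE)
  }
  if (identical(dim(tab), c(2L, 2L)) && all(tab[1, ] == tab[2, ])) {
    return(list(statistic = 0, df = 1L, p = 1))
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
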