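#' Carrier frequency point estimate
#'
#' @param k Number of carriers observed.
#' @param n Cohort size (`n >= 1`).
#' @return The proportion `k/n`.
#' @export
carrier_frequency <- function(k, n) {
  check_kn(k, n)
  k / n
}

#' Wald binomial confidence interval
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` with `z` the
#' standard-normal quantile at `(1+confidence)/2`, clipped to `[0, 1]`.
#' This is the construction whose 95% interval for 10 of 46 renders as
#' 10--34%; the Wilson and exact intervals do not (12--36% and 11--36%),
#' and are available through [binom_ci()].
#'
#' @param k Successes. @param n Trials. @param confidence Level in (0, 1).
#' @return Named vector `c(low, high)`.
#' @export
wald_ci <- function(k, n, confidence = 0.95) {
  check_kn(k, n)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  p <- k / n
  z <- stats::qnorm((1 + confidence) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

#' Binomial proportion confidence interval, selectable method
#'
#' `"wald"` is the package default (see [wald_ci()]); `"wilson"` is the
#' score interval (via [stats::prop.test()] without continuity correction);
#' `"exact"` is Clopper-Pearson (via [stats::binom.test()]).
#'
#' @inheritParams wald_ci
#' @param method One of `"wald"`, `"wilson"`, `"exact"`.
#' @return Named vector `c(low, high)`.
#' @export
binom_ci <- function(k, n, confidence = 0.95,
                     method = c("wald", "wilson", "exact")) {
  method <- match.arg(method)
  check_kn(k, n)
  ci <- switch(method,
    wald = wald_ci(k, n, confidence),
    wilson = {
      ci <- stats::prop.test(k, n, conf.level = confidence,
                             correct = FALSE)$conf.int
      c(low = ci[1L], high = ci[2L])
    },
    exact = {
      ci <- stats::binom.test(k, n, conf.level = confidence)$conf.int
      c(low = ci[1L], high = ci[2L])
    })
  ci
}

#' @noRd
check_kn <- function(k, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single count >= 1")
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n)
    stop("k must satisfy 0 <= k <= n")
  invisible(TRUE)
}

#' Expected number of null mutations per individual
#'
#' With per-individual allele counts supplied, returns their mean (a
#' homozygote contributes 2); otherwise falls back to `k/n`, which equals
#' the mutation rate whenever no individual carries more than one allele.
#'
#' @param x An `hrd_screen` object, or the carrier count `k`.
#' @param ... Passed on to methods.
#' @return Null alleles per genome (a rate).
#' @export
null_mutation_rate <- function(x, ...) UseMethod("null_mutation_rate")

#' @param n Cohort size (default method).
#' @param per_individual_counts Optional integer vector of null-allele
#'   counts, one per individual (overrides `k/n`).
#' @rdname null_mutation_rate
#' @export
null_mutation_rate.default <- function(x, n, per_individual_counts = NULL, ...) {
  if (!is.null(per_individual_counts)) {
    if (!length(per_individual_counts)) return(0)
    return(sum(per_individual_counts) / length(per_individual_counts))
  }
  check_kn(x, n)
  x / n
}

#' @rdname null_mutation_rate
#' @export
null_mutation_rate.hrd_screen <- function(x, ...) {
  null_mutation_rate.default(x$k, x$n,
                             per_individual_counts = x$per_individual)
}

#' Extrapolate a null-mutation rate to a "one in X individuals" figure
#'
#' Inflates the observed null-allele rate per genome by the null:missense
#' ratio of known pathogenic alleles (`inflated = m * (1 + ratio)`, i.e.
#' `ratio` missense alleles are assumed for every null allele) and, when
#' `include_unknown_genes = TRUE`, further divides by the fraction of
#' recessive cases attributable to known genes. The headline figure is the
#' reciprocal of the inflated rate ("1 carrier in X individuals"). An
#' alternative convention treating the rate as a Poisson mean and reporting
#' `1/(1 - exp(-rate))` is exposed via `convention = "poisson_carrier"`; it
#' yields systematically larger X and is not the default.
#'
#' @param m Null mutations per genome (`m > 0`).
#' @param null_to_missense_ratio Missense alleles per null allele among
#'   known pathogenic alleles (default 0.87).
#' @param known_gene_case_fraction Proportion of recessive cases explained
#'   by known genes (default 0.70).
#' @param include_unknown_genes If `TRUE`, correct for the unexplained case
#'   fraction as well.
#' @param convention `"reciprocal"` (default) or `"poisson_carrier"`.
#' @return List with `inflated_rate`, `one_in_x` (unrounded) and
#'   `one_in_x_display` (rounded to one decimal).
#' @export
extrapolate_one_in_x <- function(m, null_to_missense_ratio = 0.87,
                                 known_gene_case_fraction = 0.7,
                                 include_unknown_genes = FALSE,
                                 convention = c("reciprocal", "poisson_carrier")) {
  convention <- match.arg(convention)
  if (!is.numeric(m) || length(m) != 1L || m <= 0)
    stop("m must be a positive rate; one_in_x is undefined at m = 0")
  if (null_to_missense_ratio < 0) stop("null_to_missense_ratio must be >= 0")
  if (known_gene_case_fraction <= 0 || known_gene_case_fraction > 1)
    stop("known_gene_case_fraction must lie in (0, 1]")
  inflated <- m * (1 + null_to_missense_ratio)
  if (include_unknown_genes) inflated <- inflated / known_gene_case_fraction
  one_in_x <- switch(convention,
    reciprocal = 1 / inflated,
    poisson_carrier = 1 / (1 - exp(-inflated)))
  list(inflated_rate = inflated, one_in_x = one_in_x,
       one_in_x_display = round(one_in_x, 1))
}

#' Recessive disease risk under consanguinity
#'
#' Standard inbreeding-load arithmetic over a panel of genes with
#' deleterious allele frequencies `q_i`, treated as independent and rare:
#' the probability of an affected offspring is
#' `sum_i [(1-F) q_i^2 + F q_i]` with `F` the inbreeding coefficient
#' (first cousins: `F = 1/16`), and the risk ratio compares it with random
#' mating (`F = 0`).
#'
#' @param allele_freqs Numeric vector of per-gene deleterious allele
#'   frequencies, each in `[0, 0.5]`.
#' @param inbreeding Inbreeding coefficient `F` in `[0, 1]`.
#' @return List with `p_affected` and `risk_ratio_vs_panmixia`.
#' @export
consanguinity_risk <- function(allele_freqs, inbreeding = 0) {
  q <- allele_freqs
  if (!is.numeric(q) || !length(q) || any(q < 0) || any(q > 0.5))
    stop("allele frequencies must lie in [0, 0.5]")
  if (inbreeding < 0 || inbreeding > 1)
    stop("inbreeding coefficient must lie in [0, 1]")
  p_affected <- sum((1 - inbreeding) * q^2 + inbreeding * q)
  if (p_affected > 1)
    stop("summed affected-genotype probability exceeds 1; ",
         "allele frequencies implausible")
  p0 <- sum(q^2)
  if (p0 == 0)
    stop("all allele frequencies zero; risk ratio undefined")
  list(p_affected = p_affected, risk_ratio_vs_panmixia = p_affected / p0)
}

#' Carrier summary of a cohort screen
#'
#' @param k Carriers. @param n Cohort size. @param confidence CI level.
#' @param method CI method (see [binom_ci()]).
#' @return A `carrier_summary`: n, k, frequency, ci_low, ci_high,
#'   confidence, method.
#' @export
carrier_summary <- function(k, n, confidence = 0.95, method = "wald") {
  check_kn(k, n)
  ci <- binom_ci(k, n, confidence, method)
  structure(list(n = as.integer(n), k = as.integer(k),
                 frequency = k / n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 confidence = confidence, method = method),
            class = "carrier_summary")
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat(sprintf("Carriers of >=1 null allele: %d of %d individuals (~%d%%)\n",
              x$k, x$n, round(100 * x$frequency)))
  cat(sprintf("%d%% CI (%s): %d-%d%%\n", round(100 * x$confidence), x$method,
              round(100 * x$ci_low), round(100 * x$ci_high)))
  invisible(x)
}
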