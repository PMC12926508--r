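#' Per-line mutation rate
#'
#' `mu = x / (g * ploidy * n)`: mutations per site per generation, with the
#' ploidy factor (2 for a diploid genome) because heterozygous de novo
#' mutations are surveyed over both homologs.
#'
#' @param x Mutation count (vectorized over lines).
#' @param g Generations per line.
#' @param n Callable sites per line.
#' @param ploidy Ploidy (default 2).
#' @return Rates per site per generation.
#' @export
#' @examples
#' per_line_rate(112, 507, 8.766e7)   # ~1.26e-9
per_line_rate <- function(x, g, n, ploidy = 2) {
  if (any(g <= 0)) stopf("generations must be positive")
  if (any(n <= 0)) stopf("callable sites must be positive")
  if (any(x < 0)) stopf("mutation counts must be nonnegative")
  x / (g * ploidy * n)
}

#' Pooled mutation rate with a confidence interval across lines
#'
#' The experiment-wide rate is the unweighted mean of per-line rates. The
#' default interval uses the t quantile on `L - 1` degrees of freedom,
#' appropriate for the small line counts of MA experiments;
#' `method = "normal"` uses the z quantile (`mean +/- 1.96 * SE` at 95%),
#' which is how published MA summaries are usually reported.
#'
#' @param rates Numeric vector of per-line rates (length >= 2).
#' @param conf Confidence level (default 0.95).
#' @param method `"t"` (default) or `"normal"`.
#' @return List with `mean`, `ci_low`, `ci_high`, `se`, `n_lines`.
#' @export
pooled_rate_ci <- function(rates, conf = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  if (length(rates) < 2) stopf("need at least two per-line rates")
  assert_scalar_number(conf, "conf", 0, 1)
  m <- mean(rates)
  se <- sd(rates) / sqrt(length(rates))
  q <- if (method == "normal") qnorm(1 - (1 - conf) / 2)
       else qt(1 - (1 - conf) / 2, df = length(rates) - 1)
  list(mean = m, ci_low = m - q * se, ci_high = m + q * se,
       se = se, n_lines = length(rates))
}

#' Per-line and pooled rate table for a set of calls
#'
#' Convenience wrapper: counts calls of one class per line, applies
#' [per_line_rate()] with each line's generations and callable sites, and
#' pools with [pooled_rate_ci()].
#'
#' @param calls An `ma_calls` table.
#' @param exposures Data.table with `line`, `g`, `n_callable` (as produced
#'   by [emit_evidence()]).
#' @param classes Which event classes to count (default SNMs).
#' @param ... Passed to [pooled_rate_ci()].
#' @return List of class `ma_rate_estimate` with `per_line` (line, x, g, n,
#'   mu) and the pooled `mean`, `ci_low`, `ci_high`.
#' @export
rate_estimate <- function(calls, exposures, classes = "SNM", ...) {
  cnt <- calls[class %in% classes, .N, by = line]
  per_line <- merge(exposures[, .(line, g, n = n_callable)],
                    cnt, by = "line", all.x = TRUE)
  per_line[is.na(N), N := 0L]
  data.table::setnames(per_line, "N", "x")
  per_line[, mu := per_line_rate(x, g, n)]
  pooled <- pooled_rate_ci(per_line$mu, ...)
  structure(c(list(per_line = per_line[]), pooled),
            class = "ma_rate_estimate")
}

#' @export
print.ma_rate_estimate <- function(x, ...) {
  cat(sprintf("Pooled rate %.3g per site per generation (CI %.3g - %.3g, %d lines)\n",
              x$mean, x$ci_low, x$ci_high, x$n_lines))
  invisible(x)
}

#' Selection-corrected mutation rate
#'
#' Inflates the raw rate for the under-observation of a depleted site
#' class: `corrected = f * (1 + d) * mu + (1 - f) * mu`, where `f` is the
#' genomic fraction of the depleted class and `d` its fractional deficit.
#'
#' @param raw Raw pooled rate.
#' @param target_fraction Fraction of the genome in the depleted class.
#' @param deficit Fractional under-observation of that class.
#' @return The corrected rate.
#' @export
#' @examples
#' corrected_rate(2.23e-9, 0.21, 0.47)   # ~2.45e-9
corrected_rate <- function(raw, target_fraction, deficit) {
  assert_scalar_number(target_fraction, "target_fraction", 0, 1)
  if (any(raw < 0)) stopf("raw rate must be nonnegative")
  target_fraction * (1 + deficit) * raw + (1 - target_fraction) * raw
}

#' Fractional deficit of an observed rate against a reference rate
#'
#' `deficit = 1 - target / reference`: e.g. a depleted class observed at
#' 53% of the reference rate is under-observed by 47%.
#'
#' @param observed_rate_target Rate in the depleted class.
#' @param observed_rate_reference Rate in the unconstrained classes.
#' @return The deficit (can be negative when the target is enriched).
#' @export
estimate_deficit <- function(observed_rate_target, observed_rate_reference) {
  if (any(observed_rate_reference <= 0)) stopf("reference rate must be > 0")
  1 - observed_rate_target / observed_rate_reference
}

#' Equilibrium GC content under mutation pressure
#'
#' `GC_eq = u / (u + v)` with `u` the A/T -> G/C and `v` the G/C -> A/T
#' per-site substitution rate: the GC fraction at which GC gains and losses
#' balance, assuming base composition has reached mutational steady state.
#'
#' @param u A/T -> G/C rate.
#' @param v G/C -> A/T rate.
#' @return The equilibrium GC fraction in `[0, 1]`.
#' @export
equilibrium_gc <- function(u, v) {
  if (any(u < 0) || any(v < 0)) stopf("rates must be nonnegative")
  if (any(u + v == 0)) stopf("u + v must be positive")
  u / (u + v)
}

#' Effective population size from synonymous diversity
#'
#' `N_e = pi_s / (4 * mu)` for a diploid population at mutation-drift
#' equilibrium.
#'
#' @param pi_s Nucleotide diversity at synonymous sites.
#' @param mu Mutation rate per site per generation.
#' @return Effective population size.
#' @export
#' @examples
#' effective_population_size(0.017, 2.45e-9)   # ~1.73 million
effective_population_size <- function(pi_s, mu) {
  if (any(mu <= 0)) stopf("'mu' must be positive")
  if (any(pi_s < 0)) stopf("'pi_s' must be nonnegative")
  pi_s / (4 * mu)
}
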