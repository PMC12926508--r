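#' Hard-filter thresholds for variant-site curation
#'
#' The nine-rule stack applied to raw multi-sample variant records before
#' ancestral inference. Rules and defaults: exclude SNPs or indels within
#' `indel_proximity_window` (20 bp) of another indel; drop tri-/multi-allelic
#' sites; keep heterozygous genotypes only when the within-sample minor-read
#' fraction is at least `het_min_allele_fraction` (0.2), the alternate
#' allele has at least `min_alt_reads` (5) supporting reads, and an exact
#' two-sided binomial test against 1:1 allele balance is not rejected at
#' `balance_alpha`; require per-line depth in `[min_depth, max_depth]`
#' (20-300, inclusive); drop sites with Fisher strand bias `FS >` `max_fs`
#' (60), `MQRankSum <` `min_mq_rank_sum` (-12.5) or `ReadPosRankSum <`
#' `min_read_pos_rank_sum` (-8.0) - rank-sum annotations absent at a site
#' pass, since they only exist where both allele classes are observed.
#'
#' `balance_alpha` defaults to 0.001: the balance screen is meant to catch
#' collapsed paralogs and similar artifacts with grossly skewed ratios, and
#' a loose alpha would discard a deterministic fraction alpha of genuine
#' heterozygous mutations, biasing every downstream rate estimate by the
#' same fraction.
#'
#' @param indel_proximity_window Bases around an indel within which other
#'   variants are excluded.
#' @param drop_multiallelic Drop sites with more than one ALT allele.
#' @param het_min_allele_fraction Minimum within-sample minor-read fraction
#'   for a het call.
#' @param min_depth,max_depth Inclusive per-line depth bounds.
#' @param max_fs Maximum Fisher-strand phred score (strictly greater is
#'   removed).
#' @param min_mq_rank_sum,min_read_pos_rank_sum Lower bounds on rank-sum z
#'   scores (strictly smaller is removed).
#' @param balance_alpha Significance level of the exact two-sided binomial
#'   allele-balance test.
#' @param min_alt_reads Minimum reads supporting the alternate allele of a
#'   het call.
#' @return A validated list of class `ma_filter_config`.
#' @export
filter_config <- function(indel_proximity_window = 20L,
                          drop_multiallelic = TRUE,
                          het_min_allele_fraction = 0.2,
                          min_depth = 20, max_depth = 300,
                          max_fs = 60,
                          min_mq_rank_sum = -12.5,
                          min_read_pos_rank_sum = -8.0,
                          balance_alpha = 0.001,
                          min_alt_reads = 5L) {
  assert_scalar_number(indel_proximity_window, "indel_proximity_window", 0)
  assert_scalar_number(het_min_allele_fraction, "het_min_allele_fraction",
                       0, 1)
  assert_scalar_number(min_depth, "min_depth", 0)
  assert_scalar_number(max_depth, "max_depth", min_depth)
  assert_scalar_number(max_fs, "max_fs")
  assert_scalar_number(min_mq_rank_sum, "min_mq_rank_sum")
  assert_scalar_number(min_read_pos_rank_sum, "min_read_pos_rank_sum")
  if (!is.numeric(balance_alpha) || balance_alpha <= 0 || balance_alpha >= 1)
    stopf("'balance_alpha' must be in (0, 1)")
  assert_scalar_number(min_alt_reads, "min_alt_reads", 0)
  structure(list(indel_proximity_window = as.integer(indel_proximity_window),
                 drop_multiallelic = isTRUE(drop_multiallelic),
                 het_min_allele_fraction = het_min_allele_fraction,
                 min_depth = min_depth, max_depth = max_depth,
                 max_fs = max_fs, min_mq_rank_sum = min_mq_rank_sum,
                 min_read_pos_rank_sum = min_read_pos_rank_sum,
                 balance_alpha = balance_alpha,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "ma_filter_config")
}

#' Exact two-sided binomial test for allele balance
#'
#' Tests whether `alt_reads` out of `ref_reads + alt_reads` deviates from
#' the 1:1 allele balance expected of a true heterozygote. The p-value is
#' the exact two-sided tail: the sum of probabilities of all outcomes no
#' more likely than the observed one under Binomial(n, 0.5).
#'
#' @param ref_reads,alt_reads Nonnegative read counts (vectorized).
#' @return Two-sided p-values in `[0, 1]`.
#' @export
#' @examples
#' binomial_balance_test(10, 10)   # 1
#' binomial_balance_test(30, 10)   # ~0.0022
binomial_balance_test <- function(ref_reads, alt_reads) {
  n <- ref_reads + alt_reads
  if (any(is.na(n)) || any(n < 1))
    stopf("each test needs at least one read")
  k <- pmin(ref_reads, alt_reads)
  # symmetric null: two-sided tail is twice the lower tail of the minor
  # count, with the central term not double-counted when ref == alt
  p <- 2 * pbinom(k, n, 0.5) - ifelse(2 * k == n, dbinom(k, n, 0.5), 0)
  pmin(p, 1)
}

FILTER_RULES <- c("indel_proximity", "multiallelic", "het_allele_fraction",
                  "depth", "fs", "mq_rank_sum", "read_pos_rank_sum",
                  "min_alt_reads", "allele_balance")

#' Apply the hard-filter stack to variant records
#'
#' Site-level rules (indel proximity, multi-allelic, FS, rank sums) drop a
#' site for every line; genotype-level rules (het allele fraction, depth,
#' alternate-read support, allele balance) set the failing line's genotype
#' to missing. Each removal is tallied under the first failing rule, in
#' the order listed in [filter_config()]; the surviving *set* does not
#' depend on rule order because every rule is an independent predicate on
#' the input records.
#'
#' @param records An `ma_records` object (see [read_variants()]), sorted by
#'   chromosome and position.
#' @param config An [filter_config()].
#' @param mask Optional `ma_callable` mask; genotypes at sites that are
#'   non-callable for a line are removed (tallied under the depth rule).
#' @return A list with `records` (the surviving `ma_records`) and `report`
#'   (class `ma_filter_report`): per-rule site and genotype removal counts
#'   and per-line surviving heterozygous / homozygous genotype counts.
#' @export
apply_site_filters <- function(records, config = filter_config(),
                               mask = NULL) {
  stopifnot(inherits(records, "ma_records"),
            inherits(config, "ma_filter_config"))
  s <- data.table::copy(records$sites)
  g <- data.table::copy(records$geno)
  if (is.unsorted(order(s$chrom, s$pos)) ||
      any(s[, is.unsorted(pos), by = chrom]$V1))
    stopf("records must be sorted by chromosome and position")

  ns <- nrow(s)
  input_geno <- g[, .(n_input = sum(!is.na(gt))), by = line]

  # --- site-level rules, first-failure tally
  site_fail <- rep(NA_character_, ns)

  is_indel <- nchar(s$ref) != 1L |
    vapply(strsplit(s$alt, ","), function(a) any(nchar(a) != 1L), logical(1))
  near <- rep(FALSE, ns)
  w <- config$indel_proximity_window
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    ipos <- s$pos[idx][is_indel[idx]]
    if (!length(ipos)) next
    d <- nearest_other_distance(s$pos[idx], ipos, is_indel[idx])
    near[idx] <- d <= w
  }
  site_fail[near] <- "indel_proximity"

  multi <- grepl(",", s$alt, fixed = TRUE)
  if (config$drop_multiallelic)
    site_fail[is.na(site_fail) & multi] <- "multiallelic"

  fs_bad <- !is.na(s$fs) & s$fs > config$max_fs
  mq_bad <- !is.na(s$mqrs) & s$mqrs < config$min_mq_rank_sum
  rp_bad <- !is.na(s$rprs) & s$rprs < config$min_read_pos_rank_sum
  site_fail[is.na(site_fail) & fs_bad] <- "fs"
  site_fail[is.na(site_fail) & mq_bad] <- "mq_rank_sum"
  site_fail[is.na(site_fail) & rp_bad] <- "read_pos_rank_sum"

  site_rules <- data.table::data.table(rule = FILTER_RULES)
  tab <- table(site_fail)
  site_rules[, sites_removed := as.integer(tab[rule])]
  site_rules[is.na(sites_removed), sites_removed := 0L]

  keep_sites <- is.na(site_fail)
  skey <- paste(s$chrom, s$pos)
  g_keep <- paste(g$chrom, g$pos) %in% skey[keep_sites]
  g <- g[g_keep]
  s <- s[keep_sites]

  # --- genotype-level rules
  g[, fail := NA_character_]
  het <- !is.na(g$gt) & g$gt == 1L
  tot <- g$ad_ref + g$ad_alt
  minor_frac <- ifelse(tot > 0, pmin(g$ad_ref, g$ad_alt) / tot, 0)
  g[het & minor_frac < config$het_min_allele_fraction & is.na(fail),
    fail := "het_allele_fraction"]

  dp_bad <- is.na(g$dp) | g$dp < config$min_depth | g$dp > config$max_depth
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "ma_callable"))
    mk <- mask$mask[callable == FALSE]
    if (nrow(mk)) {
      bad_key <- paste(mk$chrom, mk$pos, mk$line)
      dp_bad <- dp_bad | (paste(g$chrom, g$pos, g$line) %in% bad_key)
    }
  }
  g[!is.na(gt) & dp_bad & is.na(fail), fail := "depth"]

  low_alt <- het & g$ad_alt < config$min_alt_reads
  g[low_alt & is.na(fail), fail := "min_alt_reads"]

  bal_idx <- which(het & is.na(g$fail) & tot >= 1)
  if (length(bal_idx)) {
    p <- binomial_balance_test(g$ad_ref[bal_idx], g$ad_alt[bal_idx])
    g$fail[bal_idx[p < config$balance_alpha]] <- "allele_balance"
  }

  geno_rules <- g[!is.na(fail), .(genotypes_removed = .N), by = fail]
  data.table::setnames(geno_rules, "fail", "rule")
  g[!is.na(fail), gt := NA_integer_]
  g[, fail := NULL]

  surviving <- g[, .(n_het = sum(gt == 1L, na.rm = TRUE),
                     n_hom = sum(gt != 1L, na.rm = TRUE)), by = line]

  report <- structure(list(site_rules = site_rules,
                           genotype_rules = geno_rules,
                           surviving = surviving,
                           input_genotypes = input_geno),
                      class = "ma_filter_report")
  out <- records
  out$sites <- s
  out$geno <- g
  list(records = out, report = report)
}

# distance from every position to the nearest indel position, excluding a
# position's own entry when it is itself an indel
nearest_other_distance <- function(pos, ipos, self_is_indel) {
  n <- length(pos)
  if (!length(ipos)) return(rep(Inf, n))
  ipos <- sort(ipos)
  lo <- findInterval(pos, ipos)
  d_lo <- ifelse(lo >= 1, pos - ipos[pmax(lo, 1)], Inf)
  d_hi <- ifelse(lo < length(ipos), ipos[pmin(lo + 1L, length(ipos))] - pos,
                 Inf)
  out <- pmin(d_lo, d_hi)
  # an indel's own entry sits at distance 0: replace with gap to the
  # nearest *other* indel
  self <- which(self_is_indel & out == 0)
  if (length(self)) {
    r <- match(pos[self], ipos)
    left <- ifelse(r > 1, ipos[r] - ipos[pmax(r - 1L, 1)], Inf)
    right <- ifelse(r < length(ipos), ipos[pmin(r + 1L, length(ipos))] -
                      ipos[r], Inf)
    out[self] <- pmin(left, right)
  }
  out
}

#' @export
print.ma_filter_report <- function(x, ...) {
  cat("Site-level removals:\n")
  print(x$site_rules)
  cat("Genotype-level removals:\n")
  print(x$genotype_rules)
  cat("Surviving genotypes per line:\n")
  print(x$surviving)
  invisible(x)
}
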