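#' Parameters of the two-state LOH hidden Markov model
#'
#' The chain runs over the ordered ancestral heterozygous sites of a
#' chromosome with states RETAINED (still heterozygous) and LOH
#' (homozygosed by descent). Emissions are the focal line's genotype calls
#' at those sites; miscall rates absorb genotyping error. Decoded LOH runs
#' are kept only when their minimal span exceeds `min_tract_span` and they
#' contain at least `min_tract_sites` homozygous observations.
#'
#' @param p_loh_entry Per-site transition probability RETAINED -> LOH.
#' @param p_loh_exit Per-site transition probability LOH -> RETAINED.
#' @param het_miscall_rate Probability an LOH site still reads heterozygous.
#' @param hom_miscall_rate Probability a retained het site reads homozygous.
#' @param min_tract_span Minimum minimal-span length in bases (default
#'   1,000).
#' @param min_tract_sites Minimum homozygous observations per tract.
#' @param background_het_fraction Minimum fraction of a tract's sites that
#'   must remain heterozygous in every non-focal line.
#' @return List of class `ma_hmm_params`.
#' @export
hmm_params <- function(p_loh_entry = 1e-6, p_loh_exit = 1e-3,
                       het_miscall_rate = 0.01, hom_miscall_rate = 0.01,
                       min_tract_span = 1000, min_tract_sites = 3L,
                       background_het_fraction = 0.9) {
  for (p in c(p_loh_entry, p_loh_exit, het_miscall_rate, hom_miscall_rate))
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stopf("HMM probabilities must lie strictly in (0, 1)")
  assert_scalar_number(min_tract_span, "min_tract_span", 1)
  assert_scalar_number(min_tract_sites, "min_tract_sites", 1)
  assert_scalar_number(background_het_fraction, "background_het_fraction",
                       0, 1)
  structure(list(p_loh_entry = p_loh_entry, p_loh_exit = p_loh_exit,
                 het_miscall_rate = het_miscall_rate,
                 hom_miscall_rate = hom_miscall_rate,
                 min_tract_span = min_tract_span,
                 min_tract_sites = as.integer(min_tract_sites),
                 background_het_fraction = background_het_fraction),
            class = "ma_hmm_params")
}

# Viterbi decoding of the two-state chain over one chromosome's observation
# vector (0 = het, 1 = hom, NA = missing). Returns the decoded state per
# site (1 = RETAINED, 2 = LOH).
viterbi_loh <- function(obs, params) {
  n <- length(obs)
  if (n == 0) return(integer(0))
  lt <- log(matrix(c(1 - params$p_loh_entry, params$p_loh_entry,
                     params$p_loh_exit, 1 - params$p_loh_exit),
                   nrow = 2, byrow = TRUE))
  # emission log-probs per state for obs 0/1; missing observations are
  # uninformative (log 1)
  em <- log(matrix(c(1 - params$hom_miscall_rate, params$hom_miscall_rate,
                     params$het_miscall_rate, 1 - params$het_miscall_rate),
                   nrow = 2, byrow = TRUE))
  e_at <- function(state, o) if (is.na(o)) 0 else em[state, o + 1L]

  # stationary-ish prior: start retained with high probability
  delta <- c(log(1 - params$p_loh_entry) + e_at(1, obs[1]),
             log(params$p_loh_entry) + e_at(2, obs[1]))
  psi <- matrix(0L, nrow = n, ncol = 2)
  for (t in seq_len(n - 1L)[n > 1]) {
    o <- obs[t + 1L]
    e1 <- e_at(1, o); e2 <- e_at(2, o)
    c11 <- delta[1] + lt[1, 1]; c21 <- delta[2] + lt[2, 1]
    c12 <- delta[1] + lt[1, 2]; c22 <- delta[2] + lt[2, 2]
    if (c11 >= c21) { d1 <- c11 + e1; psi[t + 1L, 1] <- 1L }
    else { d1 <- c21 + e1; psi[t + 1L, 1] <- 2L }
    if (c12 >= c22) { d2 <- c12 + e2; psi[t + 1L, 2] <- 1L }
    else { d2 <- c22 + e2; psi[t + 1L, 2] <- 2L }
    delta <- c(d1, d2)
  }
  states <- integer(n)
  states[n] <- if (delta[1] >= delta[2]) 1L else 2L
  if (n > 1) for (t in (n - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  states
}

#' Detect loss-of-heterozygosity tracts per line
#'
#' Viterbi-decodes the two-state {RETAINED, LOH} chain over each line's
#' genotype observations at the ancestral heterozygous sites, then applies
#' the post-filters: minimal span (first to last homozygous site) longer
#' than `min_tract_span`, at least `min_tract_sites` homozygous sites, and
#' the tract's sites still heterozygous in at least
#' `background_het_fraction` of observations in every non-focal line. The
#' maximal span extends to one base inside the nearest flanking site that
#' remained heterozygous in the focal line (clipped to the chromosome).
#'
#' @param records Filtered `ma_records`.
#' @param ancestral `ma_ancestral` table; its `anc_gt == 1` rows define
#'   the heterozygous-site scaffold.
#' @param params An [hmm_params()] object.
#' @param ref Optional `ma_reference` for chromosome-end clipping of
#'   maximal spans.
#' @return List of class `ma_loh`: `tracts` (line, chrom, min_start,
#'   min_end, max_start, max_end, n_sites, mechanism = "unclassified") and
#'   `sites` (line, chrom, pos, resolved genotype 0/2 and resolved allele).
#' @export
detect_loh_tracts <- function(records, ancestral, params = hmm_params(),
                              ref = NULL) {
  stopifnot(inherits(records, "ma_records"),
            inherits(ancestral, "ma_ancestral"),
            inherits(params, "ma_hmm_params"))
  het_sites <- ancestral[anc_gt == 1L, .(chrom, pos)]
  empty <- list(
    tracts = data.table::data.table(
      line = character(), chrom = character(), min_start = integer(),
      min_end = integer(), max_start = integer(), max_end = integer(),
      n_sites = integer(), mechanism = character()),
    sites = data.table::data.table(
      line = character(), chrom = character(), pos = integer(),
      gt = integer(), allele = character()))
  if (!nrow(het_sites))
    return(structure(empty, class = "ma_loh"))

  g <- merge(records$geno, het_sites, by = c("chrom", "pos"))
  s <- records$sites
  tracts_l <- list(); sites_l <- list()

  for (ch in unique(het_sites$chrom)) {
    gs <- g[chrom == ch]
    if (!nrow(gs)) next
    wide <- data.table::dcast(gs, pos ~ line, value.var = "gt")
    data.table::setorder(wide, pos)
    pos <- wide$pos
    lines <- setdiff(names(wide), "pos")
    gm <- as.matrix(wide[, !"pos"])
    chrom_end <- if (!is.null(ref)) Biostrings::width(ref$seq[ch]) else
      max(pos)

    for (l in lines) {
      gv <- gm[, l]
      obs <- ifelse(is.na(gv), NA_integer_, ifelse(gv == 1L, 0L, 1L))
      states <- viterbi_loh(obs, params)
      r <- rle(states == 2L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (ri in runs) {
        i0 <- starts[ri]; i1 <- ends[ri]
        hom_idx <- i0:i1
        hom_idx <- hom_idx[!is.na(obs[hom_idx]) & obs[hom_idx] == 1L]
        if (length(hom_idx) < params$min_tract_sites) next
        min_start <- pos[hom_idx[1]]
        min_end <- pos[hom_idx[length(hom_idx)]]
        if (min_end - min_start + 1L <= params$min_tract_span) next
        # background: every other line must remain het over the tract
        ok <- TRUE
        for (l2 in setdiff(lines, l)) {
          g2 <- gm[hom_idx, l2]
          frac <- mean(g2 == 1L, na.rm = TRUE)
          if (!is.nan(frac) && frac < params$background_het_fraction) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        max_start <- if (i0 > 1L) pos[i0 - 1L] + 1L else 1L
        max_end <- if (i1 < length(pos)) pos[i1 + 1L] - 1L else chrom_end
        tracts_l[[length(tracts_l) + 1L]] <- data.table::data.table(
          line = l, chrom = ch, min_start = min_start, min_end = min_end,
          max_start = max_start, max_end = max_end,
          n_sites = length(hom_idx), mechanism = "unclassified")
        sites_l[[length(sites_l) + 1L]] <- data.table::data.table(
          line = l, chrom = ch, pos = pos[hom_idx],
          gt = gv[hom_idx])
      }
    }
  }
  if (!length(tracts_l))
    return(structure(empty, class = "ma_loh"))
  tracts <- data.table::rbindlist(tracts_l)
  sites <- data.table::rbindlist(sites_l)
  # resolved allele per converted site from the site's REF/ALT
  sites <- merge(sites, s[, .(chrom, pos, ref, alt)], by = c("chrom", "pos"),
                 all.x = TRUE, sort = FALSE)
  sites[, allele := ifelse(gt == 0L, ref, alt)]
  data.table::setorder(tracts, line, chrom, min_start)
  data.table::setorder(sites, line, chrom, pos)
  structure(list(tracts = tracts, sites = sites), class = "ma_loh")
}

#' LOH rate per heterozygous site per generation
#'
#' `mu = x / (g * n_het)` with `x` the number of homozygosed (LOH) sites,
#' `g` the generations and `n_het` the ancestral heterozygous-site count.
#' The experiment-wide rate is the unweighted mean of per-line rates,
#' lines with zero events contributing rate 0.
#'
#' @param x LOH site count (vectorized over lines).
#' @param g Generations.
#' @param n_het Ancestral heterozygous sites.
#' @return Rates per heterozygous site per generation.
#' @export
#' @examples
#' loh_rate(264, 507, 3.14e5)   # ~1.66e-6
loh_rate <- function(x, g, n_het) {
  if (any(g <= 0)) stopf("generations must be positive")
  if (any(n_het <= 0)) stopf("ancestral het count must be positive")
  x / (g * n_het)
}

#' Per-line and experiment-wide LOH rate table
#'
#' @param loh An `ma_loh` result.
#' @param exposures Data.table with `line` and `g`.
#' @param n_het Ancestral heterozygous-site count (scalar or named per
#'   line).
#' @return List with `per_line` (line, events, x sites, rate) and
#'   `experiment_rate` (unweighted mean over lines, zero-event lines
#'   included).
#' @export
loh_rate_table <- function(loh, exposures, n_het) {
  ev <- loh$tracts[, .(events = .N, x = sum(n_sites)), by = line]
  tab <- merge(exposures[, .(line, g)], ev, by = "line", all.x = TRUE)
  tab[is.na(events), `:=`(events = 0L, x = 0L)]
  nh <- if (!is.null(names(n_het))) n_het[tab$line] else n_het
  tab[, rate := loh_rate(x, g, nh)]
  list(per_line = tab[], experiment_rate = mean(tab$rate))
}

#' Classify LOH tracts as gene conversion or heterozygous deletion
#'
#' Standardized coverage is a line's mean depth over a region divided by
#' that line's mean depth across its callable sites. A tract is a putative
#' heterozygous deletion iff the focal line's standardized tract coverage
#' is at most `del_max` (0.70) of both flanking regions and of the
#' genome-wide average, while every other line keeps at least `other_min`
#' (0.80) standardized coverage over the same region relative to the same
#' benchmarks; otherwise it is a gene conversion. Tracts with depth
#' observations missing for more than half their sites are left
#' unclassified.
#'
#' @param loh An `ma_loh` result.
#' @param depth Depth track (`chrom`, `pos`, `line`, `depth`).
#' @param flank Flanking window in bases on each side (default 50 kb).
#' @param del_max Maximum focal standardized coverage for a deletion.
#' @param other_min Minimum standardized coverage of non-focal lines.
#' @return The `ma_loh` object with `mechanism` filled in.
#' @export
classify_mechanism <- function(loh, depth, flank = 5e4,
                               del_max = 0.70, other_min = 0.80) {
  stopifnot(inherits(loh, "ma_loh"))
  tr <- data.table::copy(loh$tracts)
  if (!nrow(tr)) { loh$tracts <- tr; return(loh) }
  line_mean <- depth[, .(mu = mean(depth)), by = line]
  mu_of <- setNames(line_mean$mu, line_mean$line)
  lines <- line_mean$line

  region_mean <- function(l, ch, lo, hi) {
    d <- depth[line == l & chrom == ch & pos >= lo & pos <= hi, depth]
    if (!length(d)) NA_real_ else mean(d)
  }

  for (i in seq_len(nrow(tr))) {
    ch <- tr$chrom[i]; l <- tr$line[i]
    lo <- tr$min_start[i]; hi <- tr$min_end[i]
    n_obs <- depth[line == l & chrom == ch & pos >= lo & pos <= hi, .N]
    if (n_obs < tr$n_sites[i] / 2) {
      tr$mechanism[i] <- "unclassified"; next
    }
    focal_tract <- region_mean(l, ch, lo, hi) / mu_of[[l]]
    fl <- region_mean(l, ch, max(1, lo - flank), lo - 1L) / mu_of[[l]]
    fr <- region_mean(l, ch, hi + 1L, hi + flank) / mu_of[[l]]
    flanks <- c(fl, fr)
    flanks <- flanks[!is.na(flanks)]
    focal_del <- !is.na(focal_tract) && focal_tract <= del_max &&
      (!length(flanks) || all(focal_tract <= del_max * flanks))
    others_ok <- TRUE
    for (l2 in setdiff(lines, l)) {
      ot <- region_mean(l2, ch, lo, hi) / mu_of[[l2]]
      ofl <- region_mean(l2, ch, max(1, lo - flank), lo - 1L) / mu_of[[l2]]
      ofr <- region_mean(l2, ch, hi + 1L, hi + flank) / mu_of[[l2]]
      oflanks <- c(ofl, ofr); oflanks <- oflanks[!is.na(oflanks)]
      if (is.na(ot) || ot < other_min ||
            (length(oflanks) && any(ot < other_min * oflanks))) {
        others_ok <- FALSE; break
      }
    }
    tr$mechanism[i] <- if (focal_del && others_ok) "deletion" else
      "conversion"
  }
  loh$tracts <- tr
  loh
}

#' GC bias of gene-conversion events
#'
#' Among converted sites whose two ancestral alleles are one strong (G/C)
#' and one weak (A/T) base, tests whether resolution favours the G/C
#' allele, with an exact two-sided binomial test against 0.5. Sites that
#' are not strong/weak informative (e.g. A/T heterozygotes, indels) are
#' excluded from the denominator.
#'
#' @param loh A classified `ma_loh` result; only tracts with
#'   `mechanism == "conversion"` contribute.
#' @return List with `n_eligible`, `n_gc`, `gc_fraction`, `p_value`.
#' @export
gc_conversion_bias <- function(loh) {
  stopifnot(inherits(loh, "ma_loh"))
  conv <- loh$tracts[mechanism == "conversion"]
  if (!nrow(conv)) stopf("no conversion tracts to test")
  st <- merge(loh$sites, conv[, .(line, chrom, min_start, min_end)],
              by = c("line", "chrom"), allow.cartesian = TRUE)
  st <- st[pos >= min_start & pos <= min_end]
  # strong/weak informative SNV sites: one G/C and one A/T ancestral allele
  el <- st[!is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L]
  el <- el[(ref %in% STRONG) != (alt %in% STRONG)]
  el <- unique(el, by = c("line", "chrom", "pos"))
  n <- nrow(el)
  if (n == 0) stopf("no strong/weak-informative converted sites")
  k <- sum(el$allele %in% STRONG)
  p <- binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  list(n_eligible = n, n_gc = k, gc_fraction = k / n, p_value = p)
}
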