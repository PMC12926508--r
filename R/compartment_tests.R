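#' Mutation counts, densities and pairwise tests across genomic compartments
#'
#' Compares observed mutation counts per compartment (nonsynonymous,
#' synonymous, UTR, intron, intergenic) against expectations proportional
#' to each compartment's callable base content, with Pearson chi-squared
#' tests (1 df, no continuity correction) for every compartment pair. A
#' compartment with zero callable bases is excluded with a warning.
#'
#' @param calls Annotated `ma_calls` (needs a `compartment` column; see
#'   [annotate_calls()]).
#' @param exposure Named numeric vector of callable base counts per
#'   compartment (e.g. from [compartment_counts()] scaled by the callable
#'   fraction).
#' @return List of class `ma_compartments`: `table` (compartment, count,
#'   exposure, density), `pairwise` (comp1, comp2, chisq, df, p).
#' @export
compartment_rates <- function(calls, exposure) {
  if (!"compartment" %in% names(calls))
    stopf("calls must carry a 'compartment' column; run annotate_calls()")
  zero <- names(exposure)[exposure <= 0]
  if (length(zero)) {
    warning("excluding compartment(s) with zero callable bases: ",
            paste(zero, collapse = ", "), call. = FALSE)
    exposure <- exposure[exposure > 0]
  }
  comps <- names(exposure)
  cnt <- setNames(vapply(comps, function(k)
    sum(calls$compartment == k), numeric(1)), comps)
  tab <- data.table::data.table(compartment = comps,
                                count = as.integer(cnt),
                                exposure = as.numeric(exposure),
                                density = cnt / exposure)
  pw <- list()
  if (length(comps) >= 2) {
    prs <- utils::combn(comps, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      x <- c(cnt[[a]], cnt[[b]])
      e <- c(exposure[[a]], exposure[[b]])
      if (sum(x) == 0) {
        pw[[j]] <- data.table::data.table(comp1 = a, comp2 = b,
                                          chisq = 0, df = 1L, p = 1)
      } else {
        ct <- suppressWarnings(chisq.test(x, p = e / sum(e),
                                          correct = FALSE))
        pw[[j]] <- data.table::data.table(comp1 = a, comp2 = b,
                                          chisq = unname(ct$statistic),
                                          df = 1L,
                                          p = unname(ct$p.value))
      }
    }
  }
  structure(list(table = tab,
                 pairwise = if (length(pw)) data.table::rbindlist(pw)
                 else NULL),
            class = "ma_compartments")
}

#' Chi-squared test of mutation uniformity across chromosomes
#'
#' Expected counts proportional to callable bases per chromosome;
#' `df = #chromosomes - 1`; Pearson statistic without continuity
#' correction.
#'
#' @param calls An `ma_calls` table.
#' @param chrom_exposure Named numeric vector of callable bases per
#'   chromosome (length >= 2).
#' @return List with `chisq`, `df`, `p`, `observed`, `expected`.
#' @export
chromosome_uniformity <- function(calls, chrom_exposure) {
  if (length(chrom_exposure) < 2)
    stopf("need at least two chromosomes")
  cnt <- setNames(vapply(names(chrom_exposure), function(k)
    sum(calls$chrom == k), numeric(1)), names(chrom_exposure))
  ct <- suppressWarnings(
    chisq.test(cnt, p = chrom_exposure / sum(chrom_exposure),
               correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), observed = cnt,
       expected = unname(ct$expected))
}

#' Neutral expectation of impact-category proportions by simulation
#'
#' Places `n_snm` substitutions uniformly over the genome in each of
#' `reps` replicates, draws each substitution type from the six-class
#' spectrum conditioned on the reference base (so the realized Ts/Tv
#' matches the observed spectrum in expectation; set
#' `condition_on_base = FALSE` to draw classes unconditionally), annotates
#' every simulated SNM with [annotate_impact()], and tallies the
#' HIGH/MODERATE/LOW/MODIFIER proportions. The mean and SD over replicates
#' form the neutral distribution against which observed impact fractions
#' are compared.
#'
#' @param n_snm Number of SNMs per replicate.
#' @param spectrum Named six-class weights (as in [sim_config()]).
#' @param ref The `ma_reference`.
#' @param reps Number of replicates (published analyses use 1,000).
#' @param seed Seed for the simulation.
#' @param condition_on_base Condition class draws on the reference base.
#' @return List of class `ma_neutral_impact`: `summary` (impact, mean, sd
#'   of proportions) and `reps`.
#' @export
neutral_impact_simulation <- function(n_snm, spectrum, ref, reps = 1000,
                                      seed = 1L, condition_on_base = TRUE) {
  assert_scalar_number(n_snm, "n_snm", 1)
  assert_scalar_number(reps, "reps", 1)
  spectrum <- spectrum[SIX_CLASSES]
  chrom_len <- setNames(Biostrings::width(ref$seq), names(ref$seq))
  impacts <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  with_seed(stage_seed(seed, "neutral"), {
    total <- n_snm * reps
    draw_sites <- function(n) {
      chrom <- sample(names(chrom_len), n, replace = TRUE,
                      prob = chrom_len / sum(chrom_len))
      pos <- as.integer(floor(runif(n, 1, chrom_len[chrom] + 1)))
      list(chrom = chrom, pos = pos, refb = ref_base(ref, chrom, pos))
    }
    st <- draw_sites(total)
    chrom <- st$chrom; pos <- st$pos; refb <- st$refb
    if (condition_on_base) {
      alt <- draw_alt_allele(refb, spectrum)
    } else {
      # draw the class first, then a site whose (pyrimidine-strand) base
      # matches the class source, by rejection
      cls <- sample(SIX_CLASSES, total, replace = TRUE, prob = spectrum)
      src <- substr(cls, 1, 1)
      bad <- which(ifelse(refb %in% PYRIMIDINES, refb,
                          comp_base(refb)) != src)
      while (length(bad)) {
        nd <- draw_sites(length(bad))
        chrom[bad] <- nd$chrom; pos[bad] <- nd$pos; refb[bad] <- nd$refb
        bad <- bad[ifelse(nd$refb %in% PYRIMIDINES, nd$refb,
                          comp_base(nd$refb)) != src[bad]]
      }
      tgt <- substr(cls, 3, 3)
      alt <- ifelse(refb %in% PYRIMIDINES, tgt, comp_base(tgt))
    }
    imp <- annotate_impact(ref, chrom, pos, ref_allele = refb,
                           alt_allele = alt)
    rep_id <- rep(seq_len(reps), each = n_snm)
    prop <- vapply(impacts, function(k)
      tapply(imp == k, rep_id, mean), numeric(reps))
    if (reps == 1) prop <- matrix(prop, nrow = 1,
                                  dimnames = list(NULL, impacts))
    summary <- data.table::data.table(
      impact = impacts,
      mean = colMeans(prop),
      sd = apply(prop, 2, sd))
    structure(list(summary = summary, reps = reps, n_snm = n_snm),
              class = "ma_neutral_impact")
  })
}
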