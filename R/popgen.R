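#' Per-site nucleotide diversity
#'
#' `pi = 2 p (1 - p)` for a biallelic site with minor-allele frequency `p`.
#'
#' @param p Minor-allele frequencies in `[0, 0.5]` (vectorized).
#' @return Per-site diversity values.
#' @export
site_pi <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 0.5))
    stopf("minor-allele frequencies must lie in [0, 0.5]")
  2 * p * (1 - p)
}

#' Synonymous and nonsynonymous site counts of a gene
#'
#' Nei-Gojobori-style fractional counting: each coding position
#' contributes a synonymous weight equal to the fraction of its three
#' possible substitutions that are silent, and the complementary
#' nonsynonymous weight, so the two sum to the CDS length. Genes with an
#' internal stop codon are skipped with a warning (returns `NA`s).
#'
#' @param gene_id Gene identifier present in the reference annotation.
#' @param ref The `ma_reference`.
#' @return List with `n_syn`, `n_nonsyn`.
#' @export
count_syn_nonsyn_sites <- function(gene_id, ref) {
  cds <- ref$cds[[gene_id]]
  if (is.null(cds)) stopf("gene '%s' not found in the annotation", gene_id)
  n <- nchar(cds$seq)
  codons <- substring(cds$seq, seq(1, n, 3), seq(3, n, 3))
  aa <- translate_codons(codons)
  if (any(aa[-length(aa)] == "*")) {
    warning(sprintf("gene %s has an internal stop codon; skipped", gene_id),
            call. = FALSE)
    return(list(n_syn = NA_real_, n_nonsyn = NA_real_))
  }
  sf <- as.vector(t(SYN_FRAC[codons, , drop = FALSE]))
  list(n_syn = sum(sf), n_nonsyn = n - sum(sf))
}

#' Gene-level diversity at synonymous and nonsynonymous sites
#'
#' Classifies each polymorphic coding site of the gene by the effect of
#' its minor allele (silent -> synonymous), sums [site_pi()] within each
#' class, and divides by the Nei-Gojobori site counts. The ratio is
#' reported as `NA` when `pi_s` is zero.
#'
#' @param gene_id Gene identifier.
#' @param freqs An `ma_popfreq` table (`chrom`, `pos`, `major`, `minor`,
#'   `maf`).
#' @param ref The `ma_reference`.
#' @return List with `pi_n`, `pi_s`, `ratio`, `n_poly_n`, `n_poly_s`.
#' @export
gene_pi_ratio <- function(gene_id, freqs, ref) {
  cds <- ref$cds[[gene_id]]
  if (is.null(cds)) stopf("gene '%s' not found in the annotation", gene_id)
  sites <- count_syn_nonsyn_sites(gene_id, ref)
  if (is.na(sites$n_syn)) return(list(pi_n = NA_real_, pi_s = NA_real_,
                                      ratio = NA_real_, n_poly_n = NA,
                                      n_poly_s = NA))
  f <- freqs[chrom == cds$chrom & pos %in% cds$gpos &
               nchar(minor) == 1L & nchar(major) == 1L]
  if (!nrow(f)) return(list(pi_n = 0, pi_s = 0, ratio = NA_real_,
                            n_poly_n = 0L, n_poly_s = 0L))
  imp <- annotate_impact(ref, f$chrom, f$pos, ref_allele = f$major,
                         alt_allele = f$minor)
  silent <- imp == "LOW"
  pi <- site_pi(f$maf)
  pi_s <- sum(pi[silent]) / sites$n_syn
  pi_n <- sum(pi[!silent]) / sites$n_nonsyn
  list(pi_n = pi_n, pi_s = pi_s,
       ratio = if (pi_s > 0) pi_n / pi_s else NA_real_,
       n_poly_n = sum(!silent), n_poly_s = sum(silent))
}

#' Overlap of MA mutations with standing variation
#'
#' An SNM is counted as present in the population iff a segregating site
#' exists at the same chromosome and position with minor-allele frequency
#' strictly above `maf_min` and (by default) a minor allele identical to
#' the SNM's alternate allele. Fractions are reported per compartment and
#' overall; the overall fraction is the call-count-weighted mean of the
#' compartment fractions.
#'
#' @param calls Annotated `ma_calls` (needs `compartment`).
#' @param freqs An `ma_popfreq` table.
#' @param maf_min Strict minor-allele-frequency threshold (default 0.02).
#' @param match_allele Require allele identity, not just position.
#' @return Data.table with one row per compartment plus `overall`:
#'   `n_calls`, `n_present`, `fraction`.
#' @export
snm_overlap <- function(calls, freqs, maf_min = 0.02, match_allele = TRUE) {
  snm <- calls[class == "SNM"]
  if (!"compartment" %in% names(snm))
    stopf("calls must carry a 'compartment' column; run annotate_calls()")
  if (!nrow(snm))
    return(data.table::data.table(compartment = "overall", n_calls = 0L,
                                  n_present = 0L, fraction = NA_real_))
  m <- merge(snm, freqs[, .(chrom, pos, minor, maf)],
             by = c("chrom", "pos"), all.x = TRUE)
  m[, present := !is.na(maf) & maf > maf_min &
      (!match_allele | minor == alt)]
  by_comp <- m[, .(n_calls = .N, n_present = sum(present)),
               by = compartment]
  by_comp[, fraction := n_present / n_calls]
  overall <- data.table::data.table(
    compartment = "overall", n_calls = nrow(m),
    n_present = sum(m$present), fraction = sum(m$present) / nrow(m))
  rbind(by_comp, overall)
}
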