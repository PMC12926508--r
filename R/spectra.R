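#' Six-type mutation spectrum with conditional rates
#'
#' Collapses SNM calls onto the pyrimidine strand into the six substitution
#' classes and normalizes each count by the genomic abundance of its source
#' base pair: the conditional rate of a C:G class is
#' `count / sum_l(2 * g_l * n_GC_l)` over lines, and analogously with A:T
#' content for the A:T classes, so classes are comparable per source site.
#' Also reports the transition/transversion ratio, the GC-gain (`u`) and
#' GC-loss (`v`) per-site rates, and the equilibrium GC content
#' `u / (u + v)`.
#'
#' @param calls An `ma_calls` table (only `class == "SNM"` rows are used).
#' @param exposures Data.table with `line`, `g`, `n_gc`, `n_at` callable
#'   base counts (see [emit_evidence()]).
#' @return List of class `ma_spectrum`: `table` (class, label, count,
#'   rate), `ts_tv`, `u`, `v`, `gc_equilibrium`, `n_snm`.
#' @export
six_type_spectrum <- function(calls, exposures) {
  snm <- calls[class == "SNM"]
  cls <- collapse_substitution(snm$ref, snm$alt)
  counts <- setNames(vapply(SIX_CLASSES, function(k) sum(cls == k),
                            numeric(1)), SIX_CLASSES)
  denom_gc <- sum(2 * exposures$g * exposures$n_gc)
  denom_at <- sum(2 * exposures$g * exposures$n_at)
  denom <- ifelse(startsWith(SIX_CLASSES, "C"), denom_gc, denom_at)
  rate <- counts / denom
  tab <- data.table::data.table(class = SIX_CLASSES,
                                label = six_class_label(SIX_CLASSES),
                                transition = is_transition(SIX_CLASSES),
                                count = as.integer(counts), rate = rate)
  structure(list(table = tab,
                 ts_tv = ts_tv_ratio(counts),
                 u = rate[["T>C"]] + rate[["T>G"]],
                 v = rate[["C>T"]] + rate[["C>A"]],
                 gc_equilibrium = if (sum(rate) > 0)
                   equilibrium_gc(rate[["T>C"]] + rate[["T>G"]],
                                  rate[["C>T"]] + rate[["C>A"]]) else NA_real_,
                 n_snm = nrow(snm)),
            class = "ma_spectrum")
}

#' Transition / transversion ratio from six-class counts
#'
#' @param counts Named counts for the six classes (`C>A` ... `T>G`).
#' @return `(C>T + T>C) / (C>A + C>G + T>A + T>G)`. Under a uniform
#'   spectrum the expectation is 0.5 (two transition vs four transversion
#'   classes).
#' @export
ts_tv_ratio <- function(counts) {
  counts <- counts[SIX_CLASSES]
  ts <- sum(counts[c("C>T", "T>C")])
  tv <- sum(counts[c("C>A", "C>G", "T>A", "T>G")])
  if (tv == 0) return(Inf)
  ts / tv
}

#' 96-context trinucleotide mutation spectrum
#'
#' Counts SNMs in the standard pyrimidine-centred 96-category convention:
#' six substitution classes by the 16 combinations of 5' and 3' flanking
#' bases; purine-reference calls are reverse-complemented onto the
#' pyrimidine strand. Calls at chromosome edges (no flanking base) are
#' dropped and tallied.
#'
#' @param calls An `ma_calls` table.
#' @param ref The `ma_reference` supplying flanking bases.
#' @return List of class `ma_trispectrum`: `counts` (named 96-vector,
#'   names like `"C>T:TCA"`), `n_edge_dropped`, `n_snm`.
#' @export
trinucleotide_spectrum <- function(calls, ref) {
  snm <- calls[class == "SNM"]
  bins <- trinucleotide_bins()
  counts <- setNames(integer(96), bins)
  n_edge <- 0L
  if (nrow(snm)) {
    ctx <- trinucleotide_context(ref, snm$chrom, snm$pos, snm$alt)
    n_edge <- sum(ctx$edge)
    t <- table(ctx$context[!ctx$edge])
    counts[names(t)] <- as.integer(t)
  }
  structure(list(counts = counts, n_edge_dropped = n_edge,
                 n_snm = nrow(snm)), class = "ma_trispectrum")
}

trinucleotide_bins <- function() {
  out <- character(0)
  for (cls in SIX_CLASSES) {
    ctr <- substr(cls, 1, 1)
    for (l in BASES) for (r in BASES)
      out <- c(out, paste0(cls, ":", l, ctr, r))
  }
  out
}
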