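#' Simulate the heterozygous ancestor of an MA experiment
#'
#' Draws the set of ancestral heterozygous sites. Each genomic site is
#' heterozygous independently with probability `config$het_density`; a
#' fraction `config$het_indel_fraction` of heterozygous sites carry a short
#' (1-3 bp) indel polymorphism instead of a SNV. Alternate SNV alleles are
#' drawn uniformly from the three non-reference bases. All remaining sites
#' are homozygous for the reference allele.
#'
#' @param config An [sim_config()] object.
#' @param ref An `ma_reference` from [generate_reference()].
#' @return A data.table of class `ma_ancestor` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `is_indel`, sorted by position.
#' @export
simulate_ancestor <- function(config, ref) {
  stopifnot(inherits(config, "ma_sim_config"), inherits(ref, "ma_reference"))
  with_seed(stage_seed(config$seed, "ancestor"), {
    out <- list()
    for (ch in names(ref$seq)) {
      L <- Biostrings::width(ref$seq[ch])
      k <- rbinom(1, L, config$het_density)
      if (k == 0) next
      pos <- sort(sample.int(L, k))
      refb <- ref_base(ref, rep(ch, k), pos)
      n_indel <- rbinom(1, k, config$het_indel_fraction)
      is_indel <- rep(FALSE, k)
      if (n_indel > 0)
        is_indel[sample.int(k, n_indel)] <- TRUE
      # avoid deletions running off the chromosome end
      is_indel[pos > L - 4L] <- FALSE

      alt <- character(k)
      snv <- which(!is_indel)
      ri <- match(refb[snv], BASES)
      alt[snv] <- BASES[((ri - 1L + sample(1:3, length(snv),
                                           replace = TRUE)) %% 4L) + 1L]
      refout <- refb
      for (i in which(is_indel)) {
        len <- sample(1:3, 1)
        if (runif(1) < 0.5) {   # insertion
          ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
          alt[i] <- paste0(refb[i], ins)
        } else {                # deletion, VCF-anchored
          refout[i] <- ref_base(ref, ch, pos[i], width = len + 1L)
          alt[i] <- refb[i]
        }
      }
      out[[ch]] <- data.table::data.table(
        chrom = ch, pos = pos, ref = refout, alt = alt, is_indel = is_indel)
    }
    anc <- if (length(out)) data.table::rbindlist(out) else
      data.table::data.table(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             is_indel = logical())
    # a deletion allele must not swallow a neighbouring het site
    anc <- anc[!duplicated(anc, by = c("chrom", "pos"))]
    data.table::setattr(anc, "class", c("ma_ancestor", class(anc)))
    data.table::setattr(anc, "genome_size", genome_size(ref))
    anc[]
  })
}
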