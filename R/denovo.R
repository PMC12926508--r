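#' Infer ancestral genotypes by cross-line consensus
#'
#' In a clonal MA design every line descends from one ancestor, so the
#' genotype shared by nearly all lines at a polymorphic site is the
#' ancestral state. A site receives an ancestral genotype iff at least
#' `min_consensus` lines agree (default: all but one line, generalizing
#' the seven-of-eight rule); sites with any missing genotype are left
#' uncallable (conservative), as are sites without sufficient agreement.
#'
#' @param records A filtered `ma_records` object.
#' @param min_consensus Minimum number of agreeing lines; default
#'   `length(records$lines) - 1`.
#' @return Data.table of class `ma_ancestral`: `chrom`, `pos`, `anc_gt`
#'   (0 hom-ref / 1 het / 2 hom-alt, `NA` when uncallable), `support`
#'   (agreeing line count).
#' @export
infer_ancestral <- function(records, min_consensus = NULL) {
  stopifnot(inherits(records, "ma_records"))
  nl <- length(records$lines)
  if (nl < 3) stopf("ancestral consensus needs at least 3 lines, got %d", nl)
  if (is.null(min_consensus)) min_consensus <- nl - 1L
  assert_scalar_number(min_consensus, "min_consensus", 2, nl)

  anc <- records$geno[, {
    if (anyNA(gt)) list(anc_gt = NA_integer_, support = 0L)
    else {
      tab <- tabulate(gt + 1L, 3L)
      m <- which.max(tab)
      if (tab[m] >= min_consensus)
        list(anc_gt = m - 1L, support = as.integer(tab[m]))
      else list(anc_gt = NA_integer_, support = as.integer(tab[m]))
    }
  }, by = .(chrom, pos)]
  data.table::setattr(anc, "class", c("ma_ancestral", class(anc)))
  anc[]
}

#' Call de novo mutations unique to one MA line
#'
#' A de novo mutation is accepted iff: the site has an ancestral homozygous
#' genotype; exactly one line deviates from it; the deviating line is
#' heterozygous (Hom > Het only - het-to-hom changes feed the LOH module
#' and hom-to-hom allele switches are rejected as artifacts); no other
#' line carries a single read of the novel allele; the site is callable in
#' every line; and the site is more than `indel_window` bases from any
#' surviving indel record. Indel calls use the same logic, with event
#' length `abs(nchar(ref) - nchar(alt))` capped at `max_indel_len`.
#'
#' @param ancestral An `ma_ancestral` table from [infer_ancestral()].
#' @param records The filtered `ma_records` the consensus was built from.
#' @param mask Optional `ma_callable`; when supplied, sites non-callable in
#'   any line are skipped.
#' @param indel_window Exclusion distance around surviving indels (bases).
#' @param max_indel_len Maximum indel length in bases (larger events are
#'   dropped and tallied in the `dropped` attribute).
#' @return Data.table of class `ma_calls`: `line`, `chrom`, `pos`, `ref`,
#'   `alt`, `class` (`SNM`, `insertion`, `deletion`), `mnm_group` (`NA`
#'   until [group_mnms()]).
#' @export
call_mutations <- function(ancestral, records, mask = NULL,
                           indel_window = 20L, max_indel_len = 5L) {
  stopifnot(inherits(ancestral, "ma_ancestral"),
            inherits(records, "ma_records"))
  g <- records$geno
  s <- records$sites
  anc <- ancestral[!is.na(anc_gt)]

  gg <- merge(g, anc[, .(chrom, pos, anc_gt)], by = c("chrom", "pos"))
  cand <- gg[, {
    dev <- which(gt != anc_gt[1])
    if (anc_gt[1] %in% c(0L, 2L) && length(dev) == 1L &&
          gt[dev] == 1L && !anyNA(gt)) {
      # novel allele: the one the ancestor lacks
      novel_is_alt <- anc_gt[1] == 0L
      other_reads <- if (novel_is_alt) sum(ad_alt[-dev]) else
        sum(ad_ref[-dev])
      list(line = line[dev], novel_is_alt = novel_is_alt,
           other_reads = other_reads)
    } else NULL
  }, by = .(chrom, pos)]

  if (nrow(cand)) cand <- cand[other_reads == 0L]

  if (!is.null(mask) && nrow(cand)) {
    stopifnot(inherits(mask, "ma_callable"))
    bad <- mask$mask[callable == FALSE, .(chrom, pos)]
    if (nrow(bad))
      cand <- cand[!paste(chrom, pos) %in% paste(bad$chrom, bad$pos)]
  }

  calls <- merge(cand, s[, .(chrom, pos, ref, alt)], by = c("chrom", "pos"))
  # novel allele orientation: ancestral hom-alt with a het deviator means
  # the deviator regained the reference base
  calls[, `:=`(ref_len = nchar(ref), alt_len = nchar(alt))]
  calls[, class := ifelse(ref_len == 1L & alt_len == 1L, "SNM",
                          ifelse(alt_len > ref_len, "insertion",
                                 "deletion"))]
  dropped_long <- calls[class != "SNM" &
                          abs(ref_len - alt_len) > max_indel_len]
  calls <- calls[class == "SNM" | abs(ref_len - alt_len) <= max_indel_len]

  # exclusion around surviving indels
  is_indel_site <- nchar(s$ref) != 1L | vapply(
    strsplit(s$alt, ","), function(a) any(nchar(a) != 1L), logical(1))
  if (any(is_indel_site) && nrow(calls)) {
    keep <- rep(TRUE, nrow(calls))
    for (ch in unique(calls$chrom)) {
      si <- which(s$chrom == ch)
      ipos <- s$pos[si][is_indel_site[si]]
      ci <- which(calls$chrom == ch)
      if (!length(ipos) || !length(ci)) next
      d <- nearest_other_distance(calls$pos[ci], ipos,
                                  self_is_indel = calls$class[ci] != "SNM")
      keep[ci] <- d > indel_window
    }
    calls <- calls[keep]
  }

  calls[, c("ref_len", "alt_len", "novel_is_alt", "other_reads") := NULL]
  calls[, mnm_group := NA_character_]
  data.table::setcolorder(calls, c("line", "chrom", "pos", "ref", "alt",
                                   "class", "mnm_group"))
  data.table::setorder(calls, line, chrom, pos)
  data.table::setattr(calls, "class", c("ma_calls", class(calls)))
  data.table::setattr(calls, "dropped_long_indels", nrow(dropped_long))
  calls[]
}

#' Group multinucleotide mutations (MNMs)
#'
#' Chains same-line SNMs whose consecutive gaps are at most `window` bases
#' (default 50) into MNM groups; groups have at least two members. MNM
#' members keep their individual-SNM status in every count downstream.
#'
#' @param calls An `ma_calls` table.
#' @param window Maximum gap in bases between consecutive members.
#' @return The calls with `mnm_group` filled in (`"<line>:<chrom>:<k>"`).
#' @export
group_mnms <- function(calls, window = 50L) {
  stopifnot(inherits(calls, "ma_calls"))
  calls <- data.table::copy(calls)
  calls[, mnm_group := NA_character_]
  snm <- calls$class == "SNM"
  calls[snm, mnm_group := {
    gap_new <- c(TRUE, diff(pos) > window)
    grp <- cumsum(gap_new)
    sizes <- tabulate(grp)
    ifelse(sizes[grp] >= 2L, paste(line, chrom, grp, sep = ":"),
           NA_character_)
  }, by = .(line, chrom)]
  calls[]
}

#' MNM summary: group count and member count
#'
#' @param calls Calls processed by [group_mnms()].
#' @return List with `n_groups`, `n_members`, and the fraction of all SNMs
#'   that are MNM members.
#' @export
mnm_summary <- function(calls) {
  m <- calls[!is.na(mnm_group)]
  list(n_groups = length(unique(m$mnm_group)),
       n_members = nrow(m),
       member_fraction = if (sum(calls$class == "SNM"))
         nrow(m) / sum(calls$class == "SNM") else 0)
}

#' Annotate calls with trinucleotide context, compartment and impact
#'
#' Adds the pyrimidine-centred trinucleotide context (SNMs only), the
#' compartment label at the call position, and a SnpEff-style impact
#' class: coding SNMs are translated through the affected codon
#' (strand-aware) - stop-gained, stop-lost or start-lost are `HIGH`,
#' missense `MODERATE`, silent `LOW`; everything non-coding (and every
#' indel) is `MODIFIER` except coding indels, which are `HIGH` when their
#' length is not a multiple of three (frameshift) and `MODERATE` otherwise.
#'
#' @param calls An `ma_calls` table.
#' @param ref The `ma_reference`.
#' @return The calls with `context`, `compartment`, `impact` columns.
#' @export
annotate_calls <- function(calls, ref) {
  stopifnot(inherits(calls, "ma_calls"), inherits(ref, "ma_reference"))
  reference <- ref   # the calls table has a 'ref' allele column
  calls <- data.table::copy(calls)
  if (!nrow(calls)) {
    calls[, `:=`(context = character(), compartment = character(),
                 impact = character())]
    return(calls[])
  }
  for (ch in unique(calls$chrom))
    if (any(calls[chrom == ch, pos] > Biostrings::width(reference$seq[ch])))
      stopf("call position beyond the end of %s", ch)
  calls[, context := NA_character_]
  snm <- which(calls$class == "SNM")
  if (length(snm))
    calls$context[snm] <- trinucleotide_context(
      reference, calls$chrom[snm], calls$pos[snm], calls$alt[snm])$context
  calls$compartment <- compartment_at(reference, calls$chrom, calls$pos)
  calls$impact <- annotate_impact(reference, calls$chrom, calls$pos,
                                  ref_allele = calls$ref,
                                  alt_allele = calls$alt,
                                  class = calls$class)
  calls[]
}

#' SnpEff-style impact of substitutions at genomic positions
#'
#' Vectorized impact annotation used by [annotate_calls()] and the neutral
#' simulation. Positions outside any CDS are `MODIFIER`.
#'
#' @param ref The `ma_reference`.
#' @param chrom,pos Call coordinates.
#' @param ref_allele,alt_allele Alleles as written in the record.
#' @param class Event class per call (`SNM` or indel classes).
#' @return Character vector of `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#' @export
annotate_impact <- function(ref, chrom, pos, ref_allele, alt_allele,
                            class = rep("SNM", length(pos))) {
  n <- length(pos)
  impact <- rep("MODIFIER", n)
  map <- cds_position_lookup(ref, chrom, pos)
  in_cds <- !is.na(map$gene)
  if (!any(in_cds)) return(impact)

  idx <- which(in_cds)
  is_snm <- class[idx] == "SNM"

  # coding indels: frameshift when length is not a multiple of 3
  ind <- idx[!is_snm]
  if (length(ind)) {
    len <- abs(nchar(ref_allele[ind]) - nchar(alt_allele[ind]))
    impact[ind] <- ifelse(len %% 3L == 0L, "MODERATE", "HIGH")
  }

  sidx <- idx[is_snm]
  if (length(sidx)) {
    gene <- map$gene[sidx]
    cpos <- map$cds_pos[sidx]
    codon_i <- (cpos - 1L) %/% 3L + 1L
    offset <- (cpos - 1L) %% 3L + 1L
    ref_codon <- character(length(sidx))
    for (gid in unique(gene)) {
      gi <- which(gene == gid)
      st <- (codon_i[gi] - 1L) * 3L + 1L
      ref_codon[gi] <- substring(ref$cds[[gid]]$seq, st, st + 2L)
    }
    strand <- vapply(ref$cds[map$gene[sidx]], `[[`, character(1), "strand")
    alt_b <- alt_allele[sidx]
    alt_cds <- ifelse(strand == "-", comp_base(alt_b), alt_b)
    alt_codon <- ref_codon
    substr(alt_codon, offset, offset) <- alt_cds
    ref_aa <- translate_codons(ref_codon)
    alt_aa <- translate_codons(alt_codon)
    imp <- ifelse(ref_aa == alt_aa, "LOW",
                  ifelse(alt_aa == "*" | ref_aa == "*" |
                           (codon_i == 1L & ref_aa == "M"),
                         "HIGH", "MODERATE"))
    impact[sidx] <- imp
  }
  impact
}

# Map genomic positions to (gene, CDS position); NA outside CDS.
cds_position_lookup <- function(ref, chrom, pos) {
  n <- length(pos)
  gene <- rep(NA_character_, n)
  cds_pos <- rep(NA_integer_, n)
  if (!length(ref$cds)) return(list(gene = gene, cds_pos = cds_pos))
  for (gid in names(ref$cds)) {
    cds <- ref$cds[[gid]]
    hit <- which(chrom == cds$chrom & pos >= min(cds$gpos) &
                   pos <= max(cds$gpos))
    if (!length(hit)) next
    m <- match(pos[hit], cds$gpos)
    ok <- !is.na(m)
    gene[hit[ok]] <- gid
    cds_pos[hit[ok]] <- m[ok]
  }
  list(gene = gene, cds_pos = cds_pos)
}

# Pyrimidine-centred trinucleotide context and collapsed substitution.
trinucleotide_context <- function(ref, chrom, pos, alt) {
  refb <- ref_base(ref, chrom, pos)
  left <- ref_base(ref, chrom, pmax(pos - 1L, 1L))
  right_ok <- pos + 1L <= setNames(
    Biostrings::width(ref$seq), names(ref$seq))[chrom]
  right <- ref_base(ref, chrom, ifelse(right_ok, pos + 1L, pos))
  edge <- pos == 1L | !right_ok
  tri <- paste0(left, refb, right)
  flip <- !(refb %in% PYRIMIDINES)
  tri[flip] <- rev_comp(tri[flip])
  sub <- collapse_substitution(refb, alt)
  ctx <- paste0(sub, ":", tri)
  ctx[edge] <- NA_character_
  list(context = ctx, substitution = sub, edge = edge)
}
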