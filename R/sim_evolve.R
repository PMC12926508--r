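#' Evolve MA lines from a common ancestor
#'
#' Plants de novo mutations and LOH events independently in each line, the
#' way a single-progeny-descent MA experiment accumulates them. Per line,
#' SNM and indel counts are Poisson with mean `rate * 2 * genome_size *
#' generations` (the factor 2 for the diploid genome); LOH events convert
#' contiguous runs of ancestral heterozygous sites to one resolved allele
#' (gene conversion) or mark the tract hemizygous (deletion), with tract
#' lengths drawn from a clipped log-normal. Parallel mutations across lines
#' are never planted. Every planted event is recorded in the returned truth
#' table, the recovery oracle for the calling pipeline.
#'
#' @param ancestor An `ma_ancestor` from [simulate_ancestor()].
#' @param config An [sim_config()] object.
#' @param ref The `ma_reference` the ancestor was simulated on.
#' @return A list of class `ma_lines` with elements `snms`, `indels`,
#'   `loh_tracts`, `loh_sites` (data.tables keyed by `line`), the
#'   `ancestor`, and `truth`, an `ma_truth` list with `planted_snms`,
#'   `planted_indels`, `planted_loh` and `planted_loh_sites`.
#' @export
evolve_ma_lines <- function(ancestor, config, ref) {
  stopifnot(inherits(ancestor, "ma_ancestor"), inherits(config, "ma_sim_config"))
  with_seed(stage_seed(config$seed, "evolve"), {
    L <- genome_size(ref)
    chrom_len <- setNames(Biostrings::width(ref$seq), names(ref$seq))
    lines <- line_names(config)
    n_het <- nrow(ancestor)
    # positions already carrying a polymorphism or a planted event in ANY
    # line: parallel mutations are never planted
    global_used <- paste(ancestor$chrom, ancestor$pos)

    snm_l <- list(); indel_l <- list(); tract_l <- list(); site_l <- list()

    # intervals occupied by any line's tract: overlapping tracts in two
    # lines would drop their shared sites from the consensus het scaffold
    # (both lines homozygous), erasing the evidence of both events, so --
    # like parallel point mutations -- they are never planted
    occupied <- data.table::data.table(chrom = character(),
                                       start = integer(), end = integer())

    for (li in seq_along(lines)) {
      g <- config$generations_per_line[li]

      # --- LOH tracts first, so point mutations can avoid deleted tracts
      loh <- plant_loh(ancestor, config, g, lines[li], chrom_len, occupied)
      if (nrow(loh$tracts))
        occupied <- rbind(occupied,
                          loh$tracts[, .(chrom, start, end)])
      tract_l[[li]] <- loh$tracts
      site_l[[li]] <- loh$sites

      in_tract <- function(chrom, pos) {
        if (!nrow(loh$tracts)) return(rep(FALSE, length(pos)))
        hit <- rep(FALSE, length(pos))
        for (ti in seq_len(nrow(loh$tracts))) {
          tr <- loh$tracts[ti]
          hit <- hit | (chrom == tr$chrom & pos >= tr$start & pos <= tr$end &
                          tr$mechanism == "deletion")
        }
        hit
      }

      # --- SNMs
      n_snm <- rpois(1, config$snm_rate * 2 * L * g)
      spos <- draw_positions(n_snm, chrom_len, global_used, in_tract)
      if (nrow(spos)) {
        refb <- ref_base(ref, spos$chrom, spos$pos)
        alt <- draw_alt_allele(refb, config$spectrum)
        snm_l[[li]] <- data.table::data.table(
          line = lines[li], chrom = spos$chrom, pos = spos$pos,
          ref = refb, alt = alt)
        global_used <- c(global_used, paste(spos$chrom, spos$pos))
      }

      # --- indels (length <= 5, VCF-anchored)
      n_ind <- rpois(1, config$indel_rate * 2 * L * g)
      ipos <- draw_positions(n_ind, chrom_len - 6L, global_used, in_tract)
      if (nrow(ipos)) {
        k <- nrow(ipos)
        len <- sample(1:5, k, replace = TRUE)
        is_ins <- runif(k) < 0.5
        anchor <- ref_base(ref, ipos$chrom, ipos$pos)
        refa <- anchor; alta <- anchor
        for (i in seq_len(k)) {
          if (is_ins[i]) {
            alta[i] <- paste0(anchor[i], paste(
              sample(BASES, len[i], replace = TRUE), collapse = ""))
          } else {
            refa[i] <- ref_base(ref, ipos$chrom[i], ipos$pos[i],
                                width = len[i] + 1L)
          }
        }
        indel_l[[li]] <- data.table::data.table(
          line = lines[li], chrom = ipos$chrom, pos = ipos$pos,
          ref = refa, alt = alta,
          class = ifelse(is_ins, "insertion", "deletion"))
        global_used <- c(global_used, paste(ipos$chrom, ipos$pos))
      }
    }

    snms <- rbind_or_empty(snm_l, c("line", "chrom", "pos", "ref", "alt"))
    indels <- rbind_or_empty(indel_l,
                             c("line", "chrom", "pos", "ref", "alt", "class"))
    tracts <- data.table::rbindlist(tract_l)
    sites <- data.table::rbindlist(site_l)

    truth <- structure(list(planted_snms = data.table::copy(snms),
                            planted_indels = data.table::copy(indels),
                            planted_loh = data.table::copy(tracts),
                            planted_loh_sites = data.table::copy(sites)),
                       class = "ma_truth")
    structure(list(snms = snms, indels = indels, loh_tracts = tracts,
                   loh_sites = sites, ancestor = ancestor,
                   lines = lines, truth = truth),
              class = "ma_lines")
  })
}

rbind_or_empty <- function(lst, cols) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst)) return(data.table::rbindlist(lst))
  out <- data.table::as.data.table(
    setNames(rep(list(character()), length(cols)), cols))
  out$pos <- integer()
  out
}

# Uniform genomic positions avoiding a set of used "chrom pos" keys and a
# per-line deleted-tract predicate.
draw_positions <- function(n, chrom_len, used_keys, in_tract) {
  if (n == 0) return(data.table::data.table(chrom = character(),
                                            pos = integer()))
  got <- NULL
  for (attempt in 1:20) {
    need <- n - (if (is.null(got)) 0L else nrow(got))
    if (need <= 0) break
    m <- max(need * 2L, 10L)
    chrom <- sample(names(chrom_len), m, replace = TRUE,
                    prob = chrom_len / sum(chrom_len))
    pos <- floor(runif(m, 1, chrom_len[chrom] + 1))
    cand <- data.table::data.table(chrom = chrom, pos = as.integer(pos))
    key <- paste(cand$chrom, cand$pos)
    keep <- !(key %in% used_keys) & !duplicated(key) &
      !in_tract(cand$chrom, cand$pos)
    cand <- cand[keep]
    got <- rbind(got, cand)
    if (nrow(got)) {
      used_keys <- c(used_keys, paste(got$chrom, got$pos))
      got <- got[!duplicated(paste(chrom, pos))]
    }
  }
  data.table::setorder(got[seq_len(min(n, nrow(got)))], chrom, pos)[]
}

# Draw alternate alleles for SNMs given reference bases, from the six-class
# conditional spectrum (pyrimidine-centred weights).
draw_alt_allele <- function(refb, spectrum) {
  alt <- character(length(refb))
  for (src in PYRIMIDINES) {
    cls <- SIX_CLASSES[startsWith(SIX_CLASSES, src)]
    w <- spectrum[cls]
    targets <- substr(cls, 3, 3)
    # sites whose pyrimidine-strand base is `src`
    direct <- which(refb == src)
    flipped <- which(refb == comp_base(src))
    if (length(direct)) {
      pick <- sample(targets, length(direct), replace = TRUE, prob = w)
      alt[direct] <- pick
    }
    if (length(flipped)) {
      pick <- sample(targets, length(flipped), replace = TRUE, prob = w)
      alt[flipped] <- comp_base(pick)
    }
  }
  alt
}

# Plant LOH events for one line over the ancestral het sites, avoiding
# intervals already occupied by any line's tract.
plant_loh <- function(ancestor, config, g, line, chrom_len, occupied) {
  empty_tracts <- data.table::data.table(
    line = character(), chrom = character(), start = integer(),
    end = integer(), mechanism = character(), n_sites = integer(),
    first_site = integer(), last_site = integer())
  empty_sites <- data.table::data.table(
    line = character(), chrom = character(), pos = integer(),
    kept = character(), mechanism = character())
  n_het <- nrow(ancestor)
  target <- if (n_het == 0) 0 else
    rpois(1, config$loh_rate_per_het_site * n_het * g)
  if (target == 0)
    return(list(tracts = empty_tracts, sites = empty_sites))

  dist <- config$tract_length_dist
  converted <- 0L
  taken <- logical(n_het)      # het sites already inside a tract
  tracts <- list(); sites <- list(); attempts <- 0L
  while (converted < target && attempts < 500L) {
    attempts <- attempts + 1L
    len <- round(rlnorm(1, dist$meanlog, dist$sdlog))
    len <- min(max(len, dist$min), dist$max)
    anchor <- sample.int(n_het, 1)
    if (taken[anchor]) next
    ch <- ancestor$chrom[anchor]
    tr_start <- max(1L, ancestor$pos[anchor] - as.integer(len %/% 2))
    tr_end <- min(chrom_len[[ch]], tr_start + as.integer(len) - 1L)
    idx <- which(ancestor$chrom == ch & ancestor$pos >= tr_start &
                   ancestor$pos <= tr_end)
    if (!length(idx) || any(taken[idx])) next
    if (nrow(occupied) &&
          occupied[chrom == ch & start <= tr_end & end >= tr_start,
                   .N] > 0) next
    taken[idx] <- TRUE
    mech <- if (runif(1) < config$deletion_fraction) "deletion" else
      "conversion"
    kept <- sample(c("ref", "alt"), length(idx), replace = TRUE)
    tracts[[length(tracts) + 1L]] <- data.table::data.table(
      line = line, chrom = ch, start = tr_start, end = tr_end,
      mechanism = mech,
      n_sites = length(idx), first_site = ancestor$pos[idx[1]],
      last_site = ancestor$pos[idx[length(idx)]])
    sites[[length(sites) + 1L]] <- data.table::data.table(
      line = line, chrom = ch, pos = ancestor$pos[idx], kept = kept,
      mechanism = mech)
    converted <- converted + length(idx)
  }
  list(tracts = if (length(tracts)) data.table::rbindlist(tracts)
       else empty_tracts,
       sites = if (length(sites)) data.table::rbindlist(sites)
       else empty_sites)
}
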