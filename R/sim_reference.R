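#' Generate a synthetic reference genome with gene annotation
#'
#' Builds a random diploid-reference genome at a target GC content, places
#' non-overlapping protein-coding gene models (5' UTR, multi-exon CDS with a
#' start and stop codon, 3' UTR, on either strand), and derives the per-base
#' compartment map (nonsynonymous / synonymous / UTR / intron / intergenic).
#' Coding sequence is drawn codon-wise from the 61 sense codons weighted to
#' match the target base composition.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `ma_reference`: a list with elements
#'   `seq` (a [Biostrings::DNAStringSet]), `genes`, `features`
#'   (data.tables of gene spans and GFF3-style feature segments), `cds`
#'   (per-gene spliced CDS sequence plus the genome position of every CDS
#'   base in transcription order), and `compartments` (per-chromosome
#'   label codes; see [compartment_counts()]).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "ma_sim_config"))
  with_seed(stage_seed(config$seed, "reference"), {
    L <- config$chromosome_length
    gc <- config$gc_content
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))

    genes_list <- list()
    feats_list <- list()
    cds_list <- list()
    seqs <- character(config$n_chromosomes)
    gene_counter <- 0L

    for (ci in seq_along(chroms)) {
      chrom_seq <- sample(BASES, L, replace = TRUE, prob = base_prob)
      n_genes <- round(config$gene_density * L / 1e6)
      if (n_genes > 0) {
        layouts <- replicate(n_genes, random_gene_layout(gc), simplify = FALSE)
        fp <- vapply(layouts, function(g) length(g$seq), integer(1))
        if (sum(fp) + n_genes + 1 > L)
          stopf(paste("chromosome_length %d is too short to place %d gene(s)",
                      "with total footprint %d bp"), L, n_genes, sum(fp))
        # spread genes uniformly: slack split by an exponential partition
        slack <- L - sum(fp)
        w <- rexp(n_genes + 1)
        gaps <- floor(slack * w / sum(w))
        starts <- cumsum(c(1 + gaps[1], head(fp, -1) + gaps[-c(1, n_genes + 1)]))
        for (gi in seq_len(n_genes)) {
          gene_counter <- gene_counter + 1L
          gid <- sprintf("gene%04d", gene_counter)
          placed <- place_gene(layouts[[gi]], gid, chroms[ci], starts[gi])
          chrom_seq[starts[gi]:(starts[gi] + fp[gi] - 1L)] <- placed$bases
          genes_list[[gid]] <- placed$gene
          feats_list[[gid]] <- placed$features
          cds_list[[gid]] <- placed$cds
        }
      }
      seqs[ci] <- paste(chrom_seq, collapse = "")
    }

    seq <- Biostrings::DNAStringSet(seqs)
    names(seq) <- chroms
    genes <- if (length(genes_list)) data.table::rbindlist(genes_list)
             else empty_genes()
    feats <- if (length(feats_list)) data.table::rbindlist(feats_list)
             else empty_features()
    new_reference(seq, genes, feats, cds_list)
  })
}

empty_genes <- function() {
  data.table::data.table(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer())
}

empty_features <- function() {
  data.table::data.table(gene_id = character(), chrom = character(),
                         strand = character(), type = character(),
                         start = integer(), end = integer(),
                         phase = integer())
}

# A gene layout in transcription order: base vector, feature label per base,
# and CDS position per base (0 outside CDS).
random_gene_layout <- function(gc) {
  n_codons <- sample(100:350, 1)              # includes start and stop
  codon_w <- codon_weights(gc)
  codons <- c("ATG",
              sample(SENSE_CODONS, n_codons - 2L, replace = TRUE,
                     prob = codon_w[SENSE_CODONS]),
              sample(STOP_CODONS, 1))
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
  cds_len <- length(cds)

  n_exons <- sample(1:4, 1)
  # split at codon boundaries, every exon at least one codon
  if (n_exons > 1) {
    cuts <- sort(sample(seq_len(n_codons - 1L), n_exons - 1L)) * 3L
    sizes <- diff(c(0L, cuts, cds_len))
  } else sizes <- cds_len

  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rand_bases <- function(n) sample(BASES, n, replace = TRUE, prob = base_prob)

  utr5 <- sample(50:200, 1); utr3 <- sample(50:200, 1)
  seqv <- rand_bases(utr5)
  lab <- rep("five_prime_UTR", utr5)
  cdspos <- integer(utr5)
  off <- 0L
  for (ei in seq_len(n_exons)) {
    seg <- cds[(off + 1L):(off + sizes[ei])]
    seqv <- c(seqv, seg)
    lab <- c(lab, rep("CDS", sizes[ei]))
    cdspos <- c(cdspos, (off + 1L):(off + sizes[ei]))
    off <- off + sizes[ei]
    if (ei < n_exons) {
      il <- sample(60:300, 1)
      seqv <- c(seqv, rand_bases(il))
      lab <- c(lab, rep("intron", il))
      cdspos <- c(cdspos, integer(il))
    }
  }
  seqv <- c(seqv, rand_bases(utr3))
  lab <- c(lab, rep("three_prime_UTR", utr3))
  cdspos <- c(cdspos, integer(utr3))

  strand <- sample(c("+", "-"), 1)
  list(seq = seqv, lab = lab, cdspos = cdspos, strand = strand,
       cds_seq = paste(cds, collapse = ""))
}

codon_weights <- function(gc) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(CODONS, function(cod) {
    prod(pb[strsplit(cod, "")[[1]]])
  }, numeric(1))
  setNames(w, CODONS)
}

# Realize a layout on the genome at `start`, honouring strand.
place_gene <- function(layout, gid, chrom, start) {
  n <- length(layout$seq)
  if (layout$strand == "+") {
    bases <- layout$seq
    lab <- layout$lab
    cdspos <- layout$cdspos
  } else {
    bases <- rev(comp_base(layout$seq))
    lab <- rev(layout$lab)
    cdspos <- rev(layout$cdspos)
  }
  pos <- start:(start + n - 1L)

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts_rel <- ends - r$lengths + 1L
  feats <- data.table::data.table(
    gene_id = gid, chrom = chrom, strand = layout$strand,
    type = r$values,
    start = pos[starts_rel], end = pos[ends], phase = NA_integer_)
  is_cds <- feats$type == "CDS"
  # phase: bases to skip (in transcription direction) to reach a codon start
  first_tpos <- vapply(which(is_cds), function(i) {
    seg <- starts_rel[i]:ends[i]
    if (layout$strand == "+") cdspos[seg[1]] else cdspos[seg[length(seg)]]
  }, integer(1))
  feats$phase[is_cds] <- (3L - (first_tpos - 1L) %% 3L) %% 3L

  gene <- data.table::data.table(
    gene_id = gid, chrom = chrom, strand = layout$strand,
    start = pos[1], end = pos[n])

  idx <- which(cdspos > 0L)
  gpos <- pos[idx][order(cdspos[idx])]     # genome pos per CDS base, 5'->3'
  cds <- list(chrom = chrom, strand = layout$strand,
              seq = layout$cds_seq, gpos = gpos)
  list(bases = bases, gene = gene, features = feats, cds = cds)
}

new_reference <- function(seq, genes, features, cds_list) {
  ref <- structure(list(seq = seq, genes = genes, features = features,
                        cds = cds_list, compartments = NULL),
                   class = "ma_reference")
  ref$compartments <- derive_compartments(ref)
  ref
}

#' @export
print.ma_reference <- function(x, ...) {
  cat(sprintf("MA reference: %d chromosome(s), %s bp, %d gene(s)\n",
              length(x$seq),
              format(sum(Biostrings::width(x$seq)), big.mark = ","),
              nrow(x$genes)))
  cc <- compartment_counts(x)
  cat("  compartments:",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  invisible(x)
}

# Per-base compartment codes: 1 nonsynonymous, 2 synonymous, 3 UTR,
# 4 intron, 5 intergenic.  Codes index COMPARTMENTS.
derive_compartments <- function(ref) {
  comp <- lapply(Biostrings::width(ref$seq), function(w)
    rep.int(5L, w))
  names(comp) <- names(ref$seq)
  if (nrow(ref$genes)) {
    for (i in seq_len(nrow(ref$genes))) {
      g <- ref$genes[i]
      comp[[g$chrom]][g$start:g$end] <- 4L
    }
    utr <- ref$features[ref$features$type %in%
                          c("five_prime_UTR", "three_prime_UTR")]
    if (nrow(utr)) for (i in seq_len(nrow(utr))) {
      u <- utr[i]
      comp[[u$chrom]][u$start:u$end] <- 3L
    }
    for (gid in names(ref$cds)) {
      cds <- ref$cds[[gid]]
      n <- nchar(cds$seq)
      if (n %% 3L != 0L) next      # invalid CDS left as intron
      codons <- substring(cds$seq, seq(1, n, 3), seq(3, n, 3))
      sf <- as.vector(t(SYN_FRAC[codons, , drop = FALSE]))
      lab <- ifelse(is.na(sf) | sf < 0.5, 1L, 2L)
      comp[[cds$chrom]][cds$gpos] <- lab
    }
  }
  lapply(comp, function(v) as.raw(v))
}

#' Compartment label counts of a reference
#'
#' @param ref An `ma_reference`.
#' @param by_chrom Return a chromosome-by-compartment matrix instead of
#'   genome totals.
#' @return Named integer vector of base counts per compartment label (or a
#'   matrix when `by_chrom = TRUE`).
#' @export
compartment_counts <- function(ref, by_chrom = FALSE) {
  tab1 <- function(v) {
    iv <- as.integer(v)
    vapply(1:5, function(k) sum(iv == k), numeric(1))
  }
  m <- vapply(ref$compartments, tab1, numeric(5))
  rownames(m) <- COMPARTMENTS
  if (by_chrom) t(m) else setNames(rowSums(m), COMPARTMENTS)
}

#' Compartment label at genomic positions
#'
#' @param ref An `ma_reference`.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Character vector of compartment labels.
#' @export
compartment_at <- function(ref, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- ref$compartments[[ch]]
    if (is.null(v)) stopf("unknown chromosome '%s'", ch)
    out[idx] <- COMPARTMENTS[as.integer(v[pos[idx]])]
  }
  out
}

ref_base <- function(ref, chrom, pos, width = 1L) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- as.character(Biostrings::extractAt(
      ref$seq[[ch]], IRanges::IRanges(pos[idx], width = width)))
  }
  out
}

genome_size <- function(ref) sum(Biostrings::width(ref$seq))

gc_fraction <- function(ref) {
  f <- Biostrings::letterFrequency(ref$seq, c("G", "C"))
  sum(f) / genome_size(ref)
}
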