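#' Write a reference bundle to FASTA and GFF3
#'
#' @param ref An `ma_reference`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the two paths. Output is byte-stable for a fixed
#'   reference.
#' @export
write_reference <- function(ref, fasta, gff3) {
  stopifnot(inherits(ref, "ma_reference"))
  Biostrings::writeXStringSet(ref$seq, fasta)
  grl <- list()
  if (nrow(ref$genes)) {
    genes <- GenomicRanges::GRanges(
      ref$genes$chrom,
      IRanges::IRanges(ref$genes$start, ref$genes$end),
      strand = ref$genes$strand, type = "gene", ID = ref$genes$gene_id,
      Parent = NA_character_, phase = NA_integer_)
    fid <- sprintf("%s.%s%03d", ref$features$gene_id, tolower(
      substr(ref$features$type, 1, 1)), seq_len(nrow(ref$features)))
    feats <- GenomicRanges::GRanges(
      ref$features$chrom,
      IRanges::IRanges(ref$features$start, ref$features$end),
      strand = ref$features$strand, type = ref$features$type,
      ID = fid, Parent = ref$features$gene_id, phase = ref$features$phase)
    gr <- c(genes, feats)
    gr <- gr[order(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))]
    rtracklayer::export.gff3(gr, gff3)
  } else {
    writeLines("##gff-version 3", gff3)
  }
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a reference genome and gene annotation
#'
#' Parses FASTA sequences and GFF3 gene models and derives the per-base
#' compartment map: CDS bases are split into nonsynonymous and synonymous
#' by Nei-Gojobori-style site weights (a base is synonymous when at least
#' half of its three possible substitutions are silent), annotated UTR
#' bases are `UTR`, bases inside a gene but outside annotated exons are
#' `intron`, everything else `intergenic`. Genes whose CDS length is not a
#' multiple of three after phase adjustment are excluded from the
#' compartment map with a warning (their bases keep the intron label).
#'
#' @param fasta Path to the reference FASTA.
#' @param gff3 Path to the GFF3 annotation (may contain only headers).
#' @return An `ma_reference`; see [generate_reference()].
#' @export
read_reference <- function(fasta, gff3) {
  if (!file.exists(fasta)) stopf("FASTA not found: %s", fasta)
  if (!file.exists(gff3)) stopf("GFF3 not found: %s", gff3)
  seq <- Biostrings::readDNAStringSet(fasta)
  names(seq) <- sub("\\s.*$", "", names(seq))

  gff <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                  error = function(e) NULL)
  genes <- empty_genes(); feats <- empty_features(); cds_list <- list()
  if (!is.null(gff) && length(gff)) {
    d <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gff)),
      start = GenomicRanges::start(gff), end = GenomicRanges::end(gff),
      strand = as.character(GenomicRanges::strand(gff)),
      type = as.character(gff$type),
      phase = if (!is.null(gff$phase)) gff$phase else NA_integer_,
      id = if (!is.null(gff$ID)) as.character(gff$ID) else NA_character_,
      parent = if (!is.null(gff$Parent))
        vapply(gff$Parent, function(p)
          if (length(p)) as.character(p[1]) else NA_character_,
          character(1))
      else NA_character_)
    gd <- d[type == "gene"]
    if (nrow(gd)) {
      genes <- data.table::data.table(
        gene_id = gd$id, chrom = gd$chrom, strand = gd$strand,
        start = gd$start, end = gd$end)
      fd <- d[type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                          "exon", "mRNA")]
      # resolve each feature to its gene (parents may be mRNA ids)
      parent_gene <- setNames(gd$id, gd$id)
      mr <- d[type == "mRNA"]
      if (nrow(mr)) parent_gene[mr$id] <- parent_gene[mr$parent]
      fd[, gene_id := parent_gene[parent]]
      fd <- fd[!is.na(gene_id) & type != "mRNA"]
      feats <- fd[, .(gene_id, chrom, strand, type, start, end, phase)]
      cds_list <- build_cds_index(seq, genes, feats)
    }
  }
  new_reference(seq, genes, feats, cds_list)
}

# Spliced CDS sequences plus genome positions per CDS base (5'->3').
build_cds_index <- function(seq, genes, feats) {
  cds_list <- list()
  cd <- feats[feats$type == "CDS"]
  for (gid in unique(cd$gene_id)) {
    segs <- cd[cd$gene_id == gid]
    minus <- segs$strand[1] == "-"
    data.table::setorder(segs, start)
    if (minus) segs <- segs[rev(seq_len(nrow(segs)))]
    gpos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      if (minus) segs$end[i]:segs$start[i] else segs$start[i]:segs$end[i]
    }))
    total <- length(gpos)
    # honour the phase of the first segment (bases to skip 5' of codon 1)
    ph <- segs$phase[1]
    if (!is.na(ph) && ph > 0) gpos <- gpos[-seq_len(ph)]
    if (length(gpos) %% 3L != 0L) {
      warning(sprintf(
        "gene %s: CDS length %d not a multiple of 3; excluded from %s",
        gid, total, "the compartment map"), call. = FALSE)
      next
    }
    chrom <- segs$chrom[1]
    bases <- strsplit(as.character(seq[[chrom]]), NULL)[[1]][gpos]
    if (minus) bases <- comp_base(bases)
    cds_list[[gid]] <- list(chrom = chrom,
                            strand = segs$strand[1],
                            seq = paste(bases, collapse = ""),
                            gpos = gpos)
  }
  cds_list
}

# --- variant records --------------------------------------------------------

GT_CODES <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Read multi-sample variant records from a VCF
#'
#' Parses a VCF v4.2 file with `GT:AD:DP` genotype fields into the site and
#' genotype tables the filter stack consumes. Missing site annotations
#' (FS, MQRankSum, ReadPosRankSum) surface as `NA`, never as zero.
#' Genotypes with more than one ALT allele are kept with the full ALT
#' string so the multi-allelic filter can see them. Rows whose allele
#' depths exceed the total depth are rejected with a parse error.
#'
#' @param path Path to a plain or gzipped VCF.
#' @return An object of class `ma_records`: a list with data.tables `sites`
#'   (`chrom`, `pos`, `ref`, `alt`, `fs`, `mqrs`, `rprs`) and `geno`
#'   (`chrom`, `pos`, `line`, `gt` coded 0 = hom-ref, 1 = het,
#'   2 = hom-alt, `NA` = missing, `ad_ref`, `ad_alt`, `dp`), plus `lines`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  sites <- data.table::data.table(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    fs = suppressWarnings(vcfR::extract.info(v, "FS", as.numeric = TRUE)),
    mqrs = suppressWarnings(
      vcfR::extract.info(v, "MQRankSum", as.numeric = TRUE)),
    rprs = suppressWarnings(
      vcfR::extract.info(v, "ReadPosRankSum", as.numeric = TRUE)))

  gt <- vcfR::extract.gt(v, "GT")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  lines <- colnames(gt)
  ns <- nrow(sites); nl <- length(lines)

  ad1 <- suppressWarnings(as.integer(sub(",.*$", "", ad)))
  ad2 <- suppressWarnings(as.integer(
    vapply(strsplit(as.vector(ad), ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))))

  geno <- data.table::data.table(
    chrom = rep(sites$chrom, times = nl),
    pos = rep(sites$pos, times = nl),
    line = rep(lines, each = ns),
    gt = unname(GT_CODES[as.vector(gt)]),
    ad_ref = as.vector(ad1), ad_alt = as.vector(ad2),
    dp = as.integer(as.vector(dp)))

  bad <- which(!is.na(geno$ad_ref) & !is.na(geno$ad_alt) & !is.na(geno$dp) &
                 geno$ad_ref + geno$ad_alt > geno$dp)
  if (length(bad))
    stopf("allele depths exceed total depth for %d genotype(s), e.g. %s:%d",
          length(bad), geno$chrom[bad[1]], geno$pos[bad[1]])
  data.table::setorder(geno, chrom, pos, line)
  structure(list(sites = sites, geno = geno, lines = lines),
            class = "ma_records")
}

#' Write variant records as a multi-sample VCF
#'
#' Inverse of [read_variants()]: emits VCF v4.2 with `GT:AD:DP` per sample
#' and site-level `FS`, `MQRankSum`, `ReadPosRankSum` INFO fields.
#' Output is bgzip-free gzip text (`.vcf.gz`).
#'
#' @param records An `ma_records` (or `ma_evidence`) object.
#' @param path Output path; `.vcf.gz` is appended if no `.gz` suffix.
#' @return Invisibly, the path written.
#' @export
write_variants <- function(records, path) {
  stopifnot(inherits(records, "ma_records"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  s <- records$sites
  g <- records$geno
  info <- sprintf("FS=%s", format_num(s$fs))
  info <- ifelse(is.na(s$mqrs), info,
                 sprintf("%s;MQRankSum=%s", info, format_num(s$mqrs)))
  info <- ifelse(is.na(s$rprs), info,
                 sprintf("%s;ReadPosRankSum=%s", info, format_num(s$rprs)))
  info[is.na(s$fs) & is.na(s$mqrs) & is.na(s$rprs)] <- "."

  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos), ID = ".",
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt_str <- ifelse(is.na(g$gt), "./.:.,.:.",
                   sprintf("%s:%d,%d:%d",
                           c("0/0", "0/1", "1/1")[g$gt + 1L],
                           g$ad_ref, g$ad_alt, g$dp))
  key <- paste(g$chrom, g$pos)
  skey <- paste(s$chrom, s$pos)
  m <- matrix("./.:.,.:.", nrow = nrow(s), ncol = length(records$lines),
              dimnames = list(NULL, records$lines))
  m[cbind(match(key, skey), match(g$line, records$lines))] <- gt_str
  gt <- cbind(FORMAT = "GT:AD:DP", m)

  meta <- c("##fileformat=VCFv4.2",
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias (Fisher exact)">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping-quality rank-sum z">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read-position rank-sum z">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">')
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  out[is.na(x)] <- "."
  out
}

# --- depth tracks and callable mask ----------------------------------------

#' Write / read a per-site depth track
#'
#' Tab-separated with columns `chrom`, `pos` (1-based), `line`, `depth`.
#'
#' @param depth A data.table with those columns.
#' @param path File path (gzip by suffix).
#' @return `write_depth` invisibly returns `path`; `read_depth` returns the
#'   data.table.
#' @export
write_depth <- function(depth, path) {
  data.table::fwrite(depth[, .(chrom, pos, line, depth)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stopf("depth track not found: %s", path)
  d <- data.table::fread(path, sep = "\t",
                         colClasses = list(character = c("chrom", "line"),
                                           integer = c("pos", "depth")))
  stopifnot(all(c("chrom", "pos", "line", "depth") %in% names(d)))
  d
}

#' Build the callable-site mask from a depth track
#'
#' A site is callable for a line iff `min_depth <= depth <= max_depth`,
#' both bounds inclusive. Widening the bounds never removes sites.
#'
#' @param depth Depth track data.table (`chrom`, `pos`, `line`, `depth`).
#' @param min_depth,max_depth Inclusive depth bounds (defaults 20 and 300).
#' @param n_callable_override Optional named numeric vector (per line) of
#'   genome-wide callable-site totals, for sparse tracks that cover only
#'   variant sites; when supplied it replaces the per-line counts derived
#'   from the track.
#' @return An object of class `ma_callable`: list with `mask` (data.table
#'   `chrom`, `pos`, `line`, `callable`) and `n_callable` (named numeric
#'   per line).
#' @export
build_callable_mask <- function(depth, min_depth = 20, max_depth = 300,
                                n_callable_override = NULL) {
  stopifnot(min_depth <= max_depth)
  m <- depth[, .(chrom, pos, line, depth)]
  m[, callable := depth >= min_depth & depth <= max_depth]
  n <- m[, sum(callable), by = line]
  n_callable <- setNames(as.numeric(n$V1), n$line)
  if (!is.null(n_callable_override)) {
    stopifnot(!is.null(names(n_callable_override)))
    n_callable[names(n_callable_override)] <- n_callable_override
  }
  structure(list(mask = m[, .(chrom, pos, line, callable)],
                 n_callable = n_callable,
                 min_depth = min_depth, max_depth = max_depth),
            class = "ma_callable")
}
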