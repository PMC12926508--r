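eight <- sprintf("L%d", 1:8)

test_that("ancestral consensus follows the shared-by-n-minus-one rule", {
  rec <- make_records(list(
    # 7 of 8 hom-ref, one het: ancestral hom-ref
    list(pos = 100, geno = c(rep(list(HOM()), 7), list(HET()))),
    # 6 of 8 agree: uncallable at the default consensus
    list(pos = 200, geno = c(rep(list(HOM()), 6), rep(list(HET()), 2))),
    # all het: ancestral het
    list(pos = 300, geno = rep(list(HET()), 8)),
    # any missing genotype: conservative, uncallable
    list(pos = 400, geno = c(rep(list(HOM()), 7),
                             list(list(NA_integer_, 0L, 0L, 0L))))),
    eight)
  anc <- infer_ancestral(rec)
  expect_equal(anc[pos == 100, anc_gt], 0L)
  expect_equal(anc[pos == 100, support], 7L)
  expect_true(is.na(anc[pos == 200, anc_gt]))
  expect_equal(anc[pos == 300, anc_gt], 1L)
  expect_true(is.na(anc[pos == 400, anc_gt]))
  # lowering the consensus threshold rescues the 6-of-8 site
  anc6 <- infer_ancestral(rec, min_consensus = 6)
  expect_equal(anc6[pos == 200, anc_gt], 0L)
})

test_that("consensus is undefined below three lines", {
  rec <- make_records(list(list(pos = 1, geno = list(HOM(), HOM()))),
                      c("L1", "L2"))
  expect_error(infer_ancestral(rec), "at least 3")
})

test_that("call acceptance rules: uniqueness, Hom>Het only, read veto", {
  rec <- make_records(list(
    # unique A/A -> A/G, no G reads elsewhere: accepted
    list(pos = 100, ref = "A", alt = "G",
         geno = c(list(HET()), rep(list(HOM()), 7))),
    # another line carries 2 reads of the variant allele: rejected
    list(pos = 200, ref = "A", alt = "G",
         geno = c(list(HET()), list(list(0L, 78L, 2L, 80L)),
                  rep(list(HOM()), 6))),
    # two lines mutated at the same site: not unique, rejected
    list(pos = 300, ref = "A", alt = "G",
         geno = c(list(HET(), HET()), rep(list(HOM()), 6))),
    # het -> hom-alt in one line (LOH-type signal): not a mutation
    list(pos = 400, ref = "A", alt = "G",
         geno = c(list(HOMALT()), rep(list(HET()), 7)))),
    eight)
  anc <- infer_ancestral(rec)
  calls <- call_mutations(anc, rec)
  expect_equal(calls$pos, 100L)
  expect_equal(calls$line, "L1")
  expect_equal(calls$class, "SNM")
})

test_that("calls near surviving indels are excluded, boundary at the window", {
  mk <- function(snp_pos) make_records(list(
    list(pos = 500, ref = "GTT", alt = "G",
         geno = rep(list(HET()), 8)),                   # ancestral indel
    list(pos = snp_pos, ref = "A", alt = "C",
         geno = c(list(HET()), rep(list(HOM()), 7)))),
    eight)
  near <- mk(515)
  far <- mk(525)
  expect_equal(nrow(call_mutations(infer_ancestral(near), near)), 0L)
  expect_equal(nrow(call_mutations(infer_ancestral(far), far)), 1L)
})

test_that("MNM grouping chains same-line SNMs within the window", {
  calls <- data.table::data.table(
    line = c("L1", "L1", "L1", "L2", "L1"),
    chrom = c("c1", "c1", "c1", "c1", "c2"),
    pos = c(100L, 130L, 190L, 1000L, 1030L),
    ref = "A", alt = "G", class = "SNM", mnm_group = NA_character_)
  data.table::setattr(calls, "class", c("ma_calls", class(calls)))
  g <- group_mnms(calls, window = 50L)
  # 100 and 130 chain; 190 is 60 bp from 130: ungrouped
  expect_false(is.na(g[pos == 100, mnm_group]))
  expect_equal(g[pos == 100, mnm_group], g[pos == 130, mnm_group])
  expect_true(is.na(g[pos == 190, mnm_group]))
  # different line / chromosome never chain
  expect_true(is.na(g[pos == 1000, mnm_group]))
  expect_true(is.na(g[line == "L1" & pos == 1030, mnm_group]))
  s <- mnm_summary(g)
  expect_equal(s$n_groups, 1L)
  expect_equal(s$n_members, 2L)
})

test_that("impact annotation translates codons on both strands", {
  ref <- all_cds_reference()
  cds <- ref$cds$g1$seq
  # find a CAA codon and mutate its first base to T: stop gained
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  i_caa <- which(codons == "CAA")[1]
  expect_false(is.na(i_caa))
  p <- (i_caa - 1) * 3 + 1
  expect_equal(annotate_impact(ref, "chr01", p, "C", "T"), "HIGH")
  # CTT -> CTC: silent (Leu)
  i_ctt <- which(codons == "CTT")[1]
  if (!is.na(i_ctt)) {
    p3 <- (i_ctt - 1) * 3 + 3
    expect_equal(annotate_impact(ref, "chr01", p3, "T", "C"), "LOW")
  }
  # a second-position change is almost always missense
  i_aaa <- which(codons == "AAA")[1]
  p2 <- (i_aaa - 1) * 3 + 2
  expect_equal(annotate_impact(ref, "chr01", p2, "A", "G"), "MODERATE")
  # start-lost
  expect_equal(annotate_impact(ref, "chr01", 1, "A", "G"), "HIGH")
})

test_that("annotated simulated calls agree with the planted truth", {
  sim <- tiny_sim()
  calls <- tiny_calls()
  truth <- sim$truth
  tk <- paste(truth$planted_snms$line, truth$planted_snms$chrom,
              truth$planted_snms$pos)
  ck <- calls[class == "SNM", paste(line, chrom, pos)]
  expect_gte(length(tk), 100)
  expect_gte(mean(ck %in% tk), 0.95)    # precision
  expect_gte(mean(tk %in% ck), 0.95)    # recall
  ik <- paste(truth$planted_indels$line, truth$planted_indels$chrom,
              truth$planted_indels$pos)
  cik <- calls[class != "SNM", paste(line, chrom, pos)]
  expect_gte(mean(cik %in% ik), 0.9)
  expect_gte(mean(ik %in% cik), 0.9)
  # intergenic calls are MODIFIER; noncoding impact never HIGH/LOW
  expect_true(all(calls[compartment == "intergenic", impact] == "MODIFIER"))
  # per-line counts sum to the total (no double counting)
  expect_equal(sum(calls[, .N, by = line]$N), nrow(calls))
})

test_that("no call sits within 20 bp of a surviving indel record", {
  calls <- tiny_calls()
  filt <- tiny_filtered()
  s <- filt$records$sites
  indel <- s[nchar(ref) != 1L | nchar(alt) != 1L]
  for (ch in unique(calls$chrom)) {
    ip <- indel[chrom == ch, pos]
    cp <- calls[chrom == ch & class == "SNM", pos]
    if (!length(ip) || !length(cp)) next
    d <- vapply(cp, function(p) min(abs(ip - p)), numeric(1))
    expect_true(all(d > 20))
  }
})

test_that("planted trinucleotide contexts are recovered exactly", {
  sim <- tiny_sim()
  calls <- tiny_calls()
  snm <- calls[class == "SNM" & !is.na(context)]
  # recompute contexts straight from the reference sequence
  for (i in sample(nrow(snm), 25)) {
    row <- snm[i]
    tri <- as.character(Biostrings::extractAt(
      sim$ref$seq[[row$chrom]],
      IRanges::IRanges(row$pos - 1L, row$pos + 1L)))
    if (!substr(tri, 2, 2) %in% c("C", "T")) {
      tri <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tri)))
    }
    expect_equal(substr(row$context, 5, 7), tri)
  }
})
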