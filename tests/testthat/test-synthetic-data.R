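test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "ma_sim_config")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(het_density = -0.1), "het_density")
  expect_error(sim_config(spectrum = c(1, 2, 3)), "six")
  expect_error(sim_config(spectrum = setNames(rep(0, 6), mamut:::SIX_CLASSES)),
               "positive sum")
  expect_error(sim_config(generations_per_line = 0), "generation")
  expect_error(sim_config(deletion_fraction = 2), "deletion_fraction")
})

test_that("generated reference matches the GC target and partitions bases", {
  cfg <- sim_config(seed = 9, n_chromosomes = 2, chromosome_length = 5e5,
                    gc_content = 0.409, gene_density = 10)
  ref <- generate_reference(cfg)
  gc <- mamut:::gc_fraction(ref)
  expect_gt(gc, 0.399)
  expect_lt(gc, 0.419)
  # every base carries exactly one compartment label
  cc <- compartment_counts(ref)
  expect_equal(sum(cc), 2 * 5e5)
  # CDS lengths are multiples of three and consistent with phases
  for (gid in names(ref$cds))
    expect_equal(nchar(ref$cds[[gid]]$seq) %% 3L, 0L)
  ph <- ref$features[type == "CDS"]
  expect_true(all(!is.na(ph$phase)))
})

test_that("gene-free genome is all intergenic; short chromosome rejected", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chromosome_length = 1e5,
                    gene_density = 0)
  ref <- generate_reference(cfg)
  cc <- compartment_counts(ref)
  expect_equal(unname(cc["intergenic"]), 1e5)
  expect_equal(sum(cc[setdiff(names(cc), "intergenic")]), 0)
  cfg2 <- sim_config(seed = 2, n_chromosomes = 1, chromosome_length = 300,
                     gene_density = 4000)
  expect_error(generate_reference(cfg2), "too short")
})

test_that("reference generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 31, n_chromosomes = 1, chromosome_length = 1e5,
                    gene_density = 20)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  d <- tempfile(); dir.create(d)
  write_reference(r1, file.path(d, "a.fa"), file.path(d, "a.gff3"))
  write_reference(r2, file.path(d, "b.fa"), file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.fa")),
                   readLines(file.path(d, "b.fa")))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("ancestor heterozygosity tracks het_density within binomial error", {
  cfg <- sim_config(seed = 4, n_chromosomes = 2, chromosome_length = 5e5,
                    gene_density = 0, het_density = 0.0057)
  ref <- generate_reference(cfg)
  anc <- simulate_ancestor(cfg, ref)
  N <- 1e6
  expected <- N * 0.0057
  tol <- 3 * sqrt(N * 0.0057 * (1 - 0.0057))
  expect_gt(nrow(anc), expected - tol)
  expect_lt(nrow(anc), expected + tol)
  # alternate alleles differ from the reference
  snv <- anc[is_indel == FALSE]
  expect_true(all(nchar(snv$alt) == 1L & snv$alt != snv$ref))
})

test_that("het_density edge cases give none or all heterozygous", {
  cfg0 <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 2e4,
                     gene_density = 0, het_density = 0)
  ref <- generate_reference(cfg0)
  expect_equal(nrow(simulate_ancestor(cfg0, ref)), 0)
  cfg1 <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 2e4,
                     gene_density = 0, het_density = 1,
                     het_indel_fraction = 0)
  ref1 <- generate_reference(cfg1)
  expect_equal(nrow(simulate_ancestor(cfg1, ref1)), 2e4)
})

test_that("planted mutation counts follow the Poisson exposure and truth is consistent", {
  sim <- tiny_sim()
  cfg <- tiny_config()
  L <- 2 * 2e5
  expected_snm <- cfg$snm_rate * 2 * L * 500 * cfg$n_lines
  expect_gt(nrow(sim$truth$planted_snms),
            expected_snm - 4 * sqrt(expected_snm))
  expect_lt(nrow(sim$truth$planted_snms),
            expected_snm + 4 * sqrt(expected_snm))
  # no two planted events in the same line share a position
  ev <- rbind(sim$truth$planted_snms[, .(line, chrom, pos)],
              sim$truth$planted_indels[, .(line, chrom, pos)])
  expect_equal(anyDuplicated(ev), 0L)
  # every planted LOH tract overlaps at least one ancestral het site
  expect_true(all(sim$truth$planted_loh$n_sites >= 1))
  # every planted SNM appears as a het genotype in exactly one line
  g <- sim$evidence$geno
  key <- paste(g$chrom, g$pos)
  snm_key <- paste(sim$truth$planted_snms$chrom, sim$truth$planted_snms$pos)
  het_per_site <- g[key %in% snm_key, sum(gt == 1L), by = .(chrom, pos)]
  expect_true(all(het_per_site$V1 == 1L))
})

test_that("loh_rate = 0 and deletion_fraction = 1 behave as configured", {
  cfg <- tiny_config(loh_rate_per_het_site = 0, seed = 8)
  ref <- generate_reference(cfg)
  anc <- simulate_ancestor(cfg, ref)
  lin <- evolve_ma_lines(anc, cfg, ref)
  expect_equal(nrow(lin$truth$planted_loh), 0L)
  cfg2 <- tiny_config(deletion_fraction = 1, seed = 8)
  ref2 <- generate_reference(cfg2)
  anc2 <- simulate_ancestor(cfg2, ref2)
  lin2 <- evolve_ma_lines(anc2, cfg2, ref2)
  expect_true(nrow(lin2$truth$planted_loh) > 0)
  expect_true(all(lin2$truth$planted_loh$mechanism == "deletion"))
})

test_that("deletion tracts halve carrier depth; other lines unaffected", {
  sim <- tiny_sim()
  del <- sim$truth$planted_loh[mechanism == "deletion"]
  expect_gt(nrow(del), 0)
  d <- evidence_depth(sim$evidence)
  tr <- del[which.max(del$n_sites)]
  inside <- d[chrom == tr$chrom & pos >= tr$start & pos <= tr$end]
  carrier <- inside[line == tr$line, mean(depth)]
  others <- inside[line != tr$line, mean(depth)]
  expect_lt(carrier / others, 0.65)
  expect_gt(carrier / others, 0.35)
})

test_that("error-free evidence reproduces the simulated genotypes", {
  sim <- tiny_sim()
  g <- sim$evidence$geno
  # ancestral sites outside LOH tracts must be het in every line
  loh_key <- paste(sim$lines$loh_sites$line, sim$lines$loh_sites$chrom,
                   sim$lines$loh_sites$pos)
  anc_key <- paste(sim$ancestor$chrom, sim$ancestor$pos)
  gk <- paste(g$line, g$chrom, g$pos)
  anc_rows <- g[paste(chrom, pos) %in% anc_key & !(gk %in% loh_key)]
  expect_true(all(anc_rows$gt == 1L))
  # allele depths never exceed total depth
  expect_true(all(g$ad_ref + g$ad_alt <= g$dp | is.na(g$gt)))
})

test_that("artifact injection produces exactly the requested sites", {
  cfg <- tiny_config(seed = 77)
  ref <- generate_reference(cfg)
  anc <- simulate_ancestor(cfg, ref)
  lin <- evolve_ma_lines(anc, cfg, ref)
  art <- setNames(rep(3L, length(mamut:::ARTIFACT_CLASSES)),
                  mamut:::ARTIFACT_CLASSES)
  ev <- emit_evidence(lin, cfg, ref, artifacts = art)
  expect_equal(nrow(ev$artifact_truth), 3L * length(mamut:::ARTIFACT_CLASSES))
  # FS > 60 occurs exactly at the high_fs artifacts
  expect_equal(sum(ev$sites$fs > 60, na.rm = TRUE), 3L)
})

test_that("population frequencies seed the requested fraction of SNMs", {
  sim <- tiny_sim()
  pf <- sim$popfreq
  snms <- sim$truth$planted_snms
  m <- merge(snms, pf[seeded == TRUE], by = c("chrom", "pos"))
  expect_equal(nrow(m), round(0.3 * nrow(snms)))
  expect_true(all(m$maf > 0.02))
  # fixed seed: identical table on rerun
  pf2 <- simulate_population_frequencies(sim$ref, tiny_config(), sim$truth,
                                         seeded_fraction = 0.3)
  expect_identical(as.data.frame(pf), as.data.frame(pf2))
})
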