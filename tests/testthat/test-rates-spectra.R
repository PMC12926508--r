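test_that("per-line rate is the exact quotient with diploid scaling", {
  expect_equal(per_line_rate(0, 500, 1e7), 0)
  expect_equal(per_line_rate(112, 507, 8.766e7), 1.26e-9, tolerance = 5e-3)
  # doubling the callable sites halves the rate
  expect_equal(per_line_rate(100, 500, 2e7),
               per_line_rate(100, 500, 1e7) / 2)
  expect_error(per_line_rate(10, 0, 1e7), "positive")
  expect_error(per_line_rate(10, 500, 0), "positive")
})

test_that("pooled CI on the published per-line rates reproduces the printed bounds", {
  tabs <- ma_study_tables()
  p <- pooled_rate_ci(tabs$lines$mu_snm, method = "normal")
  expect_equal(p$mean, 2.23e-9, tolerance = 1e-3)
  expect_equal(p$ci_low, 1.70e-9, tolerance = 3e-3)
  expect_equal(p$ci_high, 2.76e-9, tolerance = 3e-3)
  pi <- pooled_rate_ci(tabs$lines$mu_indel, method = "normal")
  expect_equal(pi$mean, 2.75e-10, tolerance = 1e-3)
  # equal rates give a zero-width interval
  pz <- pooled_rate_ci(rep(2e-9, 8))
  expect_equal(pz$ci_low, pz$ci_high)
  expect_error(pooled_rate_ci(1e-9), "two")
})

test_that("six-type spectrum conserves counts and normalizes by source content", {
  sim <- tiny_sim()
  calls <- tiny_calls()
  spec <- six_type_spectrum(calls, sim$evidence$exposures)
  expect_equal(sum(spec$table$count), sum(calls$class == "SNM"))
  expect_equal(spec$n_snm, sum(calls$class == "SNM"))
  # per-line counts also sum to the total
  expect_equal(sum(calls[class == "SNM", .N, by = line]$N), spec$n_snm)
  # realized classes follow the planted conditional weights folded with
  # the genome base composition (classes are drawn given the source base)
  planted <- tiny_config()$spectrum
  gc <- sum(spec$table$count[startsWith(spec$table$class, "C")]) /
    sum(spec$table$count)
  p_exp <- ifelse(startsWith(names(planted), "C"),
                  gc * planted / sum(planted[startsWith(names(planted), "C")]),
                  (1 - gc) * planted /
                    sum(planted[!startsWith(names(planted), "C")]))
  ct <- suppressWarnings(chisq.test(spec$table$count,
                                    p = p_exp / sum(p_exp)))
  expect_gt(ct$p.value, 1e-4)
  # and the realized source-base split tracks the reference GC content
  expect_lt(abs(gc - mamut:::gc_fraction(sim$ref)), 0.05)
})

test_that("published six-type table yields the printed Ts/Tv and rate ratio", {
  tabs <- ma_study_tables()
  ts <- tabs$six_type[type == "transition", sum(count)]
  tv <- tabs$six_type[type == "transversion", sum(count)]
  expect_equal(ts / tv, 1.31, tolerance = 3e-3)
  expect_equal(max(tabs$six_type$rate) / min(tabs$six_type$rate), 5.6,
               tolerance = 1e-2)
})

test_that("uniform spectrum gives Ts/Tv near the 0.5 null", {
  cfg <- tiny_config(seed = 13, spectrum = setNames(rep(1, 6),
                                                    mamut:::SIX_CLASSES))
  sim <- simulate_ma_experiment(cfg)
  filt <- apply_site_filters(sim$evidence)
  calls <- call_mutations(infer_ancestral(filt$records), filt$records)
  spec <- six_type_spectrum(calls, sim$evidence$exposures)
  n <- spec$n_snm
  expect_gt(n, 200)
  se <- sqrt(n * (1 / 3) * (2 / 3)) / n    # SE of the transition fraction
  frac_ts <- spec$ts_tv / (1 + spec$ts_tv)
  expect_lt(abs(frac_ts - 1 / 3), 4 * se)
})

test_that("equilibrium GC is the exact flux balance", {
  expect_equal(equilibrium_gc(1, 1), 0.5)
  expect_equal(equilibrium_gc(0, 2), 0)
  expect_error(equilibrium_gc(0, 0), "positive")
  # arithmetic on the published conditional rates
  tabs <- ma_study_tables()
  u <- tabs$six_type[label %in% c("A:T>G:C", "A:T>C:G"), sum(rate)]
  v <- tabs$six_type[label %in% c("C:G>T:A", "C:G>A:T"), sum(rate)]
  expect_equal(equilibrium_gc(u, v), 0.326, tolerance = 2e-3)
})

test_that("a spectrum with u = v planted returns exactly 0.5", {
  w <- c("C>A" = 1, "C>G" = 0.7, "C>T" = 1, "T>A" = 0.7, "T>C" = 1,
         "T>G" = 1)
  # force equal flux by symmetric exposures and counts
  exposures <- data.table::data.table(line = "L1", g = 1,
                                      n_gc = 1e6, n_at = 1e6)
  calls <- data.table::data.table(
    line = "L1", chrom = "c1", pos = seq_len(40),
    ref = rep(c("C", "C", "T", "T"), each = 10),
    alt = rep(c("T", "A", "C", "G"), each = 10),
    class = "SNM", mnm_group = NA_character_)
  data.table::setattr(calls, "class", c("ma_calls", class(calls)))
  spec <- six_type_spectrum(calls, exposures)
  expect_identical(spec$gc_equilibrium, 0.5)
})

test_that("96-context spectrum collapses strands and conserves totals", {
  sim <- tiny_sim()
  calls <- tiny_calls()
  tri <- trinucleotide_spectrum(calls, sim$ref)
  expect_length(tri$counts, 96)
  spec <- six_type_spectrum(calls, sim$evidence$exposures)
  expect_equal(sum(tri$counts), spec$n_snm - tri$n_edge_dropped)
  # a G>A call with 5'-T C A-3' on the reverse complement strand counts
  # as C>T in the TCA bin
  d <- tempfile(); dir.create(d)
  writeLines(c(">c1", "AATGAAA"), file.path(d, "r.fa"))
  writeLines("##gff-version 3", file.path(d, "r.gff3"))
  toy <- read_reference(file.path(d, "r.fa"), file.path(d, "r.gff3"))
  # position 4: ref G, context TGA; pyrimidine strand: TCA with C>T
  one <- data.table::data.table(line = "L1", chrom = "c1", pos = 4L,
                                ref = "G", alt = "A", class = "SNM",
                                mnm_group = NA_character_)
  data.table::setattr(one, "class", c("ma_calls", class(one)))
  tri1 <- trinucleotide_spectrum(one, toy)
  expect_equal(unname(tri1$counts["C>T:TCA"]), 1L)
  expect_equal(sum(tri1$counts), 1L)
})

test_that("corrected rate reproduces the published point estimates", {
  expect_equal(corrected_rate(2.23e-9, 0.21, 0.47), 2.45e-9,
               tolerance = 2e-3)
  expect_equal(corrected_rate(2.75e-10, 0.30, 0.71), 3.34e-10,
               tolerance = 2e-3)
  expect_equal(corrected_rate(5e-9, 0.3, 0), 5e-9)
  # monotone in deficit and in target fraction for positive deficit
  expect_gt(corrected_rate(1e-9, 0.2, 0.5), corrected_rate(1e-9, 0.2, 0.4))
  expect_gt(corrected_rate(1e-9, 0.3, 0.5), corrected_rate(1e-9, 0.2, 0.5))
})

test_that("deficit estimation inverts the observed-rate ratio", {
  expect_equal(estimate_deficit(0.53, 1), 0.47)
  expect_equal(estimate_deficit(1.08e-10, mean(c(4.14e-10, 3.26e-10))),
               0.708, tolerance = 1e-2)
  expect_equal(estimate_deficit(2, 2), 0)
})

test_that("effective population size matches the published arithmetic", {
  expect_equal(effective_population_size(0.017, 2.45e-9), 1734694,
               tolerance = 1e-6)
  expect_equal(effective_population_size(0.012, 2.45e-9), 1224490,
               tolerance = 1e-6)
  expect_equal(effective_population_size(0.01, 2e-9) / 2,
               effective_population_size(0.01, 4e-9))
  expect_error(effective_population_size(0.01, 0), "positive")
})

test_that("compartment tests: proportional counts give chi-squared zero", {
  calls <- data.table::data.table(
    line = "L1", chrom = "c1", pos = 1:100, ref = "A", alt = "G",
    class = "SNM", mnm_group = NA_character_,
    compartment = rep(c("intron", "intergenic"), each = 50))
  data.table::setattr(calls, "class", c("ma_calls", class(calls)))
  res <- compartment_rates(calls, c(intron = 1e6, intergenic = 1e6))
  expect_equal(res$pairwise$chisq, 0, tolerance = 1e-12)
  expect_equal(res$pairwise$df, 1L)
  expect_gt(res$pairwise$p, 0.999)
})

test_that("a two-fold depleted compartment is detected in most replicates", {
  set.seed(202)
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    # 300 expected calls over equal exposures, one class at half density
    n1 <- rpois(1, 200); n2 <- rpois(1, 100)
    calls <- data.table::data.table(
      line = "L1", chrom = "c1", pos = seq_len(n1 + n2), ref = "A",
      alt = "G", class = "SNM", mnm_group = NA_character_,
      compartment = c(rep("intergenic", n1), rep("nonsynonymous", n2)))
    data.table::setattr(calls, "class", c("ma_calls", class(calls)))
    res <- compartment_rates(calls, c(intergenic = 1e6,
                                      nonsynonymous = 1e6))
    if (res$pairwise$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("chromosome uniformity: df, zero statistic, and null p-values", {
  calls <- data.table::data.table(chrom = rep(c("c1", "c2", "c3"),
                                              c(50, 30, 20)))
  exp0 <- c(c1 = 5e6, c2 = 3e6, c3 = 2e6)
  res <- chromosome_uniformity(calls, exp0)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # p-values approximately uniform under the null
  set.seed(7)
  ps <- replicate(60, {
    ch <- sample(names(exp0), 100, replace = TRUE,
                 prob = exp0 / sum(exp0))
    chromosome_uniformity(data.table::data.table(chrom = ch), exp0)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("neutral impact simulation matches exhaustive enumeration on an all-CDS genome", {
  ref <- all_cds_reference(n_codons = 300, seed = 6)
  w <- tiny_config()$spectrum
  # enumeration oracle: every (site, alt) weighted by the conditional
  # class probabilities
  L <- Biostrings::width(ref$seq)[1]
  bases <- strsplit(as.character(ref$seq[[1]]), NULL)[[1]]
  impacts <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  exp_prop <- setNames(numeric(4), impacts)
  for (p in seq_len(L)) {
    b <- bases[p]
    src <- if (b %in% c("C", "T")) b else c(A = "T", G = "C")[b]
    cls <- mamut:::SIX_CLASSES[startsWith(mamut:::SIX_CLASSES, src)]
    pw <- w[cls] / sum(w[cls])
    tgt <- substr(cls, 3, 3)
    alts <- if (b %in% c("C", "T")) tgt else
      c(A = "T", C = "G", G = "C", T = "A")[tgt]
    imp <- annotate_impact(ref, rep("chr01", 3), rep(p, 3),
                           ref_allele = rep(b, 3), alt_allele = alts)
    for (k in 1:3) exp_prop[imp[k]] <- exp_prop[imp[k]] + pw[k] / L
  }
  sim <- neutral_impact_simulation(400, w, ref, reps = 400, seed = 21)
  for (k in impacts) {
    row <- sim$summary[impact == k]
    expect_lt(abs(row$mean - exp_prop[[k]]),
              3 * max(row$sd / sqrt(400), 1e-4), label = k)
  }
  # all-CDS genome: nothing is MODIFIER
  expect_equal(sim$summary[impact == "MODIFIER", mean], 0)
  # fixed seed reproduces exactly
  sim2 <- neutral_impact_simulation(400, w, ref, reps = 400, seed = 21)
  expect_identical(sim$summary, sim2$summary)
})

test_that("gene-free genome sends every simulated SNM to MODIFIER", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 5e4,
                    gene_density = 0)
  ref <- generate_reference(cfg)
  sim <- neutral_impact_simulation(50, tiny_config()$spectrum, ref,
                                   reps = 20, seed = 4)
  expect_equal(sim$summary[impact == "MODIFIER", mean], 1)
  expect_equal(sim$summary[impact == "MODIFIER", sd], 0)
})
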