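# Hand-built het-site scaffolds for targeted HMM checks: `hom_at` marks
# ancestral het sites observed homozygous in the focal line L1.
loh_records <- function(positions, hom_at, lines = sprintf("L%d", 1:4),
                        hom_other = list()) {
  rows <- lapply(positions, function(p) {
    geno <- lapply(lines, function(l) {
      if ((l == "L1" && p %in% hom_at) ||
            (!is.null(hom_other[[l]]) && p %in% hom_other[[l]])) HOM(80)
      else HET(80)
    })
    list(pos = p, geno = geno)
  })
  make_records(rows, lines)
}

all_het_ancestral <- function(records) {
  anc <- records$geno[, .(anc_gt = 1L, support = .N), by = .(chrom, pos)]
  data.table::setattr(anc, "class", c("ma_ancestral", class(anc)))
  anc[]
}

test_that("a long clean homozygous run is decoded as one tract", {
  pos <- seq(1000, 1000 + 69 * 200, by = 200)   # 70 sites, 200 bp apart
  hom <- pos[11:60]                              # 50 consecutive hom sites
  rec <- loh_records(pos, hom)
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  expect_equal(nrow(loh$tracts), 1L)
  expect_equal(loh$tracts$n_sites, 50L)
  expect_equal(loh$tracts$min_start, hom[1])
  expect_equal(loh$tracts$min_end, hom[50])
  # max span reaches one base inside the flanking retained-het sites
  expect_equal(loh$tracts$max_start, pos[10] + 1L)
  expect_equal(loh$tracts$max_end, pos[61] - 1L)
  expect_true(loh$tracts$min_end - loh$tracts$min_start <=
                loh$tracts$max_end - loh$tracts$max_start)
})

test_that("an isolated homozygous observation is not a tract", {
  pos <- seq(1000, 9000, by = 400)
  rec <- loh_records(pos, hom_at = pos[10])
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  expect_equal(nrow(loh$tracts), 0L)
})

test_that("short spans below 1 kb are rejected", {
  pos <- c(seq(1000, 5000, by = 400), 5100, 5200, 5300, 5400,
           seq(6000, 9000, by = 400))
  hom <- c(5100, 5200, 5300, 5400)   # 4 sites spanning only 300 bp
  rec <- loh_records(pos, hom)
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  expect_equal(nrow(loh$tracts), 0L)
})

test_that("tracts homozygous in a second line are rejected", {
  pos <- seq(1000, 1000 + 69 * 200, by = 200)
  hom <- pos[11:60]
  rec <- loh_records(pos, hom, hom_other = list(L3 = hom[1:25]))
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  expect_equal(nrow(loh$tracts), 0L)
  # but a minor overlap (< 10% of sites) is tolerated
  rec2 <- loh_records(pos, hom, hom_other = list(L3 = hom[1:3]))
  loh2 <- detect_loh_tracts(rec2, all_het_ancestral(rec2))
  expect_equal(nrow(loh2$tracts), 1L)
})

test_that("LOH rate arithmetic matches the published per-line example", {
  expect_equal(loh_rate(264, 507, 3.14e5), 1.66e-6, tolerance = 3e-3)
  expect_equal(loh_rate(0, 500, 1e5), 0)
  expect_equal(loh_rate(100, 1000, 1e5), loh_rate(100, 500, 1e5) / 2)
  expect_error(loh_rate(1, 0, 1e5), "positive")
})

test_that("experiment-wide rate averages per-line rates including zero lines", {
  tabs <- ma_study_tables()
  rates <- tabs$loh$loh_rate
  rates[is.na(rates)] <- 0
  expect_equal(mean(rates), 3.03e-5, tolerance = 2e-3)
  expect_equal(sum(tabs$loh$events), 48)
})

test_that("classification separates deletions from conversions by coverage", {
  pos <- seq(1000, 1000 + 99 * 200, by = 200)
  hom <- pos[21:60]
  lines <- sprintf("L%d", 1:4)
  rec <- loh_records(pos, hom, lines)
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  expect_equal(nrow(loh$tracts), 1L)
  mk_depth <- function(carrier_ratio, others_ratio = 1) {
    data.table::rbindlist(lapply(lines, function(l)
      data.table::data.table(
        chrom = "chr01", pos = pos, line = l,
        depth = ifelse(pos %in% hom,
                       round(80 * (if (l == "L1") carrier_ratio
                                   else others_ratio)), 80L))))
  }
  del <- classify_mechanism(loh, mk_depth(0.5))
  expect_equal(del$tracts$mechanism, "deletion")
  conv <- classify_mechanism(loh, mk_depth(1.0))
  expect_equal(conv$tracts$mechanism, "conversion")
  # focal at 0.6x but another line also dropped: deletion criteria unmet
  both <- classify_mechanism(loh, mk_depth(0.6, others_ratio = 0.6))
  expect_equal(both$tracts$mechanism, "conversion")
})

test_that("conversion GC bias test matches the exact binomial oracle", {
  pos <- seq(1000, 1000 + 59 * 200, by = 200)
  hom <- pos[11:50]
  rec <- loh_records(pos, hom)
  # make every site strong/weak informative and resolve all to the ref
  rec$sites[, `:=`(ref = "G", alt = "T")]
  loh <- detect_loh_tracts(rec, all_het_ancestral(rec))
  loh$tracts$mechanism <- "conversion"
  res <- gc_conversion_bias(loh)
  expect_equal(res$n_eligible, 40L)
  expect_equal(res$gc_fraction, 1)       # hom calls were hom-ref = G
  expect_equal(res$p_value, 2 * 0.5^40, tolerance = 1e-9)
  # ineligible A/T<->G/C-uninformative sites drop from the denominator
  rec2 <- loh_records(pos, hom)
  rec2$sites[, `:=`(ref = "A", alt = "T")]
  loh2 <- detect_loh_tracts(rec2, all_het_ancestral(rec2))
  loh2$tracts$mechanism <- "conversion"
  expect_error(gc_conversion_bias(loh2), "informative")
})

test_that("balanced resolution gives a near-unit p-value", {
  # 10 of 10 GC vs 500 of 1000: oracle checks on binomial arithmetic
  expect_equal(binom.test(500, 1000, 0.5)$p.value, 1, tolerance = 0.05)
  expect_equal(binom.test(10, 10, 0.5)$p.value, 2 * 0.5^10,
               tolerance = 1e-9)
})

test_that("planted tracts are recovered with spans inside one inter-site gap", {
  sim <- tiny_sim()
  filt <- tiny_filtered()
  anc <- tiny_ancestral()
  loh <- detect_loh_tracts(filt$records, anc, ref = sim$ref)
  loh <- classify_mechanism(loh, evidence_depth(sim$evidence))
  tr <- loh$tracts
  tt <- sim$truth$planted_loh
  expect_gt(nrow(tt), 5)
  # every reported tract nests min span within max span
  expect_true(all(tr$min_start >= tr$max_start))
  expect_true(all(tr$min_end <= tr$max_end))
  # match detected tracts to planted ones by same-line overlap
  overlaps_other_line <- function(row) {
    nrow(tt[line != row$line & chrom == row$chrom &
              pmin(end, row$end) >= pmax(start, row$start)]) > 0
  }
  matched <- 0L
  for (i in seq_len(nrow(tr))) {
    hit <- tt[line == tr$line[i] & chrom == tr$chrom[i] &
                pmin(end, tr$min_end[i]) >= pmax(start, tr$min_start[i])]
    if (nrow(hit) == 1) {
      matched <- matched + 1L
      # exact boundary recovery holds when no other line's planted tract
      # overlaps (cross-line overlap removes sites from the consensus
      # het scaffold, truncating the recoverable span)
      if (!overlaps_other_line(hit)) {
        expect_equal(tr$min_start[i], hit$first_site)
        expect_equal(tr$min_end[i], hit$last_site)
      }
    }
  }
  expect_gte(matched / nrow(tr), 0.9)
})
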