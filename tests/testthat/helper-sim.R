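# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A small but complete experiment: genes on both strands, SNMs, indels,
# LOH tracts, clean evidence.
tiny_config <- function(...) {
  args <- list(seed = 42, n_chromosomes = 2, chromosome_length = 2e5,
               gene_density = 40, snm_rate = 1.5e-7, indel_rate = 3e-8,
               loh_rate_per_het_site = 2e-5,
               tract_length_dist = list(name = "lognormal",
                                        meanlog = log(1e4), sdlog = 0.5,
                                        min = 2e3, max = 1e5),
               genotyping_error = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_sim <- function() cached("tiny_sim", simulate_ma_experiment(
  tiny_config(), population = TRUE, seeded_fraction = 0.3))

tiny_filtered <- function() cached("tiny_filtered",
                                   apply_site_filters(tiny_sim()$evidence))

tiny_ancestral <- function() cached("tiny_ancestral",
                                    infer_ancestral(tiny_filtered()$records))

tiny_calls <- function() cached("tiny_calls", {
  sim <- tiny_sim()
  calls <- call_mutations(tiny_ancestral(), tiny_filtered()$records)
  annotate_calls(group_mnms(calls), sim$ref)
})

# A toy genome that is one single CDS spanning (almost) the whole
# chromosome: used for codon-exact oracles.
all_cds_reference <- function(n_codons = 400, seed = 5) {
  cached(sprintf("cds_ref_%d_%d", n_codons, seed), {
    set.seed(seed)
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    codons <- c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA")
    seq <- paste(codons, collapse = "")
    dir <- tempfile("cdsref")
    dir.create(dir)
    fa <- file.path(dir, "ref.fa"); gff <- file.path(dir, "ref.gff3")
    writeLines(c(">chr01", seq), fa)
    n <- nchar(seq)
    writeLines(c("##gff-version 3",
                 sprintf("chr01\ttest\tgene\t1\t%d\t.\t+\t.\tID=g1", n),
                 sprintf("chr01\ttest\tmRNA\t1\t%d\t.\t+\t.\tID=m1;Parent=g1",
                         n),
                 sprintf("chr01\ttest\tCDS\t1\t%d\t.\t+\t0\tID=c1;Parent=m1",
                         n)),
               gff)
    read_reference(fa, gff)
  })
}

# Hand-built records for unit tests of filters/calling: `rows` is a list
# of lists with chrom, pos, ref, alt, fs/mqrs/rprs, and per-line genotype
# specs list(gt, ad_ref, ad_alt, dp).
make_records <- function(rows, lines) {
  sites <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(chrom = r$chrom %||% "chr01", pos = r$pos,
                           ref = r$ref %||% "A", alt = r$alt %||% "T",
                           fs = r$fs %||% 1.0,
                           mqrs = r$mqrs %||% 0.0,
                           rprs = r$rprs %||% 0.0)))
  geno <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::rbindlist(lapply(seq_along(lines), function(i) {
      gspec <- r$geno[[i]]
      data.table::data.table(chrom = r$chrom %||% "chr01", pos = r$pos,
                             line = lines[i], gt = gspec[[1]],
                             ad_ref = gspec[[2]], ad_alt = gspec[[3]],
                             dp = gspec[[4]])
    }))
  }))
  data.table::setorder(sites, chrom, pos)
  data.table::setorder(geno, chrom, pos, line)
  structure(list(sites = sites, geno = geno, lines = lines),
            class = "ma_records")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype spec helpers: hom-ref / het / hom-alt at a given depth
HOM <- function(dp = 80) list(0L, dp, 0L, dp)
HET <- function(dp = 80, alt = NULL) {
  if (is.null(alt)) alt <- round(dp / 2)
  list(1L, dp - alt, alt, dp)
}
HOMALT <- function(dp = 80) list(2L, 0L, dp, dp)
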