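#' Configuration for a synthetic mutation-accumulation experiment
#'
#' Bundles every parameter of the simulator: the reference genome to
#' generate, the ancestral heterozygosity, the per-line mutational input,
#' loss-of-heterozygosity (LOH) dynamics, and the sequencing-evidence noise
#' model. Defaults emulate the published Daphnia MA design: eight lines
#' propagated for roughly 500 generations on a genome with GC content 0.409
#' and 0.57% ancestral heterozygosity, sequenced to ~80x depth with callable
#' sites restricted to depths 20-300.
#'
#' @param seed Integer seed governing all random draws. Per-stage seeds are
#'   derived from it so stages can be regenerated independently.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bases.
#' @param gc_content Target GC fraction of the reference, in `[0,1]`.
#' @param gene_density Protein-coding genes per megabase.
#' @param n_lines Number of MA lines.
#' @param generations_per_line Integer vector of generation counts, recycled
#'   to `n_lines`.
#' @param het_density Fraction of ancestral sites that are heterozygous.
#' @param het_indel_fraction Fraction of ancestral heterozygous sites that
#'   are short indel polymorphisms rather than SNVs.
#' @param snm_rate Single-nucleotide mutation rate per site per generation.
#' @param indel_rate Small-indel mutation rate per site per generation.
#' @param spectrum Named numeric vector of six conditional substitution
#'   weights in pyrimidine-centred order (`C>A`, `C>G`, `C>T`, `T>A`,
#'   `T>C`, `T>G`). Need not sum to one.
#' @param loh_rate_per_het_site Per-generation probability that an ancestral
#'   heterozygous site is homozygosed by an LOH event.
#' @param deletion_fraction Fraction of LOH events that are hemizygous
#'   deletions (the rest are gene conversions).
#' @param tract_length_dist Tract-length distribution: a list with `name`
#'   (`"lognormal"`) and parameters `meanlog`, `sdlog`, `min`, `max` in
#'   bases. The default spans ~1 kb to 2.5 Mb.
#' @param mean_depth Mean sequencing depth per line.
#' @param depth_overdispersion Overdispersion of the negative-binomial depth
#'   model; per-site depth has variance `mean_depth * (1 +
#'   depth_overdispersion)`. Zero gives Poisson depth.
#' @param genotyping_error Probability that an emitted genotype call differs
#'   from the simulated genotype.
#'
#' @return An object of class `ma_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 2, chromosome_length = 2e5)
#' cfg$n_lines
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 5e5,
                       gc_content = 0.409,
                       gene_density = 20,
                       n_lines = 8L,
                       generations_per_line = 500L,
                       het_density = 0.0057,
                       het_indel_fraction = 0.05,
                       snm_rate = 2.23e-9,
                       indel_rate = 2.75e-10,
                       spectrum = c("C>A" = 186, "C>G" = 89, "C>T" = 497,
                                    "T>A" = 215, "T>C" = 332, "T>G" = 144),
                       loh_rate_per_het_site = 2.93e-5,
                       deletion_fraction = 8 / 48,
                       tract_length_dist = list(name = "lognormal",
                                                meanlog = log(5e4),
                                                sdlog = 1.1,
                                                min = 1e3, max = 2.5e6),
                       mean_depth = 80,
                       depth_overdispersion = 0.3,
                       genotyping_error = 1e-3) {
  assert_scalar_number(seed, "seed", 0, 2^31 - 1)
  assert_scalar_number(n_chromosomes, "n_chromosomes", 1)
  assert_scalar_number(chromosome_length, "chromosome_length", 100)
  assert_scalar_number(gc_content, "gc_content", 0, 1)
  assert_scalar_number(gene_density, "gene_density", 0)
  assert_scalar_number(n_lines, "n_lines", 1)
  assert_scalar_number(het_density, "het_density", 0, 1)
  assert_scalar_number(het_indel_fraction, "het_indel_fraction", 0, 1)
  assert_scalar_number(snm_rate, "snm_rate", 0)
  assert_scalar_number(indel_rate, "indel_rate", 0)
  assert_scalar_number(loh_rate_per_het_site, "loh_rate_per_het_site", 0)
  assert_scalar_number(deletion_fraction, "deletion_fraction", 0, 1)
  assert_scalar_number(mean_depth, "mean_depth", 1)
  assert_scalar_number(depth_overdispersion, "depth_overdispersion", 0)
  assert_scalar_number(genotyping_error, "genotyping_error", 0, 1)

  if (length(spectrum) != 6L)
    stopf("'spectrum' must have six substitution weights")
  if (is.null(names(spectrum))) names(spectrum) <- SIX_CLASSES
  if (!setequal(names(spectrum), SIX_CLASSES))
    stopf("'spectrum' names must be %s", paste(SIX_CLASSES, collapse = ", "))
  spectrum <- spectrum[SIX_CLASSES]
  if (any(spectrum < 0) || sum(spectrum) <= 0)
    stopf("'spectrum' weights must be nonnegative with a positive sum")

  generations_per_line <- as.integer(rep_len(generations_per_line, n_lines))
  if (any(generations_per_line < 1))
    stopf("all generation counts must be >= 1")

  if (!is.list(tract_length_dist) ||
      !identical(tract_length_dist$name, "lognormal"))
    stopf("'tract_length_dist' must be list(name = \"lognormal\", ...)")
  for (p in c("meanlog", "sdlog", "min", "max"))
    if (is.null(tract_length_dist[[p]]))
      stopf("'tract_length_dist' is missing parameter '%s'", p)

  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    gc_content = gc_content,
    gene_density = gene_density,
    n_lines = as.integer(n_lines),
    generations_per_line = generations_per_line,
    het_density = het_density,
    het_indel_fraction = het_indel_fraction,
    snm_rate = snm_rate,
    indel_rate = indel_rate,
    spectrum = spectrum,
    loh_rate_per_het_site = loh_rate_per_het_site,
    deletion_fraction = deletion_fraction,
    tract_length_dist = tract_length_dist,
    mean_depth = mean_depth,
    depth_overdispersion = depth_overdispersion,
    genotyping_error = genotyping_error
  ), class = "ma_sim_config")
}

#' @export
print.ma_sim_config <- function(x, ...) {
  cat(sprintf(
    "MA simulation config: %d x %s bp chromosomes, %d lines, %s generations\n",
    x$n_chromosomes, format(x$chromosome_length, big.mark = ","),
    x$n_lines, paste(unique(x$generations_per_line), collapse = "/")))
  cat(sprintf("  het density %.4g, SNM rate %.3g, indel rate %.3g, LOH rate %.3g\n",
              x$het_density, x$snm_rate, x$indel_rate, x$loh_rate_per_het_site))
  cat(sprintf("  depth %g (overdispersion %g), genotyping error %.3g, seed %d\n",
              x$mean_depth, x$depth_overdispersion, x$genotyping_error, x$seed))
  invisible(x)
}

line_names <- function(config) sprintf("L%02d", seq_len(config$n_lines))
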