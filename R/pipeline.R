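#' Assemble a pipeline configuration
#'
#' Either supply `simulate = sim_config(...)` to run end-to-end on
#' synthetic data, or the input paths `fasta`, `gff3`, `vcf`, `depth` (and
#' optionally `frequencies`) for real inputs. Filter thresholds and HMM
#' parameters default to [filter_config()] and [hmm_params()];
#' `generations` must name each line's generation count when running from
#' files.
#'
#' @param out_dir Output directory (created if missing).
#' @param simulate `NULL` or an [sim_config()].
#' @param fasta,gff3,vcf,depth,frequencies Input paths (ignored when
#'   simulating).
#' @param generations Named numeric vector of generations per line (file
#'   mode).
#' @param filter An [filter_config()].
#' @param hmm An [hmm_params()].
#' @param seed Seed for stochastic stages (the neutral simulation).
#' @param neutral_reps Replicates of the neutral impact simulation
#'   (0 disables it).
#' @return List of class `ma_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, fasta = NULL,
                            gff3 = NULL, vcf = NULL, depth = NULL,
                            frequencies = NULL, generations = NULL,
                            filter = filter_config(), hmm = hmm_params(),
                            seed = 1L, neutral_reps = 200L) {
  if (is.null(simulate)) {
    for (p in c(fasta, gff3, vcf, depth))
      if (is.null(p) || !file.exists(p))
        stopf("input path missing or nonexistent: %s",
              if (is.null(p)) "(NULL)" else p)
    if (is.null(generations))
      stopf("'generations' per line are required when running from files")
  } else stopifnot(inherits(simulate, "ma_sim_config"))
  structure(list(out_dir = out_dir, simulate = simulate, fasta = fasta,
                 gff3 = gff3, vcf = vcf, depth = depth,
                 frequencies = frequencies, generations = generations,
                 filter = filter, hmm = hmm, seed = as.integer(seed),
                 neutral_reps = as.integer(neutral_reps)),
            class = "ma_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields are passed to [pipeline_config()]; `simulate`, `filter`
#' and `hmm` sections are forwarded to [sim_config()], [filter_config()]
#' and [hmm_params()].
#'
#' @param path YAML file.
#' @return An `ma_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("simulate", "filter", "hmm"))]
  if (!is.null(y$simulate)) args$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$hmm)) args$hmm <- do.call(hmm_params, y$hmm)
  do.call(pipeline_config, args)
}

#' Run the whole MA analysis pipeline
#'
#' Sequences the stages mask -> filters -> ancestral inference -> de novo
#' calls -> rates and spectra -> LOH -> population comparison, writes
#' every intermediate table under `config$out_dir`, and returns (and
#' writes) a summary with all headline statistics and the inputs each
#' formula consumed. A stage failure halts the run with the stage name.
#' Identical seed and inputs give identical outputs.
#'
#' @param config An `ma_pipeline_config`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ma_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  op <- function(f) file.path(config$out_dir, f)

  popfreq <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_ma_experiment(config$simulate,
                                                    population = TRUE))
    ref <- sim$ref
    records <- sim$evidence
    depth <- evidence_depth(sim$evidence)
    exposures <- sim$evidence$exposures
    popfreq <- sim$popfreq
    stage("simulate", {
      write_reference(ref, op("reference.fa"), op("annotation.gff3"))
      write_variants(records, op("variants.vcf"))
      data.table::fwrite(sim$truth$planted_snms, op("truth_snms.tsv"),
                         sep = "\t")
      data.table::fwrite(sim$truth$planted_loh, op("truth_loh.tsv"),
                         sep = "\t")
    })
  } else {
    ref <- stage("reference", read_reference(config$fasta, config$gff3))
    records <- stage("variants", read_variants(config$vcf))
    depth <- stage("mask", read_depth(config$depth))
    if (!is.null(config$frequencies)) {
      popfreq <- data.table::fread(config$frequencies)
      data.table::setattr(popfreq, "class", c("ma_popfreq", class(popfreq)))
    }
    exposures <- NULL
  }

  mask <- stage("mask", build_callable_mask(
    depth, config$filter$min_depth, config$filter$max_depth))
  if (is.null(exposures)) {
    gens <- config$generations
    exposures <- data.table::data.table(
      line = names(gens), g = as.numeric(gens),
      n_callable = as.numeric(mask$n_callable[names(gens)]))
    gcf <- gc_fraction(ref)
    exposures[, `:=`(n_gc = n_callable * gcf, n_at = n_callable * (1 - gcf))]
  }

  filt <- stage("filter", apply_site_filters(records, config$filter))
  data.table::fwrite(filt$report$site_rules, op("filter_site_rules.tsv"),
                     sep = "\t")
  data.table::fwrite(filt$report$surviving, op("filter_surviving.tsv"),
                     sep = "\t")
  ancestral <- stage("ancestral", infer_ancestral(filt$records))
  calls <- stage("call", {
    cl <- call_mutations(ancestral, filt$records)
    cl <- group_mnms(cl)
    annotate_calls(cl, ref)
  })
  data.table::fwrite(calls, op("calls.tsv"), sep = "\t")

  res <- stage("rates", {
    snm <- rate_estimate(calls, exposures, "SNM")
    indel <- rate_estimate(calls, exposures, c("insertion", "deletion"))
    spec <- six_type_spectrum(calls, exposures)
    tri <- trinucleotide_spectrum(calls, ref)
    data.table::fwrite(snm$per_line, op("rates_snm.tsv"), sep = "\t")
    data.table::fwrite(spec$table, op("spectrum_six_type.tsv"), sep = "\t")
    data.table::fwrite(data.table::data.table(
      context = names(tri$counts), count = tri$counts),
      op("spectrum_96.tsv"), sep = "\t")
    list(snm = snm, indel = indel, spec = spec, tri = tri)
  })

  comp <- stage("compartments", {
    callable_frac <- mean(res$snm$per_line$n / genome_size(ref))
    exposure <- compartment_counts(ref) * callable_frac
    cr <- compartment_rates(calls, exposure)
    data.table::fwrite(cr$table, op("compartments.tsv"), sep = "\t")
    chrom_exp <- setNames(
      Biostrings::width(ref$seq) * callable_frac, names(ref$seq))
    unif <- if (length(ref$seq) >= 2)
      chromosome_uniformity(calls, chrom_exp) else NULL
    list(rates = cr, uniformity = unif)
  })

  neutral <- NULL
  if (config$neutral_reps > 0 && res$spec$n_snm > 0)
    neutral <- stage("neutral", neutral_impact_simulation(
      res$spec$n_snm, setNames(res$spec$table$count, res$spec$table$class),
      ref, reps = config$neutral_reps, seed = config$seed))

  loh <- stage("loh", {
    lo <- detect_loh_tracts(filt$records, ancestral, config$hmm, ref = ref)
    lo <- classify_mechanism(lo, depth)
    data.table::fwrite(lo$tracts, op("loh_tracts.tsv"), sep = "\t")
    write_loh_bed(lo, op("loh_tracts.bed"))
    lo
  })
  n_het_anc <- sum(ancestral$anc_gt == 1L, na.rm = TRUE)
  loh_rates <- if (n_het_anc > 0)
    loh_rate_table(loh, exposures, n_het_anc) else NULL
  if (!is.null(loh_rates)) {
    per_line <- merge(
      loh_rates$per_line,
      loh$tracts[, .(mean_length = mean(min_end - min_start + 1),
                     mean_sites = mean(n_sites)), by = line],
      by = "line", all.x = TRUE)
    data.table::fwrite(per_line, op("loh_lines.tsv"), sep = "\t")
  }

  overlap <- NULL
  if (!is.null(popfreq)) {
    overlap <- stage("compare", snm_overlap(calls, popfreq))
    data.table::fwrite(overlap, op("snm_overlap.tsv"), sep = "\t")
  }

  summary <- list(
    n_lines = length(filt$records$lines),
    calls = list(n_snm = sum(calls$class == "SNM"),
                 n_indel = sum(calls$class != "SNM"),
                 mnm = mnm_summary(calls)),
    snm_rate = res$snm[c("mean", "ci_low", "ci_high")],
    indel_rate = res$indel[c("mean", "ci_low", "ci_high")],
    ts_tv = res$spec$ts_tv,
    gc_equilibrium = res$spec$gc_equilibrium,
    u = res$spec$u, v = res$spec$v,
    chromosome_uniformity = comp$uniformity[c("chisq", "df", "p")],
    neutral_impact = if (!is.null(neutral)) neutral$summary,
    loh = list(n_tracts = nrow(loh$tracts),
               n_deletion = sum(loh$tracts$mechanism == "deletion"),
               n_conversion = sum(loh$tracts$mechanism == "conversion"),
               rate = loh_rates$experiment_rate),
    snm_overlap = overlap,
    filter_report = list(
      site_rules = filt$report$site_rules,
      genotype_rules = filt$report$genotype_rules),
    exposures = exposures,
    seed = config$seed)
  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(summary)
}

# BED (0-based half-open) with both spans per tract.
write_loh_bed <- function(loh, path) {
  tr <- loh$tracts
  if (!nrow(tr)) { writeLines(character(0), path); return(invisible(path)) }
  bed <- rbind(
    data.table::data.table(chrom = tr$chrom, start = tr$min_start - 1L,
                           end = tr$min_end,
                           name = sprintf("%s_min_%s", tr$line,
                                          tr$mechanism)),
    data.table::data.table(chrom = tr$chrom, start = tr$max_start - 1L,
                           end = tr$max_end,
                           name = sprintf("%s_max_%s", tr$line,
                                          tr$mechanism)))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
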