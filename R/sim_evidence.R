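ARTIFACT_CLASSES <- c("near_indel", "multiallelic", "low_maf", "low_depth",
                      "high_depth", "high_fs", "low_mqrs", "low_rprs",
                      "low_alt_reads", "imbalance")

#' Emit noisy multi-sample variant evidence for evolved MA lines
#'
#' Turns the true per-line genotypes into the kind of evidence a short-read
#' variant caller produces: one record per polymorphic site with per-line
#' genotype (GT), allele depths (AD) and total depth (DP), plus site-level
#' strand-bias (FS) and rank-sum annotations drawn from null distributions.
#' Depth is negative-binomial around `mean_depth` with the configured
#' overdispersion; heterozygous allele depths are binomial(DP, 0.5);
#' hemizygous-deletion tracts emit roughly half depth in the carrier line.
#' Genotype calls are flipped with probability `genotyping_error` (allele
#' depths still reflect the true state, as for a caller error).
#'
#' Optionally injects artifact sites that the filter stack must remove, one
#' class per hard-filter rule (see `artifacts`); injected artifacts are
#' false heterozygous calls in a single line and are recorded so tests can
#' verify each class is caught.
#'
#' @param lines An `ma_lines` object from [evolve_ma_lines()].
#' @param config The [sim_config()] used throughout.
#' @param ref The `ma_reference`.
#' @param artifacts `NULL`, or a named integer vector of counts per artifact
#'   class; names from
#'   `c("near_indel","multiallelic","low_maf","low_depth","high_depth",`
#'   `"high_fs","low_mqrs","low_rprs","low_alt_reads","imbalance")`.
#' @param min_depth,max_depth Depth bounds used to report per-line callable
#'   site totals (the rate denominators), inclusive.
#' @return An object of classes `ma_evidence` and `ma_records`: a list with
#'   `sites` (site-level table with `chrom`, `pos`, `ref`, `alt`, `fs`,
#'   `mqrs`, `rprs`), `geno` (long site-by-line table with `gt` coded
#'   0/1/2/NA, `ad_ref`, `ad_alt`, `dp`), `lines`, `exposures` (per-line
#'   generations and callable-site totals, split into G:C and A:T bases),
#'   and `artifact_truth`.
#' @export
emit_evidence <- function(lines, config, ref, artifacts = NULL,
                          min_depth = 20, max_depth = 300) {
  stopifnot(inherits(lines, "ma_lines"), inherits(config, "ma_sim_config"))
  with_seed(stage_seed(config$seed, "evidence"), {
    anc <- lines$ancestor
    ln <- lines$lines
    nl <- length(ln)

    sites <- data.table::rbindlist(list(
      data.table::data.table(chrom = anc$chrom, pos = anc$pos, ref = anc$ref,
                             alt = anc$alt, origin = "ancestral",
                             origin_line = NA_character_),
      data.table::data.table(chrom = lines$snms$chrom, pos = lines$snms$pos,
                             ref = lines$snms$ref, alt = lines$snms$alt,
                             origin = "snm", origin_line = lines$snms$line),
      data.table::data.table(chrom = lines$indels$chrom,
                             pos = lines$indels$pos,
                             ref = lines$indels$ref, alt = lines$indels$alt,
                             origin = "indel",
                             origin_line = lines$indels$line)))
    data.table::setorder(sites, chrom, pos)
    ns <- nrow(sites)

    # --- true genotypes, long format (site x line)
    geno <- data.table::data.table(
      chrom = rep(sites$chrom, each = nl),
      pos = rep(sites$pos, each = nl),
      line = rep(ln, times = ns),
      origin = rep(sites$origin, each = nl),
      origin_line = rep(sites$origin_line, each = nl))
    geno[, gt := ifelse(origin == "ancestral", 1L,
                        ifelse(line == origin_line, 1L, 0L))]
    geno[, deleted := FALSE]

    if (nrow(lines$loh_sites)) {
      loh <- lines$loh_sites[, .(chrom, pos, line, kept, mechanism)]
      geno[loh, on = c("chrom", "pos", "line"),
           `:=`(gt = ifelse(i.kept == "ref", 0L, 2L),
                deleted = i.mechanism == "deletion")]
    }

    # --- depth and allele depths from the true state
    size <- nb_size(config)
    mu <- ifelse(geno$deleted, config$mean_depth / 2, config$mean_depth)
    geno[, dp := draw_depth(.N, mu, size)]
    geno[, ad_alt := 0L]
    het <- which(geno$gt == 1L)
    geno$ad_alt[het] <- rbinom(length(het), geno$dp[het], 0.5)
    hom_alt <- which(geno$gt == 2L)
    geno$ad_alt[hom_alt] <- geno$dp[hom_alt]
    geno[, ad_ref := dp - ad_alt]

    # --- genotype-call errors (AD untouched)
    if (config$genotyping_error > 0) {
      err <- which(runif(nrow(geno)) < config$genotyping_error)
      if (length(err)) {
        old <- geno$gt[err]
        flip_het <- old == 1L
        new <- integer(length(err))
        new[flip_het] <- sample(c(0L, 2L), sum(flip_het), replace = TRUE)
        new[!flip_het] <- 1L
        geno$gt[err] <- new
      }
    }

    # --- site-level annotations (null draws; absent when no line is het)
    sites[, fs := round(rexp(ns, rate = 1 / 3), 3)]
    has_het <- geno[, any(gt == 1L), by = .(chrom, pos)]$V1
    sites[, mqrs := ifelse(has_het, round(rnorm(ns), 3), NA_real_)]
    sites[, rprs := ifelse(has_het, round(rnorm(ns), 3), NA_real_)]

    # --- artifact injection
    artifact_truth <- data.table::data.table(
      class = character(), chrom = character(), pos = integer(),
      line = character())
    if (!is.null(artifacts)) {
      inj <- inject_artifacts(artifacts, sites, config, ref, ln, size)
      sites <- rbind(sites, inj$sites)
      geno <- rbind(geno, inj$geno, fill = TRUE)
      artifact_truth <- inj$truth
      data.table::setorder(sites, chrom, pos)
    }
    data.table::setorder(geno, chrom, pos, line)
    geno[, c("origin", "origin_line", "deleted") := NULL]

    exposures <- callable_exposures(lines, config, ref, sites, geno,
                                    min_depth, max_depth)

    structure(list(sites = sites, geno = geno, lines = ln,
                   exposures = exposures, artifact_truth = artifact_truth),
              class = c("ma_evidence", "ma_records"))
  })
}

nb_size <- function(config) {
  if (config$depth_overdispersion <= 0) Inf
  else config$mean_depth / config$depth_overdispersion
}

draw_depth <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

# Per-line callable-site totals: exact at emitted sites, binomial for the
# rest of the genome under the site-iid depth law (half-depth over deleted
# tracts in the carrier line).  G:C vs A:T split uses the genome base
# composition.
callable_exposures <- function(lines, config, ref, sites, geno,
                               min_depth, max_depth) {
  L <- genome_size(ref)
  size <- nb_size(config)
  p_call <- function(mu) {
    if (is.infinite(size))
      stats::ppois(max_depth, mu) - stats::ppois(min_depth - 1, mu)
    else
      pnbinom(max_depth, size = size, mu = mu) -
        pnbinom(min_depth - 1, size = size, mu = mu)
  }
  p_full <- p_call(config$mean_depth)
  p_half <- p_call(config$mean_depth / 2)
  gcf <- gc_fraction(ref)

  del <- lines$loh_tracts[lines$loh_tracts$mechanism == "deletion"]
  out <- lapply(seq_along(lines$lines), function(li) {
    l <- lines$lines[li]
    g <- geno[line == l]
    n_emit <- sum(!is.na(g$dp) & g$dp >= min_depth & g$dp <= max_depth)
    t_del <- if (nrow(del)) sum(del$end[del$line == l] -
                                  del$start[del$line == l] + 1) else 0
    n_rest_full <- max(0, L - nrow(g) - t_del)
    n_call <- n_emit + rbinom(1, n_rest_full, p_full) +
      (if (t_del > 0) rbinom(1, t_del, p_half) else 0L)
    data.table::data.table(line = l,
                           g = config$generations_per_line[li],
                           n_callable = as.numeric(n_call),
                           n_gc = n_call * gcf,
                           n_at = n_call * (1 - gcf))
  })
  data.table::rbindlist(out)
}

# One injected site per artifact instance, each violating exactly one
# hard-filter rule; the false het is placed in one random line.
inject_artifacts <- function(artifacts, sites, config, ref, ln, size) {
  counts <- artifacts[ARTIFACT_CLASSES[ARTIFACT_CLASSES %in% names(artifacts)]]
  bad <- setdiff(names(artifacts), ARTIFACT_CLASSES)
  if (length(bad)) stopf("unknown artifact class(es): %s",
                         paste(bad, collapse = ", "))
  total <- sum(counts)
  s_l <- list(); g_l <- list(); t_l <- list()
  used <- paste(sites$chrom, sites$pos)
  chrom_len <- setNames(Biostrings::width(ref$seq), names(ref$seq))

  fresh_pos <- function(n, margin = 30L) {
    got <- 0L; out_c <- character(0); out_p <- integer(0)
    while (got < n) {
      ch <- sample(names(chrom_len), n, replace = TRUE)
      p <- as.integer(floor(runif(n, margin + 1, chrom_len[ch] - margin)))
      ok <- !(paste(ch, p) %in% used) & !duplicated(paste(ch, p))
      out_c <- c(out_c, ch[ok]); out_p <- c(out_p, p[ok])
      used <<- c(used, paste(ch[ok], p[ok]))
      got <- length(out_p)
    }
    list(chrom = out_c[seq_len(n)], pos = out_p[seq_len(n)])
  }

  norm_geno <- function(chrom, pos, focal, gt, ad_ref, ad_alt, dp) {
    g <- data.table::data.table(
      chrom = chrom, pos = pos, line = ln,
      gt = 0L, dp = draw_depth(length(ln), config$mean_depth, size))
    g[, ad_alt := 0L][, ad_ref := dp - ad_alt]
    i <- which(g$line == focal)
    g$gt[i] <- gt; g$ad_ref[i] <- ad_ref; g$ad_alt[i] <- ad_alt; g$dp[i] <- dp
    g
  }

  for (cls in names(counts)) {
    k <- counts[[cls]]
    if (k == 0) next
    for (i in seq_len(k)) {
      fp <- fresh_pos(1L)
      ch <- fp$chrom; p <- fp$pos
      focal <- sample(ln, 1)
      refb <- ref_base(ref, ch, p)
      altb <- BASES[((match(refb, BASES) - 1L + sample(1:3, 1)) %% 4L) + 1L]
      fs <- round(rexp(1, 1 / 3), 3); mq <- round(rnorm(1), 3)
      rp <- round(rnorm(1), 3)
      alt_field <- altb
      extra_site <- NULL; extra_geno <- NULL

      geno_row <- switch(cls,
        near_indel = {
          # companion ancestral-style het indel 10 bp away
          ip <- p + 10L
          iref <- ref_base(ref, ch, ip, width = 2L)
          ialt <- substr(iref, 1, 1)
          used <- c(used, paste(ch, ip))
          extra_site <- data.table::data.table(
            chrom = ch, pos = ip, ref = iref, alt = ialt,
            origin = "ancestral", origin_line = NA_character_,
            fs = round(rexp(1, 1 / 3), 3), mqrs = round(rnorm(1), 3),
            rprs = round(rnorm(1), 3))
          dpv <- draw_depth(length(ln), config$mean_depth, size)
          adl <- rbinom(length(ln), dpv, 0.5)
          extra_geno <- data.table::data.table(
            chrom = ch, pos = ip, line = ln, gt = 1L,
            ad_ref = dpv - adl, ad_alt = adl, dp = dpv)
          dp <- draw_depth(1, config$mean_depth, size)
          ada <- rbinom(1, dp, 0.5)
          norm_geno(ch, p, focal, 1L, dp - ada, ada, dp)
        },
        multiallelic = {
          alt_field <- paste(sample(setdiff(BASES, refb), 2), collapse = ",")
          dp <- draw_depth(1, config$mean_depth, size)
          ada <- rbinom(1, dp, 0.33)
          norm_geno(ch, p, focal, 1L, dp - ada, ada, dp)
        },
        low_maf = norm_geno(ch, p, focal, 1L, 72L, 8L, 80L),
        low_depth = norm_geno(ch, p, focal, 1L, 5L, 5L, 10L),
        high_depth = norm_geno(ch, p, focal, 1L, 200L, 200L, 400L),
        high_fs = {
          fs <- 80
          dp <- draw_depth(1, config$mean_depth, size)
          ada <- rbinom(1, dp, 0.5)
          norm_geno(ch, p, focal, 1L, dp - ada, ada, dp)
        },
        low_mqrs = {
          mq <- -15
          dp <- draw_depth(1, config$mean_depth, size)
          ada <- rbinom(1, dp, 0.5)
          norm_geno(ch, p, focal, 1L, dp - ada, ada, dp)
        },
        low_rprs = {
          rp <- -10
          dp <- draw_depth(1, config$mean_depth, size)
          ada <- rbinom(1, dp, 0.5)
          norm_geno(ch, p, focal, 1L, dp - ada, ada, dp)
        },
        low_alt_reads = norm_geno(ch, p, focal, 1L, 16L, 4L, 20L),
        imbalance = norm_geno(ch, p, focal, 1L, 62L, 18L, 80L))

      s_l[[length(s_l) + 1L]] <- data.table::data.table(
        chrom = ch, pos = p, ref = refb, alt = alt_field,
        origin = "artifact", origin_line = focal,
        fs = fs, mqrs = mq, rprs = rp)
      if (!is.null(extra_site)) s_l[[length(s_l) + 1L]] <- extra_site
      g_l[[length(g_l) + 1L]] <- geno_row
      if (!is.null(extra_geno)) g_l[[length(g_l) + 1L]] <- extra_geno
      t_l[[length(t_l) + 1L]] <- data.table::data.table(
        class = cls, chrom = ch, pos = p, line = focal)
    }
  }
  list(sites = data.table::rbindlist(s_l, use.names = TRUE),
       geno = data.table::rbindlist(g_l, use.names = TRUE),
       truth = data.table::rbindlist(t_l, use.names = TRUE))
}

#' Simulate population allele frequencies with seeded MA mutations
#'
#' Produces the minor-allele frequency table for two kinds of segregating
#' sites: random background SNPs and a configurable subset of the planted MA
#' mutations, seeded at minor-allele frequencies above a recoverable
#' threshold so compartment-stratified overlap can be verified against the
#' truth table.
#'
#' @param ref The `ma_reference`.
#' @param config The [sim_config()] object (its seed governs the draws).
#' @param truth An `ma_truth` object (from [evolve_ma_lines()]).
#' @param snp_density Fraction of genomic sites segregating as background
#'   SNPs.
#' @param seeded_fraction Fraction of planted SNMs seeded into the
#'   population.
#' @param seeded_maf Length-2 range of minor-allele frequencies for seeded
#'   SNMs.
#' @return A data.table of class `ma_popfreq` with columns `chrom`, `pos`,
#'   `major`, `minor`, `maf`; seeded truth rows carry `seeded = TRUE`.
#' @export
simulate_population_frequencies <- function(ref, config, truth,
                                            snp_density = 0.002,
                                            seeded_fraction = 0.3,
                                            seeded_maf = c(0.05, 0.3)) {
  stopifnot(inherits(truth, "ma_truth"))
  with_seed(stage_seed(config$seed, "population"), {
    snms <- truth$planted_snms
    seeded <- snms[0]
    if (nrow(snms) && seeded_fraction > 0) {
      n_seed <- round(seeded_fraction * nrow(snms))
      seeded <- snms[sample.int(nrow(snms), n_seed)]
    }
    seeded_dt <- data.table::data.table(
      chrom = seeded$chrom, pos = seeded$pos, major = seeded$ref,
      minor = seeded$alt,
      maf = runif(nrow(seeded), seeded_maf[1], seeded_maf[2]),
      seeded = TRUE)

    bg_l <- list()
    used <- paste(seeded_dt$chrom, seeded_dt$pos)
    for (ch in names(ref$seq)) {
      L <- Biostrings::width(ref$seq[ch])
      k <- rbinom(1, L, snp_density)
      if (k == 0) next
      pos <- sort(sample.int(L, k))
      keep <- !(paste(ch, pos) %in% used)
      pos <- pos[keep]
      major <- ref_base(ref, rep(ch, length(pos)), pos)
      minor <- BASES[((match(major, BASES) - 1L +
                         sample(1:3, length(pos), replace = TRUE)) %% 4L) + 1L]
      bg_l[[ch]] <- data.table::data.table(
        chrom = ch, pos = pos, major = major, minor = minor,
        maf = exp(runif(length(pos), log(0.005), log(0.5))),
        seeded = FALSE)
    }
    freqs <- data.table::rbindlist(c(bg_l, list(seeded_dt)))
    data.table::setorder(freqs, chrom, pos)
    data.table::setattr(freqs, "class", c("ma_popfreq", class(freqs)))
    freqs[]
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_reference()],
#' [simulate_ancestor()], [evolve_ma_lines()], [emit_evidence()] and
#' (optionally) [simulate_population_frequencies()] under one seed.
#'
#' @param config An [sim_config()] object.
#' @param artifacts Passed to [emit_evidence()].
#' @param population If `TRUE`, also simulate population frequencies.
#' @param ... Passed to [simulate_population_frequencies()].
#' @return A list with `ref`, `ancestor`, `lines`, `evidence`, `truth` and
#'   optionally `popfreq`.
#' @export
simulate_ma_experiment <- function(config, artifacts = NULL,
                                   population = FALSE, ...) {
  ref <- generate_reference(config)
  ancestor <- simulate_ancestor(config, ref)
  lines <- evolve_ma_lines(ancestor, config, ref)
  evidence <- emit_evidence(lines, config, ref, artifacts = artifacts)
  out <- list(ref = ref, ancestor = ancestor, lines = lines,
              evidence = evidence, truth = lines$truth)
  if (population)
    out$popfreq <- simulate_population_frequencies(ref, config,
                                                   lines$truth, ...)
  out
}

#' Depth track of an evidence object
#'
#' @param evidence An `ma_evidence` object.
#' @return A data.table with `chrom`, `pos`, `line`, `depth` (1-based
#'   positions), the tabular per-site depth track consumed by
#'   [build_callable_mask()] and [classify_mechanism()].
#' @export
evidence_depth <- function(evidence) {
  stopifnot(inherits(evidence, "ma_evidence"))
  evidence$geno[, .(chrom, pos, line, depth = dp)]
}
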