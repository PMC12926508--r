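#' Published per-line summaries of the Daphnia obtusa MA experiment
#'
#' Loads the bundled desk-scale summary tables of the D. obtusa
#' mutation-accumulation study this package's pipeline reproduces: the
#' per-line mutation harvest (generations, mean coverage, SNM and indel
#' counts, per-line rates), the six-type substitution spectrum with
#' conditional rates, and the per-line loss-of-heterozygosity summary.
#' These printed values serve as inputs for the arithmetic-level checks
#' (pooled rates, confidence intervals, Ts/Tv, equilibrium GC, corrected
#' rates, effective population size) that do not require raw sequence
#' data.
#'
#' @return A list of data.tables: `lines` (per-line SNM/indel counts and
#'   rates), `six_type` (six-class counts and conditional rates per site
#'   per generation), `loh` (per-line LOH events and rates).
#' @export
#' @examples
#' tabs <- ma_study_tables()
#' sum(tabs$lines$snm)   # 1463
ma_study_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mamut",
                                  mustWork = TRUE)
  list(
    lines = data.table::fread(path("dobtusa_ma_lines.tsv")),
    six_type = data.table::fread(path("dobtusa_six_type.tsv")),
    loh = data.table::fread(path("dobtusa_loh_lines.tsv"))
  )
}
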