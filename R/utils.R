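# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
STRONG <- c("G", "C")

COMPARTMENTS <- c("nonsynonymous", "synonymous", "UTR", "intron", "intergenic")

#' @importFrom stats rbinom rpois rnbinom rnorm rexp runif rlnorm setNames
#'   pbinom dbinom pnbinom qnorm qt sd chisq.test binom.test complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# Deterministic per-stage seed derived from the global experiment seed, so
# stages can be regenerated independently.  Kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 11L, ancestor = 23L, evolve = 37L,
               evidence = 53L, population = 71L, neutral = 89L,
               replicate = 101L)
  off <- offsets[[stage]]
  if (is.null(off)) off <- 7L + (sum(utf8ToInt(stage)) %% 997L)
  as.integer((as.numeric(seed) * 2654435L + off * 97L) %% 2147483647)
}

# Evaluate code under a derived seed without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

# Codon machinery -------------------------------------------------------------

CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES,
                          function(ab, c) paste0(ab, c)))
CODONS <- sort(CODONS)

codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc[CODONS]), CODONS)
})

STOP_CODONS <- names(codon_aa)[codon_aa == "*"]
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# Fraction of the three possible substitutions at each codon offset that are
# synonymous (Nei-Gojobori style site weights), as a 64 x 3 matrix.
SYN_FRAC <- local({
  m <- matrix(0, nrow = length(CODONS), ncol = 3,
              dimnames = list(CODONS, NULL))
  for (cod in CODONS) {
    aa <- codon_aa[[cod]]
    for (off in 1:3) {
      b <- substr(cod, off, off)
      alts <- setdiff(BASES, b)
      syn <- 0L
      for (a in alts) {
        alt <- cod
        substr(alt, off, off) <- a
        if (codon_aa[[alt]] == aa) syn <- syn + 1L
      }
      m[cod, off] <- syn / 3
    }
  }
  m
})

translate_codons <- function(codons) {
  aa <- codon_aa[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Strand collapse for substitution classes: returns pyrimidine-centred
# "C>T" style labels.
collapse_substitution <- function(ref, alt) {
  flip <- !(ref %in% PYRIMIDINES)
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  paste0(r, ">", a)
}

SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Table-style labels for the six classes (source base pair -> product pair).
six_class_label <- function(cls) {
  lab <- c("C>A" = "C:G>A:T", "C>G" = "C:G>G:C", "C>T" = "C:G>T:A",
           "T>A" = "A:T>T:A", "T>C" = "A:T>G:C", "T>G" = "A:T>C:G")
  unname(lab[cls])
}

is_transition <- function(cls) cls %in% c("C>T", "T>C")
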