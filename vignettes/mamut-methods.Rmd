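---
title: "Methods: mutation-accumulation analysis in mamut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-accumulation analysis in mamut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment this package analyses

A mutation-accumulation (MA) experiment propagates replicate lines of a
diploid, clonally reproducing organism (here modelled on *Daphnia*)
through repeated single-individual bottlenecks, so that drift overwhelms
selection and spontaneous mutations accumulate close to neutrally. After
hundreds of generations each line is deep-sequenced, variants are called
jointly across lines, and three classes of events are extracted:

* **de novo point mutations** (SNMs) and small indels, each unique to one
  line as a homozygous-to-heterozygous change;
* **loss-of-heterozygosity (LOH) tracts**, where an ancestrally
  heterozygous region became homozygous (gene conversion) or hemizygous
  (deletion);
* summaries of how these events distribute over substitution classes,
  trinucleotide contexts, genomic compartments and chromosomes.

`mamut` implements the full downstream analysis from a multi-sample
variant table, a reference with gene models, and per-site depth tracks
-- plus a synthetic generator that fabricates an entire experiment with
a planted-event truth table, so every stage is testable without any
sequencing data.

# Mutation rates

For each line, the per-site per-generation rate is
$\mu = x / (g \cdot 2n)$ where $x$ is the accepted mutation count, $g$
the number of MA generations and $n$ the line's callable sites (depth
within bounds); the factor 2 reflects that heterozygous mutations are
surveyed over both homologs of a diploid genome. The experiment-wide
rate is the unweighted mean of the per-line rates.

The confidence interval across $L$ lines defaults to the *t*-interval
on $L-1$ degrees of freedom, because MA experiments rarely have more
than a handful of lines ($L = 8$ here) and the normal approximation
under-covers at that size. `method = "normal"` (mean $\pm\,1.96\,$SE) is
retained because published MA summaries are reported that way; applied
to the study's per-line rates it reproduces the printed
1.70--2.76 $\times 10^{-9}$ bounds exactly.

Because purifying selection removes deleterious mutations even under MA
conditions, observed rates under-count mutations at constrained sites.
The correction
$\mu_c = f (1 + d)\,\mu + (1 - f)\,\mu$ inflates the raw rate for a
depleted class occupying fraction $f$ of the genome with fractional
deficit $d$ (`estimate_deficit()` computes $d = 1 - $ observed/reference
rate). With the study's constants ($f = 0.21$, $d = 0.47$ for
nonsynonymous sites; $f = 0.30$, $d = 0.71$ for exonic indels) the
corrected rates are the headline numbers the acceptance script
recomputes.

# Spectra and equilibrium GC

SNMs are strand-collapsed onto the pyrimidine-centred six classes;
conditional rates divide each class count by the summed diploid exposure
of its source base pair ($2 g \cdot n_{GC}$ or $2 g \cdot n_{AT}$ per
line), making classes comparable per source site. The 96-context
spectrum adds the 16 flanking-base combinations; calls at chromosome
edges are dropped with a tally. Equilibrium GC content is
$u/(u+v)$, with $u$ the A/T$\to$G/C and $v$ the G/C$\to$A/T conditional
rate sums -- the GC level at which gain and loss fluxes balance if base
composition is at mutational steady state. Applied to the printed
six-class rates of the study this arithmetic gives $\approx 0.326$; the
study prints 0.320, presumably from unrounded per-line inputs that are
not recoverable, so the package documents rather than reproduces that
value.

Impact annotation is a deliberately minimal SnpEff-style classifier:
coding SNMs are translated through their codon (strand-aware);
stop-gained/lost and start-lost are HIGH, missense MODERATE, silent
LOW, everything non-coding MODIFIER; coding indels are HIGH when their
length is not a multiple of three. Splice-site effects are not modelled
-- a documented simplification. The neutral expectation for the four
impact categories comes from placing the same number of SNMs uniformly
over the genome with substitution types drawn from the observed
spectrum *conditioned on the reference base* (so realized Ts/Tv matches
the observed ratio in expectation) and annotating them; 1,000
replicates give the mean and SD per category, and an unconditional mode
is available.

# The filter stack

Raw GATK-style records pass nine hard rules before any inference:
proximity to an indel (20 bp), multi-allelic exclusion, per-genotype
minor-read fraction $\ge 0.2$, depth within [20, 300] (both ends
inclusive -- the published wording "between 20 and 300" does not settle
inclusivity, so it is a documented, configurable default), Fisher
strand bias FS $\le 60$, rank-sum bounds (MQRankSum $\ge -12.5$,
ReadPosRankSum $\ge -8$; absent annotations pass, since they only exist
where both allele classes were observed), at least five alternate
reads, and an exact two-sided binomial test of the 1:1 allele balance.

The balance test's significance level is the one genuinely open
parameter. The default here is $\alpha = 0.001$: the screen exists to
catch collapsed paralogs and similar artifacts whose allele ratios are
grossly skewed, and a loose $\alpha$ discards a deterministic fraction
$\alpha$ of *genuine* heterozygous mutations -- biasing $\mu$ and every
derived quantity downward by that same fraction, measurably so against
the simulator's truth table. At $\alpha = 0.001$ the null loss
($\lesssim 0.1\%$) is far below Poisson counting noise. The parameter
is configurable and the test suite exercises $\alpha = 0.05$ as well.

Removals are tallied under the first failing rule in the order above;
the surviving *set* is order-independent because every rule is an
independent predicate on the input records.

# Calling de novo events

The ancestral genotype at each site is the genotype shared by at least
$L-1$ lines (generalizing the study's seven-of-eight rule); sites with
any missing genotype are conservatively uncallable. A mutation is
accepted iff exactly one line deviates, the deviation is ancestral-hom
$\to$ het, no other line carries even one read of the novel allele, the
site is callable in every line, and it lies more than 20 bp from any
surviving indel. Het$\to$hom changes feed the LOH module; hom$\to$hom
allele switches are rejected as artifacts. Indels use the same logic
with length $|\,|ref|-|alt|\,| \le 5$ bp. Same-line SNMs within 50 bp
chain into multinucleotide-mutation groups; members remain individual
SNMs in every count, and both the group count and the member count are
reported because published "event" counts are ambiguous between the
two.

# LOH detection and classification

Detection runs a two-state hidden Markov chain {RETAINED, LOH} over the
ordered ancestral heterozygous sites of each chromosome, with the focal
line's genotype calls as emissions. Defaults: entry probability
$10^{-6}$/site, exit $10^{-3}$/site, miscall rates 0.01 for both
emission directions, Viterbi decoding; decoded runs must span more than
1,000 bp (minimal span, first to last homozygous site), contain at
least 3 homozygous observations, and remain heterozygous in at least
90% of observations in *every* other line ("consistently heterozygous
in non-target lines"; the published criterion is not quantified, 90% is
the documented default). Missing observations are emission-neutral.
The published analysis used an external runs-of-homozygosity tool driven
by population allele frequencies; with the ancestral heterozygous set
known, frequencies add nothing, so the package substitutes this explicit
HMM while keeping the same acceptance surface (tract recovery on
simulated data).

The minimal span is the distance between the first and last homozygous
sites of a tract; the maximal span extends to one base inside the
nearest flanking site that stayed heterozygous in the focal line,
clipped to chromosome ends. The LOH rate is $x/(g \cdot n_{het})$ per
line ($x$ = homozygosed sites, $n_{het}$ = ancestral heterozygous
count), and the experiment-wide rate is the unweighted per-line mean
with zero-event lines contributing 0. Averaging the study's printed
per-line rates gives $\approx 3.03 \times 10^{-5}$ versus the printed
total $2.93 \times 10^{-5}$ (unrounded inputs unrecoverable); the
package implements the stated formula and documents the gap.

Mechanism classification standardizes each line's depth by its mean
callable-site depth. A tract is a heterozygous deletion iff the focal
line's standardized tract coverage is $\le 0.70$ of both flanks (50 kb
windows by default; the study does not state a window) and of the
genome-wide mean, while every other line keeps $\ge 0.80$ against the
same benchmarks; otherwise gene conversion. Tracts with depth missing
at more than half their sites stay unclassified. GC bias of conversion
is tested on strong/weak-informative converted sites (one G/C and one
A/T allele) with an exact two-sided binomial test against 0.5.

# Population comparison

Per-site diversity is $\pi = 2p(1-p)$ from the minor-allele frequency.
Gene-level $\pi_N/\pi_S$ uses Nei--Gojobori fractional site counting (a
coding position contributes the fraction of its three substitutions
that are silent as synonymous weight; the method is unstated in the
study, so this standard choice is documented and interchangeable), and
classifies each polymorphic coding site by the effect of its minor
allele. MA-mutation overlap with standing variation requires a
population site at the same position with minor-allele frequency
strictly above 0.02 and, by default, the identical alternate allele
(position-only matching is a flag, default off, because the published
wording does not settle it).

# The synthetic generator

The generator fabricates the full study: a reference at GC 0.409 with
gene models on both strands (codon-valid CDS, UTRs, introns), an
ancestor heterozygous at 0.57% of sites (5% of those short indel
polymorphisms -- the ancestral indel heterozygosity is not published;
this is a free parameter), eight lines evolved for ~500 generations
with Poisson-planted SNMs/indels at configurable rates and spectrum,
log-normal LOH tracts (default parameters span roughly 1 kb--2.5 Mb,
matching the observed span range) split between conversion and
deletion, and GATK-shaped evidence: negative-binomial depth
(variance $= \bar d(1+\phi)$, Poisson at $\phi = 0$), binomial(DP, 0.5)
allele depths at heterozygous sites, half depth over deleted tracts in
the carrier, null-distributed FS and rank-sum annotations, and optional
injected artifact sites that each violate exactly one filter rule.
A single global seed drives everything through per-stage derived seeds,
so any stage regenerates independently and reruns are byte-identical.

Two deliberate simplifications matter for interpreting test results.
First, depth is site-iid, so genome-wide callable totals per line are
drawn from the binomial distribution that per-site draws would imply,
while explicit depth-track rows cover every variant site; real coverage
is locally autocorrelated and mappability-structured, so real callable
fractions are more pessimistic than simulated ones. Second, planted
events never collide: point mutations are unique across lines (the
study's own "parallel mutations are extremely rare" assumption) and LOH
tracts never overlap across lines -- two lines homozygosing the same
region would drop those sites from the $\ge L-1$ consensus scaffold and
erase the evidence of both events, making the planted truth
unrecoverable by construction rather than by detector failure. Real
data can contain such coincidences; the pipeline then (correctly,
given its rules) reports neither event. The generator also does not
simulate reads, sequencing-error base calls, linkage structure in
population frequencies, or demography.

Passing recovery tests therefore demonstrates that the pipeline's
logic, thresholds and estimators are calibrated against the stated
evidence model -- not that real short-read artifacts (mapping error,
duplicated regions, batch structure) are handled; those enter only
through the filter annotations the pipeline consumes.

# Test and verification scales

The suite verifies desk-scale arithmetic directly against the bundled
per-line study tables, and properties on simulated experiments sized to
run on one CPU: a 2 x 200 kb fixture with elevated rates for unit-level
recovery (precision/recall $\ge 0.95$ on $> 1,000$ planted SNMs), a
20-replicate 8-line x 20 Mb x 500-generation experiment at planted
$\mu = 10^{-8}$ for CI coverage of the rate estimator (noise-free
genotype evidence, isolating estimator calibration), and a 6 Mb
experiment with ~24 planted tracts for LOH recovery and mechanism
classification at 80x depth. Elevated simulated rates shrink wall-clock
size without changing the estimators, whose calibration depends on
counts, not on the genome length per se.

# Known limitations

* The minimal impact annotator ignores splice sites and multi-isoform
  genes; HIGH-impact proportions are slight underestimates relative to
  a full annotator.
* Consensus-based ancestral inference discards sites polymorphic in
  more than one line, so regions rich in cross-line LOH lose callable
  heterozygous scaffold; boundary recovery degrades exactly there.
* Conversion vs crossover resolution is out of scope (short reads
  cannot phase the flanking exchange), as are aneuploidy and large CNVs
  beyond the hemizygous-deletion coverage signature.
* The indel proximity rule measures anchored-POS distance, which can
  differ by a base from allele-span distance for long deletions.
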