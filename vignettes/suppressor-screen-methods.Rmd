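---
title: "Methods: identifying and quantifying spontaneous suppressors in yeast strain cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and quantifying spontaneous suppressors in yeast strain cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supscan)
```

## The problem

A genetic suppressor is a secondary mutation that rescues the phenotypic
defect of a deleterious mutation. The screen this package supports isolates
spontaneous suppressors of temperature-sensitive (TS) alleles of essential
genes (SEC17, TAO3, GLN1) in genetically diverse budding-yeast isolates:
TS strains are grown at restrictive temperature, colonies that grow anyway
carry a suppressor, and whole-genome sequencing plus colony-size
quantification identify the responsible event and measure how strongly, and
how reproducibly across genetic backgrounds, it suppresses.

`supscan` implements the computational side of that design: the variant
filter chain that isolates candidate de novo suppressor mutations, a
read-depth aneuploidy caller corrected by measured ploidy, per-strain
explanation classes, colony-size fitness statistics, and RPKM expression
comparison — together with a synthetic-cohort generator that emulates the
breeding design and mutation structure so the whole pipeline can be run
and validated without any sequencing data.

## The breeding design and its 98% expectation

TS alleles are moved from the reference background into a natural isolate
by an initial cross followed by repeated backcrosses to the natural parent,
selecting a TS-carrying haploid segregant each round — six crosses in
total. Ignoring selection, each meiosis halves the donor fraction, so the
recurrent (natural) parent's genome fraction approaches
$1 - 2^{-6} = 98.4\%$.

`simulate_backcross_series()` models each meiosis with Poisson crossovers
per chromosome (no interference), with per-chromosome rates apportioning a
genome-wide map of 4,400 cM — the standard budding-yeast map length — by
physical length. The design itself only fixes the Mendelian halving; any
crossover model with the right per-chromosome expectation reproduces the
98% figure, and the Poisson/uniform choice is the simplest such model.
Selection at the TS locus is implemented by rejection-sampling the gamete
of the TS chromosome; because chromosomes segregate independently this is
exact. Selection causes linkage drag: donor sequence linked to the TS locus
survives the backcrosses, and the simulated mean recurrent fraction
(97.5% under the defaults) therefore sits slightly below the closed form.
Whether the design's quoted "98%" accounts for drag is not stated anywhere;
the simulator reports both numbers so either convention can be read off.

## The variant filter chain

Variants are consumed as per-strain VCFs (one record per ALT allele;
multiallelic sites are split; identity is chromosome, position, REF, ALT —
never quality or strain). Three filters isolate candidate de novo events:

1. **Quality**: records with Phred QUAL strictly below 200 are removed.
   Records with missing QUAL (`.`) are removed too and counted separately —
   a conservative reading, since a call without a quality cannot clear a
   quality threshold.
2. **Parental subtraction**: any identity present in a parental strain is
   removed. The default scope is *any* parental set supplied
   (`parental_scope = "any_parent"`), the natural reading of "present in
   one of the parental strains"; a matched-parent-only scope is selectable.
3. **Recurrence**: an identity observed in strictly more than 3 distinct
   suppressor strains is removed from every strain — independent
   spontaneous events are essentially never shared by that many isolates,
   so such calls are systematic artifacts. The count is taken cohort-wide
   over post-quality, post-parental records, mirroring the order in which
   the rules are stated; the first two filters commute, so only the
   recurrence count's base set depends on order, and the tests pin the
   implemented order (quality → parental → recurrence).

Survivors are annotated by a minimal single-transcript consequence model:
positions in no CDS are `intergenic` (UTR/intron subcategories are
deliberately not distinguished, matching how the screen reports its
classes); coding SNVs are classified by translating the affected codon
(standard nuclear code, strand-aware) into `synonymous`, `missense` or
`nonsense` (premature stop); indels overlapping a CDS are `frameshift`
when the length change is not a multiple of 3, else `inframe_indel`.
Stop-loss substitutions are folded into `missense`. Indels spanning a CDS
boundary are classified by their CDS-overlapping portion — a dialect
choice, documented here. The annotator is verified exhaustively against an
oracle that rebuilds and translates the full mutant protein for every
possible SNV of randomized toy genomes (both strands, spliced genes
included).

## Aneuploidy calling with ploidy correction

Read depth arrives as fixed 30-kb windows (the final partial window of a
chromosome is kept if at least half a window, else merged). Because the
relative depth shift caused by an extra chromosome depends on the base
ploidy — one extra copy is +100% in a haploid but +50% in a diploid — the
caller consumes an externally measured DNA content per strain
(flow-cytometry genome equivalents) and proceeds as:

* `relative_depth` = window depth / genome-wide **median** window depth.
  The median, not the mean, so the normalization is robust to the
  aneuploid fraction itself. Scale invariance is a tested property.
* `copy_estimate` = relative depth × base ploidy, where base ploidy is the
  DNA content rounded to the nearest integer. A clearly fractional content
  (e.g. 1.4) is an error: the screen treats strains as 1n or 2n, and a
  mosaic strain needs different methods.
* Segmentation assigns each window the integer its copy estimate rounds
  to, takes maximal same-integer runs, and merges runs shorter than
  `min_windows` (default 4, i.e. 120 kb) into the longer flanking run. A
  rounding/run-merging segmenter was chosen over an HMM or CBS because the
  expected signal is integer steps of half a ploidy unit or more —
  transparent, parameter-light and directly testable; the trade-off is
  that events shorter than 120 kb are invisible by construction.
* Segments departing from base ploidy become calls; per chromosome,
  deviant segments whose combined extent reaches `full_threshold`
  (default 0.90) are reported as one `full` chromosome call, otherwise as
  `segmental` calls, with direction gain or loss.

Mitochondrial contigs are excluded (nuclear genome only). Small
chromosomes can show inflated window-to-window dispersion (in real data,
variable capture of chromosomes I, III and VI during DNA isolation);
`flag_noisy()` flags chromosomes whose MAD of relative depth exceeds twice
the genome MAD, and calls confined to flagged chromosomes carry a
low-confidence annotation rather than being dropped. The thresholds
(`min_windows = 4`, `full_threshold = 0.90`, MAD factor 2) are this
package's own operational choices, exposed as parameters, since no
published threshold exists for declaring an aneuploidy from windowed
depth output.

## Explanation classes and candidate shortlisting

Each strain is placed in the 2×2 of (any nonsynonymous surviving SNP) ×
(any aneuploidy call): `euploid_snp`, `aneuploid_only`,
`snp_and_aneuploid`, or `unexplained` when neither signal survives.
"Nonsynonymous" means missense, nonsense, frameshift or inframe indel;
intergenic and synonymous survivors do not count. The classes are mutually
exclusive and exhaustive, so the counts always sum to the cohort size.

For aneuploid strains, candidate suppressor genes are the genes on the
called regions, ranked: the query gene first when it lies on the
aneuploidy (dosage suppression by the TS allele itself — the most common
mechanism in such screens), then genes with a recorded interaction with
the query (consumed as a pre-exported undirected edge list; no live
database access, for reproducibility), then the rest alphabetically. The
ranking deliberately encodes no more than those three tiers: finer
prioritization in a real screen is manual curation that cannot be encoded
faithfully.

## Colony-size statistics

Suppression strength is the **mean** fold increase in colony size of the
suppressor strain over its matched control (means for fold change;
medians only for wild-type normalization below — matching how such
measurements are reported). Significance is a **one-sided** Welch test
(suppressor > control; the biological hypothesis is directional, and a
reversed effect must never read as suppression), Bonferroni-corrected over
the whole analysis batch — all suppressor × background × condition tests
in the table. The batch-wide family is this package's operational choice;
the family definition is config-exposed because no published rule exists.
A cell is called *suppressed* only when both the adjusted p-value clears
α = 0.05 **and** the fold change exceeds `min_fold = 1`: significance and
effect size are reported separately in real screens, and the compound rule
is the package's explicit operationalization. A suppressor is *conserved*
when suppressed in every tested background, judged at the best condition
(largest fold change; ties broken by smaller adjusted p, then by condition
label) per suppressor × background.

For combined-overexpression experiments, colony sizes are first divided by
the **median** wild-type colony size of the same background, then all
pairwise group contrasts are tested with Tukey's HSD, reporting which
multi-gene combinations exceed which single-gene groups at adjusted
p < 0.05.

Rare oversized colonies in a control lawn may themselves be spontaneous
suppressors; no outlier trimming is applied by default, since whether to
exclude such escapees is a judgement call the analyst should make
explicitly.

## Expression comparison

Counts are normalized to RPKM
($\mathrm{count} / (\mathrm{length}/10^3) / (\mathrm{total}/10^6)$) with
the library size taken as the total of *counted* gene reads in that sample
— the ambiguity between all mapped reads and post-filter reads is resolved
in favour of the latter, and documented here. Between-strain comparison of
a gene uses mean RPKM over replicates, percent change of strain B relative
to strain A, and a two-sided equal-variance Student's t-test on replicate
RPKMs (Student, not Welch, for this comparison; technical replicates are
treated as independent observations, as is conventional for such panels —
with n = 3 the test is indicative, and the planted-effect recovery, not
the p-value, is what the validation asserts).

## The synthetic cohort: what it emulates, and what it does not

`emit_cohort()` generates a complete input bundle with recorded ground
truth:

* **Three natural isolates** at 0.40% / 0.59% / 0.69% divergence from the
  reference: substitution counts are binomial over the genome, positions
  uniform, so realized divergence matches its expectation within binomial
  error (a tested property).
* **Nine parental strains** (3 backgrounds × 3 TS queries): each carries
  the natural isolate's variants restricted to recurrent-parent ancestry
  blocks from a simulated 6-cross introgression, i.e. ~98% of them.
* **27 suppressor strains** in the classes 7 `euploid_snp` /
  16 `aneuploid_only` / 3 `snp_and_aneuploid` / 1 `unexplained`, with 23
  planted suppressor SNVs (5 intergenic, 6 nonsense, 2 frameshift, 10
  missense) and 22 aneuploidies (full chromosome duplications of the
  query-bearing chromosome, plus one terminal segmental duplication).
  Planted SNV qualities are drawn at or above Phred 200 and noise calls
  strictly below, so the quality filter is exercised at its boundary;
  contaminating classes are parental-background variants, sub-threshold
  noise calls, and recurrent artifacts present in more than 3 strains.
* **Depth tracks** at ~100× in 30-kb windows: per-window read counts are
  negative-binomial (squared CV ≈ 1/reads + 1/dispersion, dispersion 300),
  with dispersion inflated 3× on chromosomes I, III and VI to mimic the
  small-chromosome capture effect. Base ploidies are mostly 1n with a few
  2n strains so the ploidy correction is exercised.
* **Colony tables** with ~100 colonies per strain × condition: sizes are
  log-normal (CV ≈ 25%) around control mean × effect — log-normal keeps
  sizes positive and matches the right-skew of colony areas. Effects are
  planted > 1 for 11 suppressor genes in 4 backgrounds except SEC22 in
  UWOPS87-2421 (effect 1), so the planted conservation readout is 10 of 11.
* **Expression counts**: Poisson counts for every gene, 3 replicates per
  strain, with a planted 1.25-fold SEC22 increase in UWOPS87-2421.

Every file is deterministic (byte-identical) under a fixed seed, and each
generated quantity matches its generative expectation within Monte-Carlo
error — both tested properties.

What the generator does **not** emulate: raw reads and alignment artifacts
(mappability, GC bias), flow-cytometry histograms (ploidy is a number),
plate images (colony sizes are a table), linkage between planted SNVs and
ancestry blocks, and biological covariance between suppressor identity and
effect size. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated noise models, not that those
models capture every failure mode of real sequencing or plate data.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally (VCF convention); depth
  windows and bedGraph output are 0-based half-open, per that format.
* Welch tests require n ≥ 2 per sample and error on two zero-variance
  samples; the degenerate Student comparison of two zero-variance
  replicate sets reports the limiting p (1 when means are equal, else 0).
* Bonferroni caps at 1 and requires the family to be at least as large as
  the number of tests supplied.
* `best_condition` tie-breaks are total (fold, then adjusted p, then
  condition label) so results are order-independent.
* Filters preserve input order; every stage returns its removals, and the
  ledger identity (kept + removed = input) is asserted in tests.
* Demonstration problem sizes: the analysis scripts and the test suite run
  the cohort at 5–10% physical genome scale with windows scaled to match
  (the window *count* per chromosome, which is what the caller sees, is
  preserved); the backcross simulation and the acceptance script use the
  full 16-chromosome frame. These sizes are the package's choices for a
  quick, reproducible demonstration; nothing in the methods depends on
  them.

## Known limitations

* The consequence model is single-transcript, with no splice-site, UTR or
  regulatory categories; a real screen would follow up candidates with a
  full annotator.
* The aneuploidy caller reports integer copy numbers only; subclonal or
  mosaic events and events under 120 kb are out of scope.
* The conservation call inherits the arbitrariness of its compound rule
  (α and `min_fold`); both knobs are exposed rather than hidden.
* The recurrence filter's strain count is cohort-wide by default; if a
  cohort mixes query groups with very different sizes, the grouping flag
  should be considered.
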