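---
title: "Methods: diversity, inbreeding and mutation load in small populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, inbreeding and mutation load in small populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otterpg)
```

## Scope and model

`otterpg` implements the population-genomic workflow used in conservation
assessments of small, fragmented mammal populations: starting from a
multi-sample VCF of biallelic SNP genotypes, it quantifies genomic
diversity (individual heterozygosity, nucleotide diversity,
between-population divergence), population structure inputs (LD-thinned
SNP panels, PCA), inbreeding (runs of homozygosity and the genomic
inbreeding coefficient F~ROH~), and mutation load (outgroup-polarized
derived alleles in coding sequence, classified by functional consequence
and weighted by Grantham physicochemical distances). Each stage is an
exported function; `run_pipeline()` chains them with plain-file handoffs
so any stage can be re-run in isolation.

The intended sampling design is a handful of diploid genomes per
population (3–15), sequenced deeply enough that genotype-level filters
(depth, genotype quality) are meaningful, with one outgroup genome from a
sister species to orient ancestral vs. derived alleles.

## Site filtering

`filter_sites()` retains biallelic SNPs at which **every** sample has a
called genotype with DP > 10 and GQ > 20 (defaults). Three choices are
deliberate and documented because silent substitutes are common:

* the inequalities are strict (a genotype at exactly DP = 10 or GQ = 20
  fails);
* a missing DP or GQ FORMAT field fails the corresponding threshold
  (conservative: absence of evidence is not treated as passing);
* indel removal is allele-length based — any allele of length ≠ 1
  removes the record.

`allow_missing = TRUE` relaxes the no-missing rule and then applies the
thresholds to called genotypes only; it exists mainly so that sites whose
*outgroup* genotype is missing can still reach the polarization step,
where they are excluded as `unclassified` anyway (see below). VCF
coordinates are kept 1-based throughout the package; all interval
arithmetic is done on 1-based inclusive positions so there is a single
coordinate convention to reason about.

## Diversity statistics

Heterozygosity is reported as heterozygous genotypes per reference bp:
the denominator is the *fixed reference length* from the `genome_model`,
not the number of callable sites. This matches the field convention of
dividing by assembly span; a callable-sites denominator can be emulated by
setting `reference_length` accordingly.

Per-population diversity uses the frequency form of the mean pairwise
difference: per site $2\hat p(1-\hat p)\cdot\frac{2n}{2n-1}$, summed and
divided by the reference length. The $\tfrac{2n}{2n-1}$ correction (on by
default, `unbiased = FALSE` to disable) makes the statistic identical to
the average difference over all pairs of the $2n$ sampled haplotypes —
this identity is exercised against a brute-force pairwise loop in the
tests. Between populations,

$$d_{xy} = \tfrac{1}{L}\sum_s \left[p_A(1-p_B) + p_B(1-p_A)\right],
\qquad d_a = d_{xy} - \tfrac{\pi_A + \pi_B}{2},$$

and the $d_a$ identity holds to machine precision by construction.
$d_a$ may be negative from sampling noise and is not clipped.

Site frequency spectra are derived-allele histograms (requiring outgroup
polarization) or minor-allele (folded) histograms. Projection to a
smaller haploid size $m$ uses the hypergeometric expectation: a site with
derived count $k$ of $2n$ contributes $\Pr[\mathrm{Hyper}(j; k, 2n-k, m)]$
to bin $j$. Projection is linear and mass-conserving, and odd $m$ is
rejected because downstream diploid demographic tools expect even haploid
sizes.

## SNP thinning and PCA

`prune_variants()` applies, in a fixed order, (1) a minor-allele-frequency
filter (< 0.10 removed), (2) a pooled-sample Hardy–Weinberg exact test
(p < 0.1 removed), and (3) greedy windowed LD pruning (r² ≥ 0.2 within
20 kb windows sliding by 1 kb). The order is fixed because it changes the
retained count; it is recorded in the pipeline manifest. The HWE test is
the conditional exact test (enumeration of all heterozygote counts
compatible with the allele counts); a χ² variant is available via
`hwe_test = "chisq"`. r² is the squared Pearson correlation of dosage
vectors — phase is not required — and monomorphic pairs are defined as
r² = 0 so they can never trigger LD removal. Within a window sites are
scanned left to right and the *later* site of an offending pair is
removed; this tie-break is deterministic and the single-pass
implementation is tested for exact equality against explicit window
enumeration. The HWE test pools all samples; with strongly diverged
populations the Wahlund effect then removes some genuinely polymorphic
sites, which mirrors what pooled pre-structure filtering does in
practice.

PCA uses the drift-scale normalization: each site is centred at its mean
dosage and scaled by $\sqrt{2\hat p(1-\hat p)}$ before
eigendecomposition. All-monomorphic input is a degenerate-input error.

## Runs of homozygosity

`detect_roh()` follows the windowed scanning scheme of the standard
whole-genome ROH callers. A window of 20 consecutive SNPs is a *hit* if
it contains at most one heterozygote and at most one missing call; a SNP
is *eligible* if at least 1% of the windows covering it are hits; runs
are maximal stretches of consecutive eligible, called, homozygous SNPs
(any heterozygote breaks a run — the window tolerance applies to the
scanning stage only, which mirrors the scanning/validation split of the
original scheme; a run-level tolerance can be emulated by raising
`max_het_per_window` and lowering `window_hit_threshold`). Runs are split
at inter-SNP gaps above 1,000 kb and kept if they contain ≥ 20 SNPs, span
≥ 1,000 kb, and are no sparser than 50 kb per SNP. The two parameters not
usually reported alongside the six main ones (density, gap) default to
the common tool defaults and are exposed in `roh_params()`.

Segment length is measured SNP-to-SNP (`last − first + 1`), which biases
lengths slightly downward at low marker density; the synthetic-data tests
quantify this via boundary-tolerant recovery checks. Summaries per
individual are SROH (total kb in runs), NROH (count), LROH = SROH/NROH,
and F~ROH~ = SROH / effective autosomal genome size, the latter taken
from the `genome_model` (default: the summed autosome lengths).

## Mutation load

`annotate_effects()` reconstructs the affected codon for every biallelic
SNP inside an annotated CDS, respecting strand (alleles complemented,
codons read 5'→3' on the coding strand), translates with the standard
genetic code, and classifies changes as synonymous, nonsynonymous,
stop-gain or stop-loss. Loss of function is deliberately restricted to
stop gain/loss: with indels excluded upstream there are no frameshifts,
and splice annotation is out of scope. Transcripts whose CDS length is
not a multiple of 3 are skipped with a warning. Sites overlapping several
transcripts keep per-transcript calls, and `collapse_effects()` reduces
them to the most severe call per site for genome-level counting.

`polarize_alleles()` assigns ancestral state from one outgroup genome:
homozygous-reference outgroup ⇒ reference ancestral, homozygous-alternate
⇒ alternate ancestral, heterozygous or missing ⇒ `unclassified`, and
unclassified sites are excluded from all load counts. Because the
outgroup here is a sample inside the VCF, a missing outgroup call would
already have been removed by the strict site filter; the
`allow_missing = TRUE` filter mode keeps such sites so the exclusion
happens at polarization. The two routes yield identical load counts
(unclassified sites contribute nothing either way), which the tests
assert.

Per-genome load counts a site once when the individual carries at least
one derived allele (*carrier* counting, the default) or per derived copy
(`mode = "copies"`, heterozygote 1, homozygote 2). Nonsynonymous changes
carry the Grantham (1974) distance, bundled as a plain-text 20×20 table
and validated for symmetry at load; classes follow the conventional cut
points — conservative 0–50, moderate 51–100, radical > 100 — with
"putatively deleterious" meaning score > 50. Per genome the package
reports category counts, the nonsynonymous/synonymous ratio (missing, not
infinite, when no synonymous derived allele is present), the mean
Grantham score over carried nonsynonymous derived alleles, and the mean
and sum over the deleterious subset.

Two boundary notes: no amino-acid pair has Grantham score exactly 51, and
the only pair scoring exactly 100 (Phe/His) is not reachable by a single
nucleotide change, so synthetic fixtures exercise the class boundaries
with the reachable scores 50 (Val→Phe, conservative) and 101 (Arg→Trp,
radical), while the classifier itself is tested at the exact integers
50/51/100/101.

## Group comparisons

`anova_oneway()` and `tukey_kramer()` implement the one-way ANOVA and the
Tukey–Kramer HSD for unequal group sizes from their sum-of-squares
definitions, with studentized-range tail probabilities from R's `ptukey`
(accurate to well below 1e-4). Group summaries are reported as mean ± SE
with SE = SD/√n. The degenerate all-constant case returns F = 0, p = 1.
The tests compare against `stats::aov()`/`stats::TukeyHSD()` as an
independent reference and calibrate the family-wise error rate on a
simulated null (three groups of 10, 10,000 replicates), requiring the
empirical rate to sit in [0.04, 0.06] at α = 0.05.

## The synthetic cohort generator

`simulate_cohort()` emits a complete input set — VCF, reference FASTA,
GFF3, population map, genome model — plus the planted truth, so every
stage can be validated without external data. Its defaults describe the
study conditions the package targets:

* three populations of 13, 4 and 3 individuals plus one outgroup genome,
  the cohort shape typical of opportunistically sampled small
  populations;
* two 10-Mb autosomes and a 1-Mb sex chromosome (the genome model scales
  the statistics, not the mechanics; these sizes keep a full run in tens
  of seconds while leaving thousands of SNPs per window-analysis unit);
* background sites drawn from a shared ancestral frequency
  (uniform on 0.05–0.95) perturbed per population by a uniform
  ±0.2 drift, giving pairwise differentiation around F~st~ ≈ 0.05; the
  site count is chosen so expected per-bp heterozygosity is near 1×10⁻³;
* Hardy–Weinberg genotypes within population, except inside planted
  autozygous tracts where the genotype is forced homozygous for a single
  sampled haplotype; the default plan plants one 2-Mb tract (10% of the
  autosomes — the F~ROH~ recovery case) and three tracts of 1.5–1.8 Mb;
* synthetic two-exon genes (half on the minus strand) carrying planted
  coding variants: synonymous, nonsynonymous with Grantham scores
  spanning 5–215 including both reachable class boundaries, stop gains,
  stop losses, and sites whose outgroup call is heterozygous or missing
  to exercise the unclassified path;
* a violation plan of sites that must fail the filter: DP exactly 10, GQ
  exactly 20, missing genotypes, multiallelic records, indels.

The generator is deterministic given `seed` (byte-identical files) and
returns closed-form expectations implied by the planted frequencies
(per-individual heterozygosity, per-population π — including the small
exact correction for tract-forced duplicated haplotypes — and pairwise
d~xy~/d~a~). Test tolerances are derived from the design: binomial SDs
for heterozygosity, and parametric replicates of the exact sampling
design for π and d~xy~ (3-SE bands).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium decay (sites are
drawn independently, so LD pruning is exercised via planted duplicated
haplotype blocks in fixtures rather than a recombination landscape),
mutation-model realism (no transition/transversion structure), genotype
error correlated with depth, reference bias, and any demographic history
beyond a one-parameter frequency drift. The estimators under test do not
depend on these features; inferences that do (demographic
reconstruction, ancestry model fitting) are out of scope and only their
input files are produced.

## Numerical and design choices

* Coordinates: 1-based inclusive everywhere (VCF convention); no internal
  0-based representation survives outside single functions.
* The exact HWE p-value accumulates all tables with probability ≤ the
  observed one, with a 1+1e-12 relative guard against floating-point ties.
* r² comparisons use a 1e-12 guard on the ≥ threshold; eligibility
  fractions in the ROH scan likewise.
* `sum_grantham_deleterious` uses carrier weights by default so that the
  generator's truth bookkeeping and the pipeline count the same thing;
  copy weighting is a flag.
* Problem sizes in the shipped tests: the default 21-Mb/~60k-site cohort
  for end-to-end checks, a 4.5-Mb/6k-site cohort for file-format and
  determinism checks, ≤ 500-SNP chromosomes for exhaustive ROH oracle
  equivalence, and 840 sites (one per 25 kb) for sparse-map ROH recovery.
  These sizes were chosen to make the full validation suite convenient to
  run routinely while keeping every planted signal (tract length vs.
  window span, SNP counts per run) comfortably above its detection
  threshold.

## Known limitations

* The ROH caller assumes sorted, deduplicated sites and diploid calls; it
  does not model genotyping error inside runs beyond the window
  heterozygote tolerance.
* The HWE filter pools samples across populations (no per-population
  stratification option yet).
* `read_vcf()` loads the cohort into memory; genomes in the hundreds of
  millions of SNP records would need chunked reading.
* Effect annotation handles point substitutions in annotated CDS only:
  no splice-site, UTR or frameshift consequences, by design.
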