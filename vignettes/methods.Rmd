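---
title: "Methods: two-population sweep scans, SNV triage and convergence detection"
author: "alksweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population sweep scans, SNV triage and convergence detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alksweep)
```

## The scientific problem

A fish population that colonised an extremely alkaline lake must survive
chronic bicarbonate/carbonate stress, impaired ammonia excretion and hypoxia.
Strong recent selection on the alleles that permit this leaves three
population-genomic signatures relative to conspecific freshwater populations:
locally **elevated differentiation** (F~st~), **depressed nucleotide
diversity** in the selected population (a negative log~2~ π ratio), and a
**skew toward rare variants** (negative Tajima's *D*). At the single-variant
level, the causal and hitchhiking sites appear as near-fixed differences —
high F~st~ with a near-zero minor-allele frequency in the alkaline panel —
and, at the protein level, the same adaptive substitutions can recur in other
independently alkaline-adapted lineages (convergence).

`alksweep` implements this analysis chain for a two-population contrast
labelled **ALK** (alkaline) and **FW** (freshwater): windowed scans, outlier
region calling with gene assignment and fine mapping, highly differentiated
SNV triage with coding-effect annotation, population consensus proteins, and
convergent-column detection in ortholog alignments.

## Estimators

**F~st~.** We use the Weir & Cockerham (1984) variance-component estimator,
the convention of the standard VCF toolchains. For each biallelic site, with
$n_i$ called diploids, alt frequency $p_i$ and observed heterozygote
proportion $h_i$ in population $i \in \{ALK, FW\}$, the among-population
($a$), among-individual ($b$) and within-individual ($c$) components give
$\hat\theta = a/(a+b+c)$. A site is `NA` when monomorphic in both populations
($a+b+c=0$) or when fewer than two diploids are called in either population.
Windowed F~st~ is the **ratio of sums** $\sum a / \sum (a+b+c)$ — the
weighted estimator, which we verified recovers the simulated divergence
parameter essentially unbiasedly, whereas the mean of per-site ratios is
biased downward by Jensen's inequality (at simulated $F = 0.2$ the per-site
mean is ≈ 0.15). Whether a windowed scan should average sites or sum
components is genuinely open in the literature; ratio-of-sums is the
defensible default and the one implemented.

**π.** Per-site unbiased pairwise diversity $2p(1-p)\,n/(n-1)$ with $n$ the
called chromosomes at the site, summed over a window and divided by the
**full window span** in bp (not callable sites), matching the most common
windowed-π convention. Sites with $n < 2$ are skipped; sites fixed within a
population contribute zero.

**log~2~ π ratio.** $\log_2(\pi_{ALK}/\pi_{FW})$, so alkaline diversity loss
is negative. A window with zero diversity on either side would be undefined;
we substitute the smallest nonzero per-bp π observed in the scan (a data-driven
pseudo-floor rather than an arbitrary constant) and flag the window
(`pi_floored`), so downstream consumers can drop or inspect flagged windows.
Outlier selection uses |log~2~ ratio| (two-sided) by default, as a published
scan of this design did; `one_sided_ratio = TRUE` restricts to ALK-depleted
windows.

**Tajima's D.** The 1989 statistic
$D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard constants
from the sample size, where $\hat\pi$ is the *sum* of per-site pairwise
diversity (not per-bp). Missing data make the per-site sample size vary
within a window; the constants are computed from the **modal**
called-chromosome count (ties resolved toward the larger), and sites whose
call count deviates from the mode by more than 20% are excluded from both $S$
and $\hat\pi$. This keeps the constants and the site set mutually consistent;
at the default 2% missingness the exclusion is rarely triggered. $D$ is `NA`
for $S = 0$ or fewer than 4 chromosomes.

**Diversity comparison.** Per-chromosome mean π of the two populations is
compared with a paired two-sided *t*-test (`stats::t.test`). Zero-variance
differences are degenerate: identical vectors return $t = 0, P = 1$;
constant nonzero differences return `NA` with a `degenerate` flag rather
than an infinite statistic.

## Scan design

Windows are 0-based half-open, starting at multiples of the step (defaults:
20 kb window, 10 kb step; fine mapping at 10 kb with step = window). The
final partial window of each chromosome is kept and flagged. VCF positions
stay 1-based; the two coordinate systems meet only in interval-overlap
queries, performed once.

Outlier selection is **rank-based**: the top `ceiling(top_fraction * N)`
non-`NA` windows per criterion, with the reported threshold equal to the
minimum selected value. This reproduces a "top 1%" rule literally and avoids
percentile-interpolation dialects; the thresholds a scan prints are therefore
outputs of the data, not tunable constants. Fixed thresholds (`fst_min`,
`abs_log2_ratio_min`, strict inequalities) override the rank rule when set,
and fewer than 100 usable windows in percentile mode is an error that advises
them. Selected windows are merged when overlapping or book-ended (`max_gap`
defaults to 0); region criteria are the union over member windows and peaks
are member maxima; merging is idempotent. Genes are assigned to regions by
≥ 1 bp overlap of the gene span. Fine maps pad one fine window on each side
of a region so edge signals remain visible.

## SNV triage and coding effects

Two presets mirror the two filters a study of this design applies: preset A
(`"ca15"`): F~st~ > 0.9 **and** MAF~ALK~ < 0.1 (strict, as printed); preset B
(`"rhcg"`): F~st~ > 0.8 within CDS. Variants with `NA` statistics never pass.
Triage is monotone by construction: raising `fst_min` or lowering
`maf_alk_max` can only remove variants (property-tested on random
configurations).

Coding effects map a variant through the gene model's CDS segments in
transcription order, complementing alleles on minus-strand genes, rebuilding
the codon and translating with the standard nuclear code. The GFF3 `phase`
attribute is **trusted** over recomputation from cumulative lengths (a
mismatch warns), because annotation pipelines occasionally emit
non-canonical phases deliberately. Indels are classed `frameshift` /
`inframe_indel` by the mod-3 rule and never given amino-acid substitutions;
variants crossing a CDS boundary (or hitting an incomplete codon) are
`splice_unknown`; in-gene, out-of-CDS variants are `noncoding` (UTRs are not
distinguished unless annotated). One effect row is emitted per overlapping
gene. Correctness is checked two ways: a strand-symmetry property (mirroring
the genome and model leaves every amino-acid call unchanged) and a
whole-protein oracle (every `nonsynonymous` call must change exactly one
residue of the full translated CDS, at the reported codon).

## Convergence rule

Population consensus proteins are built by applying each population's major
allele (> 0.5 of called chromosomes; exact ties resolve to the reference and
are logged) at the triaged sites to the reference CDS and translating;
premature stops truncate with a warning. In the labelled ortholog alignment,
a column is *differentiating* iff the two focal consensus residues differ
(both non-gap) and *convergent* iff additionally (i) ≥ 1 alkaline-adapted
lineage carries the focal-ALK residue and (ii) **every** non-gap freshwater
reference carries the focal-FW residue. Strict rule (ii) reflects the
observation motivating this analysis — a freshwater-resident relative
retained the freshwater residue at the convergent sites — and a
majority-rule relaxation is available as an option. Columns where a focal
sequence is gapped are skipped; gapped non-focal sequences are ignored only
for the rules they would enter. Detection is invariant to row order and
renaming, which is property-tested.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` defines the study conditions used throughout the tests: 2
chromosomes × 500 kb, SNP density 1/200 bp, 30 + 30 diploids, 2% missing
genotypes, background divergence $F = 0.05$, and per chromosome two 40 kb
sweep intervals in which the ALK allele frequencies are drawn at $F = 0.6$
and pushed toward fixation by scaling their distance from the nearer fixation
point by 0.1 (a 10× diversity loss). Frequencies follow the
**Balding–Nichols** model: ancestral $p \sim U(0.05, 0.95)$ and population
frequencies $\sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, clipped to
$[0.001, 0.999]$ so realized monomorphic sites occur (exercising `NA` paths)
without flooding the scan. Genotypes are independent $\mathrm{Binomial}(2,p)$
draws. Twenty genes (2–3 exons, both strands, canonical start/stop, correct
phases) are written into the genome; two designated genes — a "ca15-like"
gene inside a chr1 sweep and a minus-strand "rhcg-like" gene inside a chr2
sweep — carry the planted variants: 5 nonsynonymous (one forced to the
canonical GAA→GAC, Glu→Asp) + 1 synonymous + two 2-bp frameshift deletions
in the former, 5 nonsynonymous in the latter, all with ALK alt frequency
exactly 1 and FW exactly 0 so they pass preset A by construction and the
truth manifest's pass labels are deterministic; plus 4 intergenic ALK-fixed
SNVs and 2 intermediate-frequency negative controls. A companion ortholog
alignment plants 7 differentiating columns of which 2 are convergent, with
one planted freshwater-inconsistency control. All stages draw from sub-seeds
split from one master seed, so fixtures are byte-reproducible piecewise and
end to end.

Deliberate simplifications: sites are **unlinked** (no LD, no hitchhiking
structure within windows — windows aggregate independent sites), demography
is constant-size (no bottlenecks or expansions), mutation rate is uniform,
and the designated genes carry *only* planted variants so that their triaged
content is fully determined by the manifest. Passing tests therefore
demonstrate estimator and pipeline correctness under controlled allele
frequency structure, not robustness to linkage, demographic
non-stationarity, or annotation noise in real data.

Two generator settings deserve explanation:

* **Outlier fraction at fixture scale.** The planted sweeps occupy 16% of the
  fixture genome (12 of 100 coarse windows lie fully inside them), so a scan
  of the fixture uses `top_fraction = 0.12` — the planted prevalence — rather
  than the 1% default that suits a whole genome where sweeps are rare. This
  is recorded in the config (`scan_top_fraction`) and chosen from the design,
  not fitted to any test outcome.
* **Neutral SFS for Tajima's D.** Uniform ancestral frequencies do *not*
  produce a neutral site-frequency spectrum, so Balding–Nichols draws cannot
  calibrate $D$. `simulate_neutral_sfs()` samples derived-allele counts with
  $P(i) \propto 1/i$, the constant-size neutral expectation, under which
  $E[\hat\pi] = E[S/a_1]$ holds exactly; the calibration tests confirm mean
  $D \approx 0$ there.

**Triage exactness and swept backgrounds.** Under the sweep conditions,
random background sites inside sweep intervals *legitimately* reach
F~st~ > 0.9 with MAF~ALK~ < 0.1 — a sweep fixing variants is precisely the
simulated biology. Genome-wide "recovered = planted" exactness is therefore
checked on a sweep-free configuration (`sweeps_per_chrom = 0`), where a
background pass would require a > 6σ frequency divergence at $F = 0.05$ and
effectively never occurs; on the default swept fixture, exactness is checked
restricted to the designated genes, the same restriction the motivating
study's triage applied to its carbonic-anhydrase gene set.

## Numerical and interface choices

* Estimator preconditions return `NA` rather than raising, and `NA`s are
  excluded from percentile ranking; errors are reserved for configuration
  mistakes (unmapped samples, malformed GT, unsorted VCF, reference
  mismatches — the last reported with chromosome and position).
* Multi-allelic records default to recoding onto the two most frequent
  alleles (count-ranked, ties toward the lower index); genotypes carrying a
  dropped allele become wholly missing, preserving the even-allele-count
  invariant. `multiallelic = "skip"` drops such records instead.
* Half-called diploid genotypes are treated as fully missing.
* Site filtering (biallelic handling, max-missingness 0.2, minor-allele
  count ≥ 1) is configurable and every rule can be disabled; the defaults are
  stand-ins for an upstream "strict low-quality filter" whose exact flags are
  typically unreported.
* The longest-CDS transcript represents each gene; transcript selection is
  rarely reported in scan studies and this is the common default.
* All tabular artifacts are TSV with `NA` spelled `NA`; regions are
  BED-compatible 0-based half-open; JSON reports carry thresholds and gene
  lists. Analysis functions are pure: identical inputs give byte-identical
  artifacts.
* Problem sizes in the shipped tests and acceptance script (500 random
  oracle instances, 5,000-site recovery panels, 300 calibration windows, 10
  fixture seeds) were chosen so the whole validation runs in about two
  minutes on a single CPU while keeping Monte-Carlo error well inside the
  asserted tolerances.

## Known limitations

Haplotype-based sweep statistics (iHS, XP-EHH), recombination-rate
estimation, demographic inference, enrichment analysis and alignment
construction are out of scope — alignments are inputs, and candidate genes
are assigned by annotation overlap, not sequence search. The convergence
rule is consensus-based and does not reconstruct ancestral states, so it
detects shared derived residues, not formally polarized convergent events.
Because the generator plants unlinked sites, window statistics on real data
(where linkage correlates neighbouring windows) will be noisier than the
fixture suggests; thresholds should always be taken from the empirical
distribution of the data at hand, which is what the rank-based rule does.
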