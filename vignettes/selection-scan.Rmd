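---
title: "Windowed selective-sweep scans with sweepscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed selective-sweep scans with sweepscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a population colonizes a new environment — high altitude being the
classic example — beneficial alleles can rise rapidly to fixation.  Such a
selective sweep leaves two local signatures in genome-wide resequencing
data: reduced nucleotide diversity in the selected population and elevated
allele-frequency differentiation against related populations that did not
experience the selection.  `sweepscan` implements the standard
two-statistic scan for this situation: it computes windowed diversity and
differentiation statistics between a focal ("highland") group and a pooled
reference ("lowland") group, and calls sweep candidates as windows in the
joint upper tail of both distributions.  Everything downstream of genotype
calling is covered — read-level QC, site filtering, the windowed
estimators, outlier calling, region merging, gene annotation, targeted
per-gene contrasts, gene-set enrichment, and population-structure
summaries (neighbor-joining tree, PCA) — together with a synthetic-data
generator so that the whole pipeline is testable end to end without any
external download.

# Statistics

All estimators operate on diploid biallelic SNP genotypes coded as
alternate-allele counts (0/1/2, `NA` missing), with 0-based half-open
genomic intervals throughout (VCF positions are converted on input and
output).

**Nucleotide diversity.** At a site with $m$ called alleles of which $k$
are the alternate allele, the mean pairwise difference is
$\pi = k(m-k)/\binom{m}{2}$.  Window values are sums over sites, divided
by the full window span for per-bp values.  Normalizing by span rather
than by callable sites is the convention of most windowed pipelines; it
biases $\pi$ downward where callability varies, which cancels in the
diversity *ratio* that the scan actually thresholds (both groups share
the window span), and is flagged as a limitation for absolute values.

**Watterson's estimator and Tajima's D.** With $S$ segregating sites in a
sample of $n$ sequences, $\hat\theta_W = S/a_1$ with
$a_1=\sum_{i=1}^{n-1} 1/i$, and
$$D = \frac{\pi_{\rm sum} - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}$$
with the usual constants $a_2, b_1, b_2, c_1, c_2, e_1, e_2$ derived from
$n$.  $D$ is undefined (returned as `NA`) for $S=0$, $n<4$, or a
non-positive variance term.  With missing data $n$ varies by site; per
window we use the mean called allele count over the window's SNPs,
rounded down — simpler and more stable than the minimum, which a single
badly-called site would dominate.

**F\_ST.** The paper-trail for scans of this kind rarely states the
estimator, so both standard sample-based estimators are provided and the
scan takes a configurable choice. The default is Hudson's ratio-of-sums
estimator (numerator $(p_1-p_2)^2 - p_1(1-p_1)/(m_1-1) -
p_2(1-p_2)/(m_2-1)$, denominator $p_1(1-p_2)+p_2(1-p_1)$, summed over
sites before dividing), recommended for unequal sample sizes.  The
Weir–Cockerham (1984) $\hat\theta$ from the $a,b,c$ variance components
is the alternative.  Negative estimates are reported raw, never clipped;
quantile thresholds operate on raw values.

**Windows.** Windows start at $0, s, 2s, \dots$ while the start lies
before the chromosome end; trailing windows are truncated at the
chromosome end.  Defaults are 100-kb windows sliding in 10-kb steps for
the genome scan and a 10-kb tiling for the targeted per-gene analysis.

# The joint outlier scan

Per window the scan records $F_{ST}$ (focal vs pooled reference) and the
diversity ratio $\pi_{\rm low}/\pi_{\rm high}$, whose large values mean
diversity loss in the focal group.  Thresholds are the empirical 95th
percentiles (type-7, linear interpolation — R's default; the choice is
immaterial beyond ties) of each statistic over windows where both are
defined; windows at or above *both* thresholds are selected (ties
inclusive).  Windows with $\pi_{\rm high}=0$ have an undefined ratio;
they are excluded from quantile computation but reported.  Selected
windows sharing at least 1 bp are merged into maximal disjoint regions
(abutting windows are not merged); genes overlapping a region by at
least 1 bp under half-open coordinates form the selected gene set.

The reference group pools the lowland populations rather than averaging
per-population statistics, matching the one-versus-rest contrast the
scan is designed for.  By symmetry, swapping the groups inverts the
ratio and leaves $F_{ST}$ unchanged.

**Enrichment.** For each gene category, with $n$ selected genes of which
$k$ fall in a category containing $K$ of the $N$ background genes, the
raw p-value is the upper-tail binomial probability $P(X \ge k)$,
$X \sim \mathrm{Bin}(n, K/N)$; $k=0$ gives $p=1$.  Benjamini–Hochberg
adjustment is applied across categories (the generic "FDR correction" of
enrichment pipelines), significant at $q<0.05$.  The background universe
is the full supplied annotation.

**Targeted contrasts.** Candidate genes are profiled at 10-kb resolution
and their mean $F_{ST}$, diversity ratio and Tajima's-D difference
($D_{\rm low}-D_{\rm high}$) are compared with the genome-wide window
distribution by Welch's two-sided t-test (`stats::t.test`), with an
explicit convention for degenerate inputs: both groups constant and
equal gives $t=0, p=1$; constant but different is flagged degenerate.

# Read and site filters

Read-level QC discards a pair when either mate (a) has $\ge 10\%$ `N`
bases, (b) shows adapter contamination, (c) has $>50\%$ bases below
phred 5, or when (d) the pair's two sequences exactly equal those of an
earlier kept pair (PCR duplicate; first occurrence kept, qualities
ignored).  Criteria are applied in the order a–d and each discarded pair
is attributed to its first failing criterion.  Discarding whole pairs
rather than single mates keeps the mate files synchronized for mapping.
Adapter contamination means some ungapped alignment of an adapter
substring with more than 10 *matched* nucleotides and at most 10%
mismatches of the alignment length: an exact 10-nt match does not
qualify, an 11-nt exact match or a 20-nt stretch with two mismatches
does.  (Requiring only alignment length $>10$ would make the 10-nt
boundary case unattainable, since any 10-nt exact match inside a longer
read extends to an 11-nt window with one mismatch, i.e. 9.1%.)
Matching is ungapped; gapped adapter hits are not modelled.

Site-level filters keep biallelic SNPs with summed depth in $[4, 1000]$,
RMS mapping quality $\ge 20$, variant quality $\ge 30$, distance to the
nearest other SNP $\ge 5$ bp, and distance to the nearest gap $\ge 5$
bp.  "Gap" is interpreted as an indel variant record — the only gap-like
object available after calling — with distance measured to the indel's
reference-affected interval, half-open.  The SNP-spacing rule is
symmetric (both members of a too-close pair are removed), the
conservative reading used by distance filters generally.  Indel records
inform the gap rule but are themselves removed.

The analysis-set filter then removes sites with minor allele frequency
$\le 0.1$ (computed over called alleles with all samples pooled — the
filter precedes any per-population analysis), sites called in $\le 90\%$
of individuals (strictly more than 90% required: 29/32 passes, 28/32
fails), and sites monomorphic within the sample set regardless of the
reference allele (removing fixed differences against the reference
genome of a related species, which are not polymorphisms of the study
species).  The filter is idempotent.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated.  It simulates three populations — `HIGH` (11 diploids),
`LOW1` (11), `LOW2` (10) — under a clean two-split coalescent with no
migration: `HIGH` and `LOW1` merge at `t_split_recent` (default 5,000
generations), their ancestor and `LOW2` at `t_split_deep` (default
20,000), all with diploid effective size $N_e = 10^4$ (ancestral
populations take the size of the receiving population).  The mutation
rate is $2.78\times10^{-9}$ per bp per generation under the
infinite-sites model; a generation-time helper (1.5 years/generation)
converts years to generations.  The split-time and $N_e$ defaults are
free parameters chosen to give clearly resolvable structure
($F_{ST}\approx 0.2$ between highland and pooled lowland) at desk-scale
chromosome lengths; they are not calibrated to any inferred demographic
trajectory.

Recombination is approximated by dividing the chromosome into
independent non-recombining blocks (default 10 kb), each with its own
genealogy — the standard "independent loci" shortcut.  It reproduces
what the scan needs, namely between-window variation of the statistics,
while avoiding an ancestral-recombination-graph simulation; within-block
linkage is complete and between-block linkage absent, so LD-based
statistics (not provided) could not be validated on it.

Sweeps are planted phenomenologically: inside the sweep interval a
fraction $f$ (default 0.9) of the target population's haplotypes is
replaced by one resident core haplotype — the aftermath of a hard sweep
— which reduces focal diversity to roughly $(1-f)(2-f)$ of its neutral
expectation and shifts focal allele frequencies toward the core
haplotype, elevating $F_{ST}$.  This is exactly controllable and
sufficient for the scan's signal; it is not a forward selection
simulation, models no partial linkage decay at the sweep's shoulders,
and `f = 1` produces the degenerate zero-diversity case the estimators
must tolerate.

FASTQ simulation plants each QC defect class in known counts (with a
truth table), drawing clean sequence by rejection so that no random read
accidentally contains an adapter match; duplicates are byte-identical
copies of one designated pair.  VCF output fills `QUAL`, `INFO/DP` and
`INFO/MQ` with constant passing values — the simulator does not model
sequencing — and failing values can be injected via `write_vcf()`
arguments for filter tests.

What passing tests on these simulations show — and do not show — about
real data: the estimators, filters and scan logic are exact or
calibrated under neutrality and a clean demography; real data add
migration, bottlenecks, background selection, variable recombination and
callability, none of which the generator emulates.  The scan on real
data therefore inherits the usual caveat of outlier approaches: the
top-5% tail always exists, and thresholds are relative to the data set
at hand.

# Population structure

Pairwise distances are allele-sharing distances $d = 1 - \mathrm{IBS}$
(per co-called site, shared-allele fraction $1-|g_i-g_j|/2$;
pairwise-complete over missing data) — the standard SNP distance for
trees on genotype panels; the metric behind published trees of this kind
is typically unrecoverable, so the reconstruction is method-faithful,
not bit-faithful.  The neighbor-joining implementation is the classic
Saitou–Nei agglomeration with $Q(i,j) = (r-2)d(i,j) - R_i - R_j$,
deterministic lexicographic tie-breaking (so ultrametric fixtures are
reproducible), a trifurcating root, and branch lengths written as
computed — possibly negative, with an optional clamp for display.  It
recovers any additive distance matrix exactly (checked against `ape`'s
independent implementation in the tests).

PCA mean-centres each site by twice the allele frequency, scales by
$\sqrt{p(1-p)}$ (Patterson scaling), mean-imputes missing genotypes,
drops monomorphic sites, and eigendecomposes the sample covariance;
explained-variance fractions are reported.  Eigenvalue significance
testing (Tracy–Widom) is out of scope.

# Problem sizes and runtime choices

The test suite and the acceptance script validate at sizes chosen to
exercise every code path while remaining desk-scale: 1-Mb chromosomes
with 20+20 haploids for null calibration (20 replicates; mean windowed
$F_{ST}$ within $\pm0.02$ of zero, mean Tajima's D within $\pm0.2$,
joint selection $\le 5\%$ of windows), 5-Mb chromosomes with the
11/11/10 design and a 100-kb $f=0.9$ sweep for recovery (20 replicates;
$\ge 90\%$ must place a selected window on the sweep and recover the
truth-flagged gene), 100 random 5–10-taxon additive trees for NJ, and
two-population simulations at $F_{ST}\approx 0.1$ with roughly 5,000
SNPs for PCA separation.  Larger chromosomes scale linearly in blocks
and sites.

# Known limitations

No migration, bottlenecks or forward selection in the simulator; no
haplotype statistics (iHS, XP-EHH) or LD; $\pi$ normalized by span, not
callable sites; ungapped adapter matching; no genotype-likelihood
recalling or phasing; no multi-chromosome simulation (analysis functions
are per-chromosome and the scan operates per chromosome name).
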