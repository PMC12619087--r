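---
title: "Calling imprinted expression and parent-of-origin methylation in diploid endosperm"
author: "lilyprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling imprinted expression and parent-of-origin methylation in diploid endosperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Genomic imprinting — expression of an allele conditioned on the parent it
was inherited from — is classically studied in the endosperm of flowering
plants. In water lilies (*Nymphaea*) the endosperm is diploid with a 1:1
maternal:paternal genome ratio, unlike the 2:1 triploid endosperm of most
angiosperms, which makes it a test case for whether imprinting and
parent-of-origin methylation asymmetries require the 2:1 dosage.

Reciprocal interspecies crosses (A♀×B♂ and B♀×A♂) separate
parent-of-origin effects from species-of-allele (cis) effects: a gene
imprinted by parent shows the *same* parental bias in both cross
directions, while a cis-regulated gene shows the same *species* bias.
`lilyprint` implements the full analysis downstream of allele sorting:
imprinting calls from allele-resolved counts, contamination-corrected
re-calls, windowed DMR calling between parental methylomes, metagene
profiles, and a synthetic-data generator with ground truth that makes
every stage testable without sequencing data.

# The imprinting test

For gene $g$ and one sample per cross direction, let $(m_1, p_1)$ and
$(m_2, p_2)$ be maternal/paternal allele read counts. Endosperm shows a
genome-wide maternal expression bias even for non-imprinted genes
(dissection enriches maternally loaded transcripts and mapping favours the
maternal reference); the anticipated null for diploid endosperm is
therefore not a 1:1 but a $\beta$:1 maternal:paternal ratio, with
$\beta = 1.32$ by default (a null maternal proportion of
$\beta/(1+\beta) \approx 0.57$). Rather than testing against a shifted
proportion, we *divide each maternal count by* $\beta$ (rounding half away
from zero) and keep an exact test on the adjusted table:

$$
\begin{pmatrix}
\tilde m_1 & p_1 \\
p_2 & \tilde m_2
\end{pmatrix},
\qquad \tilde m_i = \mathrm{round}(m_i/\beta),
$$

arranged in species orientation (columns = species A/B; the maternal
allele of direction 2 is species B). A two-sided Fisher's exact test on
this table tests whether the species-A proportion differs between the
directions, i.e. whether allelic bias follows the parent. With $\beta = 1$
the table is the raw data. Maternal *fractions* are always reported from
unadjusted counts. `estimate_maternal_bias()` reproduces the "average
maximum observed bias": per sample a genome-wide pooled maternal:paternal
ratio over genes passing the read filter, maximum per direction,
arithmetic mean of the two maxima.

Calls are gated, per comparison, on:

| gate | default | meaning |
|---|---|---|
| `min_reads` | 50 | allele-specific reads needed in **each** sample |
| `alpha` | 0.01 | BH-adjusted p-value cutoff (BH over testable genes) |
| `meg_min_maternal` / `peg_max_maternal` | 0.70 / 0.30 | maternal fraction in **both** directions, boundaries inclusive |
| `min_if` | 2 | imprinting factor |
| `max_cef` | 15 | cis-effect factor |
| `consistency_min` | 0.75 | fraction of all direction-1 × direction-2 pairings calling the gene |

The **imprinting factor** quantifies separation of the allelic ratio
between directions: per sample a Wilson score interval (95%) on the
$\beta$-adjusted species-A proportion is mapped to a ratio interval
$[\ell/(1-\ell),\, u/(1-u)]$; the factor is the lower ratio bound of the
direction with the larger point ratio divided by the upper ratio bound of
the other. The **cis-effect factor** uses the same intervals but asks
whether both directions share a species bias: if both lower bounds exceed
1 it is the smaller lower bound, if both upper bounds are below 1 it is
the reciprocal of the larger upper bound, otherwise 1 — so it exceeds 1
only for *consistent* species bias, and genes above 15 are excluded.
Consolidation counts a gene as MEG/PEG when it is called in at least 75%
of **all possible** pairings (3 of 4 in a 2+2 design); untestable
comparisons count against the gene.

Design choices worth flagging (the underlying description leaves them
open): the test statistic itself (we use Fisher's exact test on the
adjusted table, exact at low counts); the read cutoff applied per sample
rather than summed (both confidence intervals must be estimable); Wilson
intervals for the ratio bounds (closed-form and non-degenerate at extreme
proportions — at proportion 0 or 1 the ratio bounds are taken as the
limits 0 and $\infty$, never a division fault); and factors computed on
$\beta$-adjusted counts, consistent with the test's null. The cis-effect
formula is one faithful reading of "calculated in a similar manner": it is
1 whenever the directions disagree, so it only ever *excludes* genes with
consistent species bias.

# Contamination correction

Endosperm dissections can carry maternal sporophytic tissue whose
transcripts are 100% maternal-allele. Given a whole-seed expression
profile (per-gene shares summing to 1) and an assumed contaminated
fraction $f$ of the endosperm pool, the expected contaminating reads for
gene $g$ in a sample with $T$ allele-specific reads are
$c_g = f \cdot T \cdot \mathrm{share}_g$; the corrected maternal count is
$\max(0,\ \mathrm{round}(m_g - c_g))$, paternal counts unchanged, and the
unchanged imprinting pipeline re-runs on the corrected table (totals are
not re-normalised after subtraction). Because correction only removes
maternal evidence, corrected MEG sets should nest inside the uncorrected
set — the package reports the nesting and logs any violation as an
anomaly. The correction is deliberately isolated in
`correct_maternal_counts()` as the single point of change.

# DMR calling

DMRs between the maternal and paternal methylomes of a sample are called
per cytosine context (CG, CHG, CHH) in fixed, non-overlapping 300-bp
windows anchored at position 1 (final partial tile retained). A cytosine
is *eligible* when covered by ≥ 5 reads in **both** methylomes — a
difference is only estimable where both alleles are observed — and a
window is tested when it holds ≥ 3 eligible cytosines. The window level is
weighted methylation (pooled methylated calls over pooled total calls,
as a percent) over eligible cytosines only, keeping the filter and the
test on the same data; the p-value is a two-sided Fisher's exact test on
the pooled 2×2 table. BH runs per context over all eligible windows of
one comparison (contexts differ in threshold and cytosine density), and a
DMR requires both the adjusted p < 0.01 and an absolute difference at or
above the context threshold (35 points CG/CHG, 10 CHH, boundary
inclusive). Whether windows are filtered on the difference before or
after testing does not change the final DMR set under this BH family; we
test all eligible windows and filter afterwards, which fixes the p_adj
values reported. Adjacent significant windows are *not* merged by default
(counts are window counts); a merge option exists. Symmetric CG sites are
kept as separate strand records by default, with a merge toggle in the
CX reader, since the cytosine-count filter is defined on records.

DMRs are associated with genes and repeats by any-overlap (≥ 1 bp) with
the feature interval extended ± 2 kb; counts per direction, context and
overlap class (gene / gene+repeat / repeat / neither) are averaged over
replicate comparisons. A gene is *consistently* associated with, say,
maternal-hyper DMRs when ≥ 75% of comparisons show at least one
overlapping maternal-hyper DMR and ≤ 25% show a paternal-hyper overlap
(both boundaries inclusive).

Metagene profiles pool counts per bin (100 bp over ± 2 kb around the 5'
or 3' anchor) across features, orienting minus-strand features so 5' is
left and clipping body-side positions at the feature's far end; bins with
zero pooled coverage are reported as missing, not zero. Pooled-count
(weighted) methylation per bin is used rather than averaging per-feature
fractions — stable at low coverage. The conversion rate is estimated as
the percent of unmethylated calls on a designated fully unmethylated
control contig, standing in for the unmethylated spike-in implied by
conversion-rate reporting.

# The synthetic generator

All generators are pure functions of a seeded configuration; identical
configurations give identical bytes. The expression generator draws
per-gene baseline abundance from a log-normal (sdlog 1), per-sample gene
totals with negative-binomial overdispersion (dispersion 0.05) around the
library-scaled abundance, and splits alleles binomially with maternal
odds $\beta_{\text{true}} \times o_g$, where $o_g$ is 1 for null genes,
$s/(1-s)$ with $s = 0.92$ for MEGs (mirror for PEGs), and a 20-fold
species-following ratio for cis genes. Defaults — 10⁴ genes, 2 replicates
per direction, 5×10⁶ allele-assignable reads per library (median per-gene
depth ≈ 300, so nearly all planted genes clear the 50-read filter),
$\beta_{\text{true}} = 1.32$, 2% MEGs / 0.5% PEGs / 1% cis — mirror the
study conditions; PEGs are planted even though the modelled system shows
essentially none, because the caller's PEG path needs symmetric truth.
Whole-seed contamination draws a profile correlated with endosperm
abundance (log-normal noise, correlation by construction) and adds
Poisson maternal-only reads with expectation $f \cdot T \cdot
\mathrm{share}_g$.

The methylome generator lays out a deterministic annotation (3-kb genes
of alternating strand every 20 kb, 1-kb repeats between them) on 2 ×
100 kb contigs, places shared cytosine sites at context-dependent
densities, and assigns plant-like background levels per annotation
(gene body CG 0.30 / CHG 0.05 / CHH 0.03; repeats 0.80 / 0.60 / 0.15;
elsewhere 0.10 / 0.05 / 0.02). Planted DMR windows (4 per context per
direction) sit on the 300-bp grid in unannotated space, clear of the
± 2 kb association flanks, with effects of twice the calling threshold
(0.70 CG/CHG, 0.20 CHH) added to the designated parent. Depth is Poisson
(mean 20; 50 on the control contig) and conversion failure (0.0015) adds
false methylation everywhere, giving an expected measured conversion
rate of 99.85%.

What the generator does *not* emulate: mapping bias beyond the single
global $\beta$, positional autocorrelation of methylation, read-level
errors, partial maternal contamination of methylomes, or genes whose
imprinting is itself hybrid-dependent. Passing recovery tests therefore
demonstrates the statistical machinery under the stated model, not
robustness to alignment artifacts.

# Numerical choices and degenerate inputs

* Count adjustments round half away from zero so the exact test always
  sees integers and $\beta = 1$ is exactly the identity.
* Wilson bounds at observed proportions 0/1 reach 0/1 only when the count
  itself is 0 or $n$; ratio transforms map those to the stated limits 0
  and $\infty$. A factor numerator and denominator both infinite cannot
  occur; an infinite denominator yields factor 0.
* Empty methylomes, header-only DMR tables, all-methylated controls and
  zero-comparison consolidations are handled as logged degenerate cases
  or explicit errors, never crashes.
* BH ties resolve by the standard step-up on sorted p-values; input order
  never affects any adjusted p-value or call.
* All internal coordinates are 1-based inclusive; BED conversion is ± 1
  on the start at the I/O boundary only.

# Problem sizes

The shipped analyses and tests run the full design — 10⁴ genes at 2+2
replicates for expression (null and planted), 2 × 100 kb methylomes at
depth 20 — which exercises roughly 4 × 10⁴ gene-level exact tests and
3 × 10³ window tests per run; the test-suite fixtures reuse one shared
simulation per condition, and a `tiny` preset (500 genes, one 30-kb
contig) covers the I/O and property tests in seconds.

# Known limitations

The cis-effect factor is a concretisation (see above) and other readings
would differ in borderline cases; the contamination model assumes the
whole-seed profile represents the contaminant and does not re-normalise
endosperm totals; DMR replicate comparisons treat one methylome pair per
sample (the pipeline accepts any list of comparisons for the averaging
and association steps); and the imprinting caller requires exactly two
cross directions — multi-parent designs are out of scope.
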