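---
title: "Methods: tag-based digital gene expression and small RNA analysis with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based DGE and small RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

# Scope and model

`tagdge` implements an integrated expression-profiling pipeline for matched
tumor/normal pairs assayed by two tag-counting protocols: NlaIII-anchored
digital gene expression (DGE) tags for mRNA, and small RNA sequencing for
miRNA. Both measure abundance by counting short sequences against a library
total, so a single statistical engine — an exact test for a difference
between two counts, with Benjamini–Hochberg false discovery rate control —
serves both arms. Downstream, deregulated features feed gene-set
over-representation, GSEA leading-edge prioritization and a positional scan
for co-regulated genomic miRNA clusters.

The package is organized so every stage can be exercised on synthetic data
with a machine-readable truth record: the generator is first-class, tested
code, not a fixture.

## The count model and the exact test

A transcript present at concentration $p$ contributes tags approximately as
a Poisson variable with mean $pN$ in a library of $N$ clean tags. For a
feature observed $x$ times among $N_1$ tags and $y$ times among $N_2$ tags,
the conditional distribution of $y$ given $x$ under a common concentration
is

$$P(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. `ac_probability()` evaluates it in log-space via
`lgamma`, so library-scale counts cannot overflow. `ac_test()` reports the
two-sided p-value as the doubled smaller conditional tail, capped at 1:

$$p = \min\!\Big(1,\; 2\min\big(\textstyle\sum_{y' \le y} P(y'|x),\;
  \sum_{y' \ge y} P(y'|x)\big)\Big).$$

Numerical choices:

* Tails are summed in chunks starting at the observed count and moving away
  from the conditional mean $(x+1)N_2/N_1$. Beyond the mode the term ratio
  $P(y'+1|x)/P(y'|x) = q\,(x+y'+1)/(y'+1)$ with $q = N_2/(N_1+N_2) < 1$
  falls monotonically below 1, so stopping when the last term is below
  $10^{-18}$ of the running sum leaves an omitted mass bounded by a
  geometric series — negligible at double precision. The near-side tail is
  recovered from the exact identity
  $\text{lower} + \text{upper} = 1 + P(y|x)$, which keeps the cost
  proportional to the distribution's width rather than to the counts.
* P-values are floored at the smallest positive double so the documented
  contract $p \in (0, 1]$ survives underflow (a planted four-fold change at
  counts of $10^4$ has $p \sim 10^{-600}$).
* Because the statistic conditions on the first library, swapping the
  libraries is not an exact involution; the two p-values agree on the log
  scale and exactly in the balanced case. The doubled-tail construction
  includes the observed count in both tails and is therefore slightly
  conservative for discrete data — visible as a null rejection rate a
  little below nominal at per-feature means of tens of counts, and
  essentially exact calibration at means in the hundreds.

Calls use the joint study thresholds $P < 0.01$ **and** FDR $\le 0.001$
(both configurable), with fold changes reported as
$\log_2((\mathrm{TPM}_T + c)/(\mathrm{TPM}_N + c))$ using a $c = 0.5$ TPM
pseudocount so undetected features stay finite. TPM (tags per million
clean tags) is $10^6 \cdot \text{count}/N$; 1 TPM is the detectability
threshold throughout, and only features at $\ge 1$ TPM in at least one
library of a pair are tested.

## The tag arm

`build_virtual_tag_index()` builds the virtual reference: for every CATG on
the sense strand of an annotated transcript with at least 17 nt downstream,
the 21-nt tag (CATG + 17 nt) keyed to the transcript's gene. All sites are
indexed (not only the 3'-most), and tags shared by several genes are kept
but flagged ambiguous. `filter_clean_tags()` removes, in a fixed documented
order, N-containing tags, adapter tags, then single-copy tags; the retained
mass is the clean total used as $N$ everywhere. `map_tags()` assigns a tag
to a gene only when the index entries within Hamming distance 1 resolve to
exactly one gene, with exact matches taking precedence over 1-mismatch
matches — the convention of the short-tag aligner class this models, chosen
to maximize specificity. Everything else stays unmapped, and
(assigned + unmapped + rejected) mass always equals the clean mass.
`discover_novel_tags()` reports unannotated tags with a genomic (but not
mitochondrial or transcriptomic) home expressed at $\ge 1$ TPM in at least
2 samples.

## The small RNA arm

`clip_adapter()` performs gap-free semi-global alignment of an adapter
prefix to a read suffix (match +1, mismatch −1), clipping at the
best-scoring position when the overlap is at least 6 nt with at most 20%
mismatches; ties go to the longest overlap. Gaps are not modeled — for
3'-adapter contamination in short reads, substitutions dominate and the
scan is then exactly equivalent to the dynamic program it implements.
Reads are deduplicated to (sequence, count), inserts under 18 nt dropped,
and unique sequences assigned through a fixed hierarchy: known miRNA,
rRNA, tRNA, snRNA, snoRNA, repeat, mRNA, else unannotated. A read counts
toward a mature miRNA when it matches exactly or with a ±2 nt 3' offset
(isomiR tolerance; 3' extensions must be templated on the precursor when
one is available; `iso3p = 0` restores exact-only matching). The 5' end is
assumed demultiplexer-trimmed; only 3' clipping is modeled.

## Novel hairpin screening

`evaluate_novel_candidates()` re-expresses the published screening criteria
as explicit, testable rules. Genome-mapped unannotated reads are clustered
into loci (gap ≤ 30 nt), each locus extended by 70 nt on both sides and
folded. The built-in folder is a Nussinov-style single-hairpin dynamic
program over nested pair chains — stacking, 1-nt bulges and 1×1 internal
loops, no bifurcation — scored +2 per pair, −5 per bulge, −4 per internal
loop, with a 3-nt minimum loop. Free energy is estimated as
$4 + 5B + 4M - 2(P-1)$ kcal/mol (equivalently $6 - \text{score}$): about
−2 kcal/mol per stacked pair against a +4 loop-initiation penalty, a
deliberately simplified stacking model whose single tunable scale is
anchored so the canonical stability rule (< −20 kcal/mol) corresponds to a
cleanly stacked stem of roughly 13+ pairs. An `RNAfold` backend
(`fold_rnafold()`) is available where ViennaRNA is installed; the built-in
model is the default because it is dependency-free and deterministic
across environments.

A candidate is reported iff all three flags hold:

* `hairpin_ok` — single stem-loop in which at least 16 positions of the
  mature (most abundant) read's span are base-paired (the mature/star
  duplex criterion), and at least 90% of the read mass has its 5' end
  inside a 3-nt window lying entirely on one arm (a simplified Dicer-cut
  homogeneity rule);
* `energy_ok` — estimated free energy below −20 kcal/mol;
* `recurrence_ok` — locus expressed at ≥ 1 TPM in ≥ 2 samples.

The flags are monotone in their thresholds: relaxing any threshold never
removes a reported candidate. A folding failure marks `hairpin_ok = FALSE`
rather than aborting the run. The mature-duplex rule, not the energy rule,
carries most of the discrimination: random 160-nt sequences frequently
reach −20 kcal/mol under any folding model (as real intergenic sequence
does), but almost never pair 16 positions of one fixed 22-nt window.

## Pathway analysis

`hypergeom_enrich()` performs the right-sided hypergeometric test
$P(X \ge k)$ for the overlap $k$ between the deregulated query and each
set, BH-adjusted across sets, with the fraction of upregulated members
reported per set. The universe defaults to all features detectable at
≥ 1 TPM in ≥ 1 sample that belong to any loaded set, and is configurable —
the choice of universe is the dominant analyst degree of freedom in
over-representation testing.

`gsea_es()` implements the weighted Kolmogorov–Smirnov-like running sum:
down the list ranked by mean per-pair log2 ratio (ties broken
lexicographically for determinism), the sum gains
$|s|^p / \sum_{hits}|s|^p$ at members and loses $1/(N - |S|)$ at
non-members; the enrichment score is the extremum and the leading edge is
the members at or before the maximum (positive ES) or at or after the
minimum (negative ES). Significance uses gene-label permutation with a
fixed per-set seed — with only 10 pairs, phenotype permutation would have
too few distinct relabelings. `core_gene_priority()` and
`mirna_priority()` count, per gene (or per miRNA via its targets, set
semantics: one hit per pathway), the pathways whose leading edge contains
it, in total and within a designated cancer subset. Predicted miRNA
targets are retained only when both prediction tables agree
(`build_target_map()`); experimentally supported pairs pass through
unchanged.

`positional_cluster_test()` scans sorted miRNA loci for maximal runs with
inter-locus gaps ≤ 10 kb and ≥ 3 members, and tests each cluster's up- and
down-regulated membership against the genome-wide background with the same
right-sided hypergeometric machinery, BH-adjusted within direction. With
3–8 member clusters the null p-values are discrete and conservative — a
pooled Kolmogorov–Smirnov comparison against the uniform will reject on
discreteness alone, which is a property of the statistic, not an error of
the scan.

# The synthetic-data generator

`simulate_genome()` builds a small two-chromosome genome plus a
mitochondrial contig in which every protein-coding transcript carries a
guaranteed NlaIII site with 17 nt downstream (the 3'-most site is the
"canonical" tag that receives reads), miRNA precursors are perfect
inverted repeats with the mature on the 5' arm, and several control loci
are planted: novel hairpins (30-bp stems), one hairpin expressed in a
single library (recurrence control), one expressed non-hairpin locus
(structure control), recurrent and single-sample intergenic tags, and a
mitochondrial tag. Decoy rRNA/tRNA/sn(o)RNA/repeat collections exercise
the annotation hierarchy.

The count model: baseline abundances are log-normal (sdlog 1.5 by default
— tag counts in real libraries span orders of magnitude, which also
exercises the 1-TPM detectability boundary by construction), winsorized so
no single transcript exceeds ~2% of the library (the raw log-normal tail
would occasionally hand one synthetic transcript a tenth of the library,
which no rRNA/mito-filtered expression library shows and which makes the
planted effect mass impossible to balance compositionally); counts are
negative binomial with variance $\mu + \phi\mu^2$, reducing to Poisson at
$\phi = 0$. The exact test assumes Poisson sampling, so `dispersion`
deliberately probes the model-misspecification axis: at the default
$\phi = 0.1$ the per-pair exact test calls large fractions of features
deregulated — the same behavior the protocol shows on real tumor/normal
pairs — while $\phi = 0$ isolates the statistic's own calibration.

Planted effects are applied as a symmetric half-effect split: tumor means
$\propto w\,2^{+e/2}$, normal means $\propto w\,2^{-e/2}$, each condition
renormalized to the library size, with signs assigned by a greedy
equal-mass partition of the DE features (heaviest first to the lighter
side). This keeps the planted tumor/normal ratio exactly $2^e$, leaves
non-DE features at ratio ~1 (normalization constants agree to a fraction
of a percent), and keeps library totals on target — a one-sided scheme
would either violate the library-size contract or shift every realized
effect by the renormalization constant. Library totals land within 5% of
the target whenever no single feature dominates the total's variance.

Everything derives from one integer seed through fixed per-stage
sub-seeds; identical configurations give byte-identical outputs.

What the generator does **not** model: sequencing quality variation beyond
a constant Phred score, indels and ligation bias, isomiR ends beyond exact
templated extensions, expression correlation between genes, and patient
heterogeneity beyond NB dispersion. Passing the recovery tests therefore
demonstrates that the statistical chain is implemented correctly under its
own assumptions — not that those assumptions hold for any particular real
cohort.

# Problem sizes and study conditions

The recovery study uses the matched design the generator emulates: 10
tumor/normal pairs, $10^6$ clean tags per library, 1,000 genes with 10%
truly DE at $|\log_2 FC| = 2$, Poisson counts, averaged over 20 seeds. A
planted gene counts as recovered when it is called (P < 0.01,
FDR ≤ 0.001) with a consistent sign in at least 2 of 10 pairs — the same
recurrence rule the downstream pathway stage uses for "deregulated"
features; a non-DE gene so called counts as a false discovery. Measured:
~98–99% recovery at a false-discovery proportion of 0. The type-I study
uses $10^4$ features under the null; the novel-miRNA screen uses 10 seeds
of a 40-gene genome with 3 planted hairpins and both decoys; the cluster
scan uses 300 background loci with a planted 7-member all-down cluster
over 100 replicates. These sizes keep each study in the seconds-to-minutes
range while leaving the per-feature counts at the scale the protocol
actually produces.

# Known limitations

* The exact test treats each pair independently; it has no shrinkage
  across pairs or genes, by design (it reproduces the per-pair testing
  chain, not a modern NB-GLM analysis).
* Conservative discreteness at low counts, as analyzed above.
* The hairpin energy model is a calibrated surrogate, not a thermodynamic
  parameter set; use the RNAfold backend for physically meaningful MFEs.
* The adapter clipper models substitutions only (no indels).
* Ambiguous tags are discarded rather than fractionally assigned;
  abundance of genes whose canonical tag is shared is underestimated.
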