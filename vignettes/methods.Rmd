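---
title: "Methods: differential phospho-signalling pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phospho-signalling pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements,
the parameters that matter, what the synthetic generators do and do not
emulate, and the places where the design was genuinely open and a choice
had to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experimental design being modelled

The input is a replicated four-channel isobaric-label phosphopeptide
quantitation table: each row is one phosphopeptide observed in one
replicate, with reporter-ion intensities for four cell conditions — a
wild-type receptor line and a fusion-kinase line, each without and with
growth-factor stimulation (`WT`, `WT_FGF`, `FUS`, `FUS_FGF`). Three
pairwise comparisons are defined: C1 = FUS/WT, C2 = FUS-FGF/WT-FGF,
C3 = WT-FGF/WT. Ratios are oriented so that fusion-driven (C1, C2) and
stimulation-driven (C3) phosphorylation increases are positive on the
log2 scale; the pipeline focuses on C1 and C3 by default, i.e. on
"what does the fusion do constitutively" versus "what does physiological
stimulation do".

A phosphopeptide may carry several phosphosites; composite annotations
such as `T401/S405` are kept as one site key throughout — the data do
not support attributing the ratio to an individual residue of a
multiply-phosphorylated peptide. Positions are 1-based on the protein.

## Site statistics

Two dataset tiers are built from the same table:

* **HC** (high confidence): identification FDR ≤ `hc_fdr` (default 1%;
  the source protocol states only that the broader tier uses 5%, so the
  stringent tier's threshold is configurable). No channel-completeness
  requirement — an HC peptide may support some comparisons and not
  others.
* **QP**: identification FDR ≤ 5% *and* all four channels observed and
  positive, so every comparison ratio is computable. QP deliberately
  trades identification stringency for quantitation completeness; it
  feeds the network seeding, while HC is used for final site calls and
  as a pathway quality filter.

Per site and comparison, each replicate contributes
log2(numerator/denominator); the summary is the mean μ, the standard
deviation σ (0 when n = 1), and the interval μ ± 1.96σ. Aggregation is
the mean of per-replicate log ratios, not the ratio of summed
intensities — replicates are the unit of evidence. A site is *regulated*
when |μ| ≥ 0.5 (inclusive, log2 units) and *strict* when additionally
n > 1 and the interval excludes 0. Note the interval uses the population
z-multiplier 1.96 with a sample σ, so its null miscoverage depends on
the replicate count (7.7% at n = 3, not 5%); the tests assert the exact
t-distribution value rather than the nominal level.

### The intensity-binned outlier test (significance B)

Ratio variance in reporter-ion data grows as intensity falls, so a
global outlier test over-calls low-abundance sites. Sites are ordered by
mean total intensity and cut into consecutive bins of ≥ `bin_size`
(default 300, last short bin merged). Within a bin, the null is
summarised robustly by the median m and the two side-specific spreads
taken from the 15.87/84.13 percentiles (the ±1σ quantiles of a normal).
Each site gets a signed score `z = (μ − m)/spread(side)` and an
upper-tail p-value `p = erfc(z/√2)/2`.

Two properties motivated the signed (rather than absolute-value) score:
under a symmetric null the p-values are uniform on (0, 1), and the
fraction with p ≤ α is α — both are asserted by the acceptance tests at
n = 10,000. With an absolute-value score these calibration properties
are unattainable (every p would be ≤ 0.5 and the α-tail would hold 2α of
the sites). The cost is that a single threshold `p ≤ α` only captures
up-outliers; the reporting flag `sigb_significant()` is therefore
two-tailed (p ≤ α or p ≥ 1 − α). In degenerate bins (zero spread on a
side) p is defined as 1 at the median and undefined elsewhere. The test
is applied per comparison, since ratio distributions differ between
comparisons.

## Seeding

**Substrate seeds.** A protein seeds the network analysis when at least
one of its QP phosphosites was observed more than once and has
μ ± 1.96σ strictly excluding 0. This is deliberately *weaker* than the
HC site-report rule — the 0.5 magnitude gate does not apply — because
seeding wants a broad pool of plausibly-affected proteins; stringency is
re-applied later through the HC pathway filter.

**Kinase seeds.** For each seed site with a sequence context, every
candidate kinase is scored by a likelihood ratio combining two
independent evidence sources, mirroring the published kinase–substrate
predictors in a self-contained form:

* motif: product over the 11 positions (−5..+5) of
  P(residue | kinase PWM) / P(residue | background); termini are padded
  with `_`, contributing factor 1. The window length is an artifact
  convention (the predictors this emulates use comparable windows).
* proximity: `exp(λ(d₀ − d))` with shortest-path distance d on the
  signalling network, λ = 1, reference distance d₀ = 2 (LR = 1 at a
  typical kinase–substrate separation, matching the published
  observation that the median combined score is ≈ 1), and a ceiling
  d_max = 6 applied to unreachable or unmapped proteins. The functional
  form is an artifact choice — the original predictor's form is not
  published — chosen monotone in d and calibrated at d₀.

Kinases with combined LR below the median over *all* (site, kinase)
predictions for the comparison are discarded; the median is global, not
per site, because the source describes a single median score, and ties
at the median are kept, so at least half of predictions always survive.
Proteins appearing as both substrate and retained kinase carry
provenance `both`. When no PWMs or contexts are supplied the stage is
skipped and seeds are substrates only.

## Network stage

The signalling network is an undirected simple graph (duplicate edges
merged, self-loops dropped) read from a two-column TSV or SIF. The
tissue filter removes a protein only on *positive evidence of absence*:
it must be present in the expression table and below `min_level`
(default Low) in every listed tissue. Proteins missing from the table
are retained and tallied — silently deleting unannotated signalling
proteins would bias the module search, and "unlikely to be expressed"
requires evidence. The filter is idempotent and OR-semantic across
tissues.

Seeds are classified as mapped / filtered / absent against the
unfiltered and filtered networks, and the mapped seeds define the
*effective network*: the induced subgraph on seeds plus first
neighbours. An alternative diffusion expansion (personalised PageRank
with restart 0.5, nodes kept above a mass threshold) is available behind
`method = "diffusion"` because the source material describes the
expansion once as first-neighbour extraction and once as a graph
kernel without naming the kernel; the variant used is recorded in the
output metadata, and first neighbours are the default.

### Module expansion

Module detection runs on the tissue-filtered full network (not the
effective network): connectivity significance is defined against the
global topology. At each iteration every node with ks ≥ 1 links into the
current set is scored with the hypergeometric tail
p = Σ_{i = ks..k} C(s,i)·C(N−s,k−i)/C(N,k), and the smallest-p node
joins the set; 200 iterations by default. Nodes with ks = 0 have p = 1
by construction and are never candidates. p-values are recorded at the
iteration of addition and not multiplicity-corrected — only the ranking
matters, faithful to the published algorithm. Ties are broken by larger
ks, then larger degree, then lexicographically smallest identifier,
which makes runs byte-identical; the published algorithm leaves the tie
rule open. Seed weighting (each seed link counted α times, inflating
ks, k, s and N consistently) is implemented but defaults to α = 1,
since the protocol does not mention weighting. The implementation
updates ks incrementally; the test suite proves it equivalent to a
brute-force full-rescan oracle on 50+ random instances.

## Pathway stage

Enrichment is a one-sided hypergeometric test per pathway on the
DIAMOnD-expanded protein list, with Benjamini–Hochberg q-values over all
tested pathways and significance at q ≤ 1%. The universe defaults to
proteins present in both the filtered network and at least one pathway —
the background the query was actually drawn from; `all_network_nodes`
is available since the source does not define its background. Pathways
with fewer than 3 members in the universe are skipped as small-set
noise. BH is re-implemented (step-up with the cummin trick) rather than
delegated so it is independently testable against a quadratic-time
reference. No hierarchy-aware pruning is applied; the hierarchy is used
only for annotation edges in the exported graph.

The differential classification between comparisons A and B is:

* `unique_A = A − B`, `unique_B = B − A`, `shared = A ∩ B` on the
  significant-pathway id sets;
* unique pathways are *HC-validated* when at least one of the protein
  hits that identified them is in the HC dataset;
* shared pathways are flagged toward A when
  `hits_A ≥ (1 + f)·hits_B` with f = 0.25, inclusive (the source's
  "25% more" does not resolve strictness; inclusive was chosen and is
  documented here), with the limit rule that hits_B = 0 and hits_A > 0
  flags A. Hit counts are taken after universe restriction — the counts
  the enrichment test actually used. The A and B flags are mutually
  exclusive whenever f > 0 and both counts are positive.

The exported pathway–protein graph (GraphML + flat TSV) carries pathway
class, protein confidence tier (HC / QP / network-only — in the HC
dataset, only in the QP dataset, or introduced by network expansion),
per-comparison regulation, and hierarchy edges between retained
pathways. `local_phospho_context()` cuts the effective-network
neighbourhood around chosen proteins with their retained kinases for
close reading of a pathway's phospho-signalling context.

## The synthetic world

The generators are pure functions of a `synthetic_spec` (fixed master
seed, distinct derived sub-seed per generator; identical spec gives
byte-identical outputs). Defaults: 1,500 sites on 800 proteins, 3
replicates, multiplicative log-normal reporter noise at CV 0.1, planted
|log2| effects of 1.0 on 60 sites per comparison (applied to the
numerator channel: FUS for C1, FUS-FGF for C2, WT-FGF for C3, half up
half down), 5% random channel dropout, identification-FDR tiers drawn
at 0.005/0.03/0.08 with probability 0.7/0.2/0.1 so both the HC and QP
filters bite; a 2,000-node preferential-attachment network with a
60-node planted module (within-module edge probability 0.25; an
Erdős–Rényi background at density 0.01 is available and is the stated
world for the module-recovery acceptance check); 100 pathways of 10–60
members, 30% of them enriched to half module members; a two-tissue
expression table with 10% dropout and 15% both-tissue NotDetected
entries. `simulate_inputs()` anchors the planted module on the regulated
proteins so the quantitation signal and the network signal describe the
same biology — without that coupling the pipeline's stages are
individually exercised but no end-to-end enrichment signal exists.

What the generators do *not* emulate: peptide identification and its
error structure (FDR tiers are drawn, not modelled), isotope impurity,
phosphosite localisation uncertainty, correlated channel noise,
non-random missingness, and the literature biases of real interaction
networks and pathway databases. A green recovery test therefore
establishes that the statistics and algorithms behave as specified on
data matching their assumptions — not that the protocol's biological
conclusions transfer to any particular real dataset.

## Numerical choices and degenerate inputs

* Thresholds are inclusive throughout (|μ| ≥ 0.5, q ≤ FDR, median ties
  kept, 25% rule ≥).
* σ at n = 1 is defined as 0; such sites are never strict and never
  seed.
* Zero or missing intensities exclude a record from a comparison with a
  logged reason; they are not errors.
* Degenerate significance-B bins: p = 1 at the median, NA elsewhere.
* The hypergeometric tail is computed via `phyper` on a shifted
  argument; tests pin it to exact `choose()` enumeration at 1e-10.
* All randomness lives in the generators; the pipeline proper is
  deterministic, so reruns from identical inputs are byte-identical
  (asserted by the acceptance suite on a scaled-down world — size does
  not affect the property).
* The HC/QP protein overlap is reported with the union denominator by
  default (the source does not define its denominator); the HC-only
  denominator is available as an argument.

## Known limitations

* Identifier harmonisation is the caller's responsibility (one id space
  across quant table, network, pathways, expression); no mapping beyond
  a consistent naming convention is attempted.
* Kinase scoring is a self-contained mechanism with the published
  *shape* (motif × proximity, median filter), not a re-implementation of
  any external predictor's numbers; kinase-seed counts from specific
  external database versions are out of reach by design.
* Composite multi-site peptides are not split; a site regulated in
  opposite directions on two co-occurring peptides appears as two keys.
* Enrichment treats pathways as flat sets; hierarchy relations are
  annotation only.
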