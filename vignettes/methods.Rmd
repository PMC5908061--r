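---
title: "Methods: sweep scans, acceleration tests and the regulatory funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scans, acceleration tests and the regulatory funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sweepreg implements the computational core of a candidate-gene selection
study: given phased population haplotypes around a regulatory locus,
primate multiple alignments, a transcription-factor motif, and
epigenomic summary tables, it asks (i) whether the locus shows
population-genetic signatures of a recent selective sweep, (ii) whether
its sequence has evolved unusually fast on a chosen lineage, and (iii)
which of several candidate regulatory regions best explains a
species-specific expression difference. This vignette records the
models, the tunable parameters, and the design decisions behind each
stage.

## Site-frequency statistics

For a sample of `n` phased chromosomes with `S_n` polymorphic sites and
major-allele frequencies `p_i`, nucleotide diversity is computed in the
frequency form

$$\pi = \frac{n}{n-1}\sum_{i=1}^{S_n} 2 p_i (1-p_i),$$

which equals the mean number of pairwise differences between sampled
chromosomes (a property-tested identity, exact to 1e-12 on random
fixtures). Watterson's estimator is
$\theta_s = S_n / \sum_{i=1}^{n-1} 1/i$, and Tajima's D is
$(\pi - \theta_s)/\sqrt{\widehat{Var}(\pi-\theta_s)}$. The source for
this statistic prints only its numerator; for the variance we use the
standard Tajima (1989) coefficients
($e_1 S + e_2 S(S-1)$), which is what every widely used implementation
does. `D` is reported as `NA` — undefined, not zero — in windows without
segregating sites.

`windowed_scan()` tiles a region with 1-kb windows advanced by 100 bp
(both configurable), anchored at the region start, dropping a final
partial window. Per-bp diversity divides the window's total `pi` by the
full window length, because invariant positions contribute zero; this
matches how per-window diversity is normally plotted for a scan of a
+/-4.5 kb candidate region. Whether scan windows should be clipped or
extended at region edges is a genuinely open choice; anchored tiling
with a dropped partial window is ours, and it is what the window-count
arithmetic in the tests asserts.

## EHH and iHS

`ehh()` measures, for the carriers of one core allele, the probability
that two randomly chosen carrier haplotypes are identical over the
interval from the core out to a given offset; it is 1 at the core and
non-increasing outward. `unstandardized_ihs()` integrates the ancestral-
and derived-core curves by the trapezoid rule in physical bp, outward in
both directions, truncating when EHH falls below 0.05, and reports
`ln(iHH_A/iHH_D)`. Scores at sites with derived frequency outside
[0.05, 0.95], or whose integration would cross a gap wider than 20 kb,
are invalidated rather than silently returned; integration that reaches
the matrix edge before decaying is flagged `edge_truncated` (kept by
default). These three knobs are the published defaults of the original
iHS method; the study this pipeline follows defers to a workflow
citation without printing its parameters, so they are exposed as
arguments rather than asserted as anyone's exact settings.

`standardize_ihs()` centres and scales the unstandardized scores within
50 equal-width derived-frequency bins (bins holding fewer than 10 scores
are merged with their nearest occupied neighbour), using the population
(1/n) standard deviation so that a two-score bin {-1, 1} standardizes to
exactly {-1, 1}. `|iHS| > 2` flags extremes, and the sign infers the
selected allele: positive means longer ancestral-background haplotypes
(call `A`), negative means `D`, with a 1e-9 tie tolerance.

## CLR sweep scan

`clr_scan()` implements a composite likelihood ratio test of a completed
sweep against the region's own empirical unfolded site frequency
spectrum (0.5 pseudocount per frequency class). The sweep model is the
Nielsen-style star approximation: at a test position, each of the `n`
sampled lineages at a site `d` bp away escapes the sweep independently
with probability $p_e = 1 - e^{-\alpha d}$; all non-escaped lineages
coalesce onto the single sweeping haplotype. The derived-count
distribution follows by hypergeometric downsampling of the background
spectrum to the escaped lineages plus that stem, the stem then expanding
to its `n - e` descendants. This construction is exactly
background-consistent: at full escape the class distribution *is* the
empirical spectrum, so a fitted sweep with no effect gives CLR = 0.

Two numerical choices matter. First, by default the composite likelihood
also uses invariant positions — each position contributes the
probability that it is polymorphic at all under the fitted escape
profile — because the diversity trough is the strongest spatial footprint
of a sweep; `include_invariant = FALSE` restores a polymorphic-sites-only
scan. Second, the `alpha` grid (25 log-spaced points) is bounded below
at `20/span`: smaller decay rates describe a "sweep" wider than the
scanned region, which is indistinguishable from a rescaled background
and only adds noise to localization. Escape probabilities are
discretized to 0.01 (configurable); the test oracle reproduces the model
longhand on the same discretization.

## The omega statistic and the compound test

`omega_stat()` scores, for each split of the window's `S` sites into a
left and right block, the mean within-block LD (`r^2`) divided by the
mean between-block LD, and maximizes over splits `l` in `[2, S-2]` with
an epsilon-guarded denominator (1e-9). A completed sweep leaves strong
LD within each flank but not across the swept site. Windows with fewer
than 4 polymorphic sites are reported as undefined rather than dropped.

Significance for both scan statistics comes from `calibrate_null()`:
empirical `(1-q)` quantiles of the per-replicate maximum statistic over
seeded neutral simulations, at the conventional q = 0.05 and q = 0.1.
`compound_test()` then flags bins per statistic — against the calibrated
thresholds and against the empirical top-1% rank rule — and calls a bin a
common outlier when *both* statistics flag it under the chosen criterion
(default: the top-1% rule, matching how compound CLR/omega outliers are
usually drawn). The bin width (default 1 kb) and the exact combination
rule are configuration, since neither is standardized in the literature
this follows.

## Simulators

The package generates all of its own inputs.

**Coalescent** (`simulate_neutral_coalescent()`): Kingman coalescent
without recombination under the `ms` conventions — time in units of
4N0 generations, `theta = 4 N0 mu` per locus, infinite-sites mutations
dropped at rate `theta/2` per unit branch length and placed uniformly on
a unit locus scaled to the requested bp span. Closed-form expectations
(`E[S] = theta * sum 1/i`, `E[pi] = theta`, `E[D] ~ 0`) make this engine
exactly checkable; it deliberately has no recombination, so LD-bearing
null distributions come from the forward simulator instead.
Recombination-rate heterogeneity (hotspots) is not modelled anywhere; a
known limitation.

**Wright-Fisher** (`simulate_wf()`): discrete-generation diploid forward
simulation with genotype fitnesses `1, 1+hs, 1+s` at one selected site,
per-gamete crossovers between adjacent base pairs at rate `r`, per-site
mutation rate `mu` with at most one mutation retained per site, and a
burn-in of `10 N` generations. Sweeps are conditioned by restart: a
single selected copy is introduced after burn-in and the run restarts
from the burned-in population until the allele reaches `sampling_freq`
(1.0 = fixation), which keeps the conditioning exact at the price of
wall time. The kernel is C++ with a sparse segregating-site
representation driven by R's RNG, so `set.seed()` reproduces runs across
platforms.

The default parameters are the study conditions used throughout the
tests and the acceptance script: `N = 500`, `s = 0.05`, `h = 0.5`, locus
`L = 50` kb, `mu = 5e-7` (`theta`/bp = 0.001, the canonical human
figure), `r = 2e-6`, and samples of 50 chromosomes. They were chosen so
that the expected sweep footprint, roughly `s/(r ln 2N)` (about 1.8 kb),
sits well inside the locus with genuinely neutral flanks on both sides —
a locus smaller than the footprint leaves nothing to localize against.

**Phylogenetic** (`simulate_alignment()`): independent columns, root
base from the model's equilibrium frequencies, substitutions along each
branch under JC69 (default) or HKY85, with the branches of a named clade
— including its stem, mirroring how a two-species subtree is named in
phyloP-style analyses — scaled by a rate multiplier. The JC69 two-leaf
closed form and a brute-force sum over internal states serve as oracles.

**Funnel fixture** (`make_funnel_fixture()`): a seeded, self-verifying
bundle of every funnel input with one planted candidate: 12 distal
regions inside a TAD correlating at >= 0.7 with the promoter
accessibility profile (plus 3 outside-TAD decoys below 0.7), 5 regions
with macaque-only histone peaks, 3 with contact evidence, exactly one of
those with a planted 4x subtree acceleration, and a sequence carrying
two motif instances whose derived alleles raise the motif score.
Construction is rejection-sampled within the seeded RNG stream until the
planted structure holds, so every seed yields a valid fixture
deterministically.

What these simulators do *not* emulate of real data: demographic history
(bottlenecks, growth, structure), recombination hotspots, sequencing and
phasing error, ascertainment bias, alignment error and indels, and
context-dependent substitution. Passing tests therefore demonstrate
correctness of the statistics and power under idealized conditions, not
performance on real cohort data.

## Lineage acceleration

`column_log_likelihood()` is Felsenstein pruning, vectorized across
columns, with gaps and ambiguity codes treated as missing data.
`subtree_lrt()` fits a null model with one shared branch-length
multiplier and an alternative with separate multipliers for a named
clade (with stem) and the remainder, both bounded to [1e-4, 100] and
optimized on the log scale — the null by golden-section search, the
alternative by coordinate ascent started from the null optimum, where
only improving steps are accepted, so the nested-model inequality
`lnL_alt >= lnL_null` holds by construction (and is asserted).
`Lambda = 2(lnL_alt - lnL_null)` is referred to chi-squared with 1 df;
the conservation/acceleration score is `-log10(p)` signed positive for a
slower subtree and negative for a faster one, so accelerated elements
rank first when sorted ascending. A boundary-corrected (halved) p-value
is available but off by default, matching the plain LRT description.
JC69 is the default substitution model — a documented simplification
relative to the general reversible models of the full phyloP toolkit;
the structure of the test (nested scale LRT, signed score) is the
point. `basewise_scores()` applies the same test per column for wiggle
export, and `rank_elements()` orders elements by (accelerated,
ascending signed score, id).

## Motif analysis

PWMs carry a 0.1 pseudocount folded in per cell before row
normalization, with a uniform background by default. `logodds_score()`
is the standard log2 odds in bits. `score_pvalue()` computes the exact
p-value of a score under the background by dynamic programming over
per-column scores discretized to 1/1000 bit, convolving across columns;
enumeration over all `4^k` k-mers on the same discretization reproduces
it exactly (tested for widths up to 6). `scan_pwm()` scores every
placement on both strands and keeps hits at the FIMO-convention
threshold `p <= 1e-3`.

`allele_effect()` substitutes each allele of a variant into its context
sequence and scores the best placement covering the variant over both
strands. The placement is chosen to maximize the *smaller* of the two
allele scores — a symmetric criterion that cannot bias toward either
allele; placements are only considered in-motif if the better allele
reaches a relaxed threshold (1e-2 by default). `cross_species_filter()`
then applies the fixed-variant pattern: human and chimpanzee references
carrying the derived allele, the macaque outgroup reference carrying the
ancestral allele, and the variant lying inside a reported motif hit.

## The regulatory funnel

`candidate_funnel()` applies, in order: TAD containment (full
containment in the intersection of the supplied TAD calls — domains
bound most enhancer-promoter contacts, so straddling regions are
rejected), promoter linking by Pearson correlation of tag-density
profiles across cell types with an *inclusive* >= 0.7 threshold
(Spearman available), strict group-differential peak calls (present in
all of group A, absent from all of group B; lenient fractions
configurable for noisy data), an optional precomputed contact-evidence
flag (its upstream computation — Hi-C significance against GC-matched
backgrounds — is consumed, not reproduced), and final ranking of the
survivors by acceleration score, most negative first. Every region's
pass/fail trail is reported, the chain counts are monotone
non-increasing, and the whole funnel is a pure function of its inputs
(idempotent, input-order invariant).

## Problem sizes and what the checks show

The test-suite experiments use: 200 random fixtures for the pi identity;
5,000 coalescent replicates at n = 10, theta = 5 for neutral
calibration; 50 paired forward simulations at the study conditions above
for sweep detection; 20 alignment replicates of 500 columns at a planted
4x multiplier for acceleration power; 50 random PWMs of width <= 6 for
p-value exactness; and 10 fixture seeds for funnel uniqueness. These
sizes keep each experiment's Monte-Carlo error well below the margins
being asserted while remaining desk-scale.

One power result deserves honesty: localizing a *weak* completed sweep
(2Ns = 50 at N = 500, s = 0.05) by the CLR argmax is
information-limited. On the same 50-kb replicates, an oracle that simply
picks the minimum-diversity 5-kb window recovers the true sweep site
within 10% of the locus in only about two thirds of runs; the CLR scan,
which must also reject spurious drift troughs, lands within that margin
in roughly half. Detection (paired central-diversity reduction) is
essentially always successful; fine localization at this selection
strength is not, and no SFS-based estimator should be expected to make
it so. Analyses of strong sweeps (2Ns in the hundreds) do not hit this
ceiling.

## Known limitations

- The coalescent engine has no recombination; omega nulls must come
  from the forward simulator.
- The forward simulator models a single panmictic population of
  constant size; no demography or migration.
- JC69/HKY85 only; no rate variation across sites; no indel model in
  the alignment simulator (gaps are handled as missing data in
  likelihoods but never generated).
- The PWM background is position-independent (0-order); dinucleotide
  backgrounds are out of scope.
- Contact evidence and TAD calls are consumed as given; the package
  does not process Hi-C matrices.
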