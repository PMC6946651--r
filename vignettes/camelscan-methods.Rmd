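---
title: "Models and methods behind camelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camelscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camelscan)
```

camelscan analyses multi-population biallelic-SNP panels for local
introgression and its effect on population phylogeny. This vignette is the
package's own account of the models it implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed.

## The inference chain

The intended workflow mirrors how one asks "where were domestic Bactrian
camels domesticated?" on a panel with a dromedary outgroup, wild Bactrians,
and domestic Bactrian populations from Central Asia (IRAN, KAZA, RUS) and
East Asia (MG, IMG, XJ):

1. **Filter** variants: `QUAL > 40`, summed depth `200 < DP < 5000`,
   `MAF > 1%`, fraction of individuals missing `< 20%`, RMS mapping quality
   `> 30`, biallelic only. All inequalities strict, all thresholds
   overridable, each rule's removals tallied separately (a record failing
   several rules counts in each tally).
2. **Describe** diversity and structure: windowed π, Watterson's θ and
   Weir–Cockerham Fst in 10 kb windows; IBS distances and classical MDS;
   LD pruning (PLINK-style 50-variant/5-step/r² 0.5 scan) for structure
   analyses.
3. **Scan** for introgression: per non-overlapping 100 kb window, Patterson's
   D and f_d for the quartet (East Asian, Central Asian; wild, dromedary),
   with a delete-one jackknife over the window's 10 kb blocks giving a
   Z-score; `Z > 2` flags flow between the donor and the Central Asian side,
   `Z < −2` the East Asian side.
4. **Mask** every window with `|Z| > 2` in either direction and recompute
   Fst. Both directions are removed because lingering donor ancestry on
   either side biases the distance matrix; one-direction masking is
   available as an option.
5. **Rebuild** the population phylogeny: pairwise distance = average
   windowed Fst, neighbor joining, and bootstrap support from repeatedly
   resampling spaced 10 kb windows.

F3 and F4 admixture tests (`f3_test`, `f4_test`) complement the scan at
whole-panel scale, jackknifed over 500-SNP blocks, with the usual sign
conventions: strongly negative F3(Z; X, Y) flags Z as a mixture of X and Y;
for F4(Y, Z; W, X) with W an outgroup of Y and Z, negative means Y shares
more ancestry with X, positive means Z does.

## Statistical definitions and conventions

**Weir–Cockerham Fst.** Per site the 1984 variance components a (among
populations), b (among individuals within populations) and c (within
individuals) are computed for two populations from the observed sample
sizes, allele frequencies and heterozygote proportions; windows and overall
values aggregate as ratio-of-sums `Σa / Σ(a+b+c)`, never as means of
per-site ratios. Raw estimates may be slightly negative and are reported
as-is; only when Fst is used as a phylogenetic *distance* is the per-pair
average floored at zero. Sites need at least two called diploids in each
population; sites monomorphic across both populations contribute zero to
both sums.

**π and θ.** Per site, π adds `2x(n−x)/(n(n−1))` for `x` alternate alleles
among `n` called alleles; a window divides the sum by the full window span
in bp, not by callable sites — matching the convention of the standard
windowed tooling, so values are comparable to published per-bp diversities.
θ_W divides the window's segregating-site count by the harmonic number
`a_n` of the *modal* called allele count over the window's usable sites
(whether published θ used modal or per-site n is not stated anywhere we
know of; modal-n is the choice here and is flagged in the function
documentation).

**D and f_d.** Expectations are means over a window's usable sites — sites
where all four group frequencies are defined. Group frequencies pool all
called alleles of the member populations, because scans are run on merged
regional groups rather than single populations. The f_d denominator takes,
per site, the larger of the donor-substituted products, with the branch
selected by the sign of D on the same site set; `D = 0` exactly yields
`f_d = 0` by continuity, and a degenerate denominator yields an undefined
flag rather than a number.

**Jackknife.** The Z-score divides the pseudo-value mean by
`sqrt(var × n)` with `n` the number of blocks — the convention of the
analysis this package follows. The textbook delete-one jackknife would use
`n − 1` inside the root; `n_convention = "n-1"` switches to it. For delete-one
schemes "repetitions" and "blocks" coincide, so the ambiguity in what `n`
counts has no effect. Degenerate cases are deterministic: zero variance
gives a signed infinity, or Z = 0 when every pseudo-value is zero.

**Windows.** All intervals are 0-based half-open internally; VCF positions
are 1-based at the boundary. Windows tile each chromosome without overlap
(the published window counts imply non-overlapping windows); a partial tail
window is kept when it spans at least half the window size.

**Neighbor joining and consensus.** NJ, majority-rule consensus, newick
serialization and bipartition counting are delegated to ape; the package
adds negative-branch clamping (to zero, with a warning), support attachment
to the full-data tree by bipartition matching (the consensus of the
replicates is also returned), and strict-majority semantics — a split
present in exactly half of the trees is not retained. Bootstrap replicates
sample windows without replacement under the spacing constraint, greedily
along a shuffled candidate list, so a run is reproducible from its seed.

## The synthetic-data generator

The generator exists so that every stage above can be tested against known
truth. It is deliberately *not* a coalescent simulator: population allele
frequencies evolve on a rooted tree under the Balding–Nichols model — along
a branch with drift coefficient F, the child frequency is Beta-distributed
with mean p and variance `F·p·(1−p)`; boundary frequencies are absorbing —
and admixture enters as pulses `q' = (1−f)·q + f·p_donor` applied after all
drift, only at sites inside each pulse's window set. This makes the two
quantities the tests care about analytically checkable:

- Between two populations whose compound drifts from the root are
  `F_X = 1 − Π(1 − F_branch)` and `F_Z`, with MRCA compound drift `F_A`,
  the expected Weir–Cockerham Fst is approximately
  `(mean(F_X, F_Z) − F_A) / (1 − F_A)` — the within-population allele
  correlation in excess of the between-population correlation.
- A pulse at proportion f moves the recipient's frequency a fraction f of
  the way to the donor's, so f_d in pulse windows recovers f directly.

`make_camel_scenario()` uses the first identity to calibrate its branch
drifts so realized pairwise Fst lands in the ranges reported for the real
128-genome panel: dromedary–Bactrian 0.54–0.64, wild–domestic 0.27–0.31,
IRAN–other domestics 0.05–0.06. Working backwards: the dromedary compound
drift is 0.67 and the Bactrian ancestor 0.30, putting dromedary–Bactrian
means near 0.57–0.60; a wild branch of 0.32 and a domestic-ancestor branch
of 0.20 put wild–domestic near 0.28; and terminal domestic drifts of about
0.055 compound (IRAN 0.055; KAZA/RUS 0.015 + 0.04; MG/IMG/XJ
0.015 + 0.015 + 0.025) put IRAN–other near 0.054 while keeping the
within-East-Asian distances smaller, with IRAN the earliest-splitting
domestic. These values were fixed from the calibration algebra and are not
tuned afterwards. Default pulses send dromedary ancestry into IRAN, KAZA
and RUS at f = 0.05 — inside the 1–10% proportion reported for the real
panel — in a deterministic subset (default one window in five) of the
100 kb windows, so window occupancy is exactly known.

Genotypes are Binomial(2, p) per individual and site, with independent
Bernoulli missingness (default 2%), per-site QUAL ~ N(60, 15²) and RMS
MQ ~ N(45, 5²) floored at 1, summed DP ~ Poisson(10 per sample), and
ref/alt pairs drawn so the expected Ts/Tv equals 2.44 — the post-filter
ratio of the real panel. These covariate models exist to exercise the
filters, not to mimic a particular sequencer. Sites are evenly spaced
(default 100 bp) so window occupancy is deterministic.

Determinism: `simulate_frequencies` seeds the R generator from the config
seed and draws, in order, the ancestral frequencies and then one Beta block
per branch in tree-row order; `sample_genotypes` uses seed + 1. The
pipeline fans one master seed out to its stages by fixed offsets, so a
rerun reproduces byte-identical artifacts.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium and recombination (sites
are exchangeable within windows, so jackknife blocks are more independent
than real 10 kb blocks and real-data Z-scores will be noisier); continuous
or ancient migration (only instantaneous post-drift pulses; a
coalescent-with-migration history would spread donor ancestry more
diffusely than the sharp window boundaries here); selection; and
sequence-level error processes. The migration-band helper
`total_migration_rate(m, tau_m) = m·tau_m` is provided for summarizing
continuous-migration analyses run elsewhere, but the generator itself
cannot produce such histories.

## Numerical and degenerate-input choices

- MAF uses all samples jointly over non-missing alleles; "individuals with
  missing genotypes" counts half-calls as missing. Both follow standard
  tooling where the published criteria are silent.
- r² for LD pruning is the squared Pearson correlation of genotype dosages
  with pairwise-complete observations (no haplotype phasing is assumed);
  ties in the greedy scan drop the later variant.
- Sites where any quartet group has zero called alleles are excluded from
  that window's D/f_d sums; all-missing frequency cells are NA with n = 0.
- `select_neutral_loci` offers random placement (sorted uniform candidates
  accepted greedily under the 30 kb gap) and deterministic earliest-fit
  packing, which realizes the maximum locus count; both respect merged
  exclusion intervals.
- Classical MDS drops axes with negative eigenvalues (warning) but keeps
  zero-eigenvalue axes as zero coordinates; each axis's first nonzero
  loading is made positive so coordinates are sign-deterministic.
- NJ branch lengths below zero are clamped to zero with a warning; the
  distance input must be symmetric to 1e-9.

## Problem sizes used in the tests

The shipped test-suite scenarios use one 10 Mb chromosome with 1e5 evenly
spaced sites (100 non-overlapping 100 kb scan windows of ten 10 kb blocks
each), 20 diploids per population, pulse proportion 0.2 in 20 of the 100
windows for recovery checks, and a 5e4-site panel with 80 spaced 10 kb
windows × 100 replicates for the bootstrap-phylogeny checks. These sizes
keep each property estimable with comfortable statistical margin (e.g.
roughly a thousand sites per scan window) while the whole suite runs in
well under a minute per heavy scenario on one CPU.

## Known limitations

Beyond the generator's simplifications listed above: the scan assumes the
quartet topology is correct and its groups are fixed panel-wide;
frequencies, not genotype likelihoods, enter every statistic, so low-depth
uncertainty is not propagated; the Fst distance is not transformed
(no Reynolds/Slatkin linearization), matching the source convention at the
cost of distances that saturate for deep splits; and bootstrap support is
attached to the full-data NJ topology, so splits absent from it are only
visible in the returned consensus tree.
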