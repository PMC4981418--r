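---
title: "Detecting allopolyploid origins from ITS additivity and plastid haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allopolyploid origins from ITS additivity and plastid haplotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allohex)
```

## The inference problem

An allopolyploid arises when two species hybridize and the hybrid doubles
its chromosome set, so its nucleus carries subgenomes from both parents.
Two classical molecular witnesses of such an origin are:

* **Nuclear ribosomal ITS.** The internal transcribed spacers sit in rDNA
  arrays with thousands of copies. A fresh hybrid carries both parental
  copy types, and a direct Sanger read shows *both* parental bases
  superimposed wherever the parents differ — recorded as IUPAC ambiguity
  codes (Y, R, W, K, M, S). Over generations, concerted evolution
  (gene conversion and unequal crossing over) homogenizes the arrays,
  usually toward one parent, gradually erasing this additivity.
* **Chloroplast DNA.** Plastids are maternally inherited in most
  angiosperms, so the cpDNA haplotype of a hybrid identifies its seed
  parent.

`allohex` implements the full inference chain for a
diploid × tetraploid → hexaploid system: diagnostic-site detection between
the parental groups, per-ribotype additivity scoring and homogenization
classification (including chimeric, fully homogenized recombinants), indel
coding and statistical-parsimony haplotype networks for the plastid side,
group nucleotide diversities, and a seeded synthetic-data generator that
makes every stage testable without external data.

## Data model

An alignment is a rectangular character matrix over
`A C G T`, the IUPAC ambiguity codes, and the gap `-`, with a per-sequence
group label: `parentA_diploid`, `parentB_tetraploid`, `hybrid_hexaploid`,
`outgroup` or `unassigned`. All coordinates are 1-based alignment columns.
Identical residue strings — ambiguity codes and gaps included — form one
*ribotype* (nuclear) or *haplotype* (plastid): a direct-sequence consensus
with a distinct intraindividual polymorphism pattern is evidence of a
distinct array composition, so it is a distinct type.

```{r}
aln <- alignment(c(d1 = "ACGTACGT", d2 = "ACGTACGT", hx = "ACGTRCGT"),
                 group = c("parentA_diploid", "parentA_diploid",
                           "hybrid_hexaploid"))
collapse_ribotypes(aln)$table
```

## Diagnostic sites and additivity

A column is *diagnostic* when the IUPAC-expanded state sets of the two
parental groups are disjoint. The group-wide set union is used rather than
a consensus because parental ribotypes themselves may segregate ambiguity
codes; a column where one diploid shows `Y = {C,T}` and the tetraploids
show `T` cannot attribute a hybrid's `T` to either side and is excluded by
the disjointness rule itself. Columns with any parental gap or `N` are
excluded: the diagnostic set is substitution-based, and indels are handled
separately.

Each hybrid state at a diagnostic column is classified by
`classify_site_state()`:

* **additive** — the observed set intersects both parental sets. The
  default is this permissive test rather than strict equality to the
  two-state union, because direct-sequence peak calling is noisy and
  homogenization is partial; `strict = TRUE` additionally rejects observed
  sets containing a third state.
* **parentA_like / parentB_like** — the observed set is contained in one
  side.
* **inconclusive** — a third state, or missing data. A hybrid-private
  mutation at a diagnostic column therefore counts as inconclusive, not as
  evidence for either parent.

`score_ribotype()` aggregates the calls. With `D` diagnostic sites and
`n_additive` additive calls, the category is

* `fully_additive` if `n_additive / D >= additive_threshold` (default
  0.9). The threshold separates "complete or nearly complete" additivity
  from partial homogenization; sequences one or two conversions short of
  complete additivity are biologically equivalent to a fresh hybrid.
* `fully_homogenized` if `n_additive = 0` and all parental calls fall on
  one side — concerted evolution has erased one copy.
* `chimeric` if `n_additive = 0` but both sides are represented: a
  homogenized recombinant that fixed different parental states at
  different sites.
* `partially_homogenized` for intermediate additivity, and `unclassified`
  when no parental signal is interpretable.

The homogenization *direction* is the side holding the majority of
non-additive parental calls; exact ties give `none` and raise a flag in
the report rather than an arbitrary choice.

```{r}
parents <- alignment(c(dip = strrep("A", 10), tet = strrep("G", 10)),
                     group = c("parentA_diploid", "parentB_tetraploid"))
prof <- diagnostic_sites(parents)
score_ribotype(paste0(strrep("R", 7), strrep("G", 3)), prof)
```

The estimator connecting this scan to the generator is the mean additivity
loss `mean(1 - n_additive / D)` over hybrids, which recovers the per-site
conversion probability.

## Indels: inventory, simple coding, A/T recoding

Chloroplast spacer variation is rich in indels of very different lengths.
Treating each gapped column as a character would weight a 385-bp deletion
385 times more than a 1-bp one, so indels are scored by *simple indel
coding*: each distinct maximal gap extent (identical start and end) is one
binary presence/absence character; a sequence whose own longer gap
strictly contains a shorter extent is *inapplicable* (`?`) for it, since
the shorter indel cannot be observed inside a larger deletion. Terminal
gaps are missing data (incomplete reads, not deletions) and produce no
character — the convention standard in practice.

For network building, each binary character is appended to the alignment
as one pseudo-nucleotide column (`1 -> T`, `0 -> A`, `? -> N`). The step
counter skips gaps, `N` and ambiguity codes, so the original gap columns
are invisible and every indel contributes exactly one mutational step
regardless of length.

Before any of this, mononucleotide repeats are masked:
`mask_mononucleotide_repeats()` removes every column falling inside a
homopolymer run of at least `min_run` residues (default 8) in *any*
sequence, gaps inside the run not breaking it. Replication slippage makes
homopolymer length variation highly homoplastic, and its length noise
would otherwise masquerade as indel characters. The removal is
column-wise, keeping the alignment rectangular; the removed ranges are
reported. The threshold of 8 targets the long poly-A/T stretches that
dominate slippage noise while leaving short runs informative; it is a
configurable default, and whether per-sequence trimming would ever be
preferable is deliberately left to the masking report rather than decided
silently.

## Statistical-parsimony networks

Haplotypes are connected TCS-style: all pairs one step apart first, then
at increasing distance *d* up to the connection limit, pairs in distinct
components are joined through chains of *d* − 1 inferred (unsampled)
intermediate haplotypes. All equally parsimonious alternative connections
arising at the joining distance are retained, so loops are possible; they
are flagged and never broken automatically, because any loop-breaking
criterion (frequency, topology) injects assumptions the data do not
contain.

The *connection limit* is the largest step count *j* for which the
probability of parsimony exceeds 95%. That probability — the chance that
*j* observed differences over *m* compared sites reflect exactly *j*
substitutions, with no superimposed change anywhere — is computed under an
explicit model: per-site substitution counts are Poisson with mean *b*
under Jukes–Cantor, *b* moment-matched to the observed divergence
*j*/*m* through the saturation curve
H(b) = 3/4 (1 − e^(−4b/3)). Conditioning on the observed pattern
factorizes over sites and gives

P(parsimony) = (b e^(−b) / H)^j × (e^(−b) / (1 − H))^(m−j).

Single-step connections are always accepted (a lone difference is taken at
face value), so the limit is at least 1, and it is non-decreasing in *m*.
The computed limit is recorded in every report, and `fixed_limit` lets the
user bypass the calculation for reproducibility across tools. The test
suite cross-checks the probability against an independent Monte-Carlo
simulation of the same model; agreement with any particular legacy
implementation of the calculation is not asserted.

```{r}
connection_limit(1184)
```

Ambiguity codes in haplotypes are treated as missing for step counting:
directly sequenced cpDNA is effectively haploid, so an ambiguous plastid
base is a read artefact, not information.

## Distances and diversities

`p_distance()` is the uncorrected proportion of differing sites with
pairwise deletion of gap/`N` columns. Ambiguity codes are handled by two
policies: `average` (default) scores a column as the expected mismatch
between uniform draws from the two expanded state sets,
1 − |A∩B| / (|A||B|); `exclude` drops ambiguous columns entirely. The two
agree exactly on ambiguity-free input. Note that under `average` an
ambiguity code has positive expected mismatch even against itself — the
code asserts a mixture, not a state. No substitution-model correction is
applied: at the sub-2% divergences where this analysis operates, the
correction would be far below the sampling noise.

Group diversities are unweighted means over within-group pairs or over
cross pairs, computed at ribotype level (one representative per type), so
abundant types do not dominate — matching how sequence-type diversity is
conventionally reported.

## The synthetic generator

`synth_params()` fixes the study conditions; the defaults encode the
system the package targets: 624 ITS columns, 37 planted diagnostic sites
between the clades (≈ 5.9% fixed divergence), within-clade diversity 0.3%,
tetraploid maternal parent, per-site conversion probability `h = 0.9`
toward the maternal ribotype (most hexaploid ribotypes in such systems
are fully or nearly fully homogenized), and a 5% chance of a chimeric,
ambiguity-free homogenization outcome. Note the two divergence dials are
not independent: planting `n_diagnostic_target` fixed differences already
implies a between-clade p-distance of at least `n_diagnostic_target /
length`, so between-clade divergence is an emergent quantity, not a
parameter.

The ITS generator builds an ancestral sequence, plants the diagnostic
differences, adds Poisson private variation calibrated so the expected
within-clade pairwise p-distance equals `d_within` (each ribotype receives
on average `d_within × length / 2` private mutations), and composes each
hybrid from one maternal and one paternal ribotype with per-site
conversion. The cpDNA generator grows haplotypes on a bifurcating
genealogy split into a diploid and a tetraploid lineage — one to three
fresh SNPs per haplotype, occasional indels realized as gap runs, and
length jitter in a planted homopolymer — and hands every hexaploid a
tetraploid-lineage haplotype. Substitutions are uniform over the three
alternative bases: the downstream analysis is count-based, so a
transition/transversion bias would add realism without touching any
tested quantity. Ploidy dosage (four maternal vs two paternal genome
copies) is *not* modeled in peak calling: ambiguity is binary presence of
both variants, which is exactly what an IUPAC consensus records.

Every generator returns its ground truth (planted diagnostic columns,
per-site conversion outcomes, genealogy), sufficient to recompute every
expected report deterministically; identical seeds give byte-identical
output. What the generator does **not** emulate: alignment error, PCR
drift and chimera formation during amplification, rDNA copy-number
dynamics, within-spacer recombination, or base-calling noise. Passing
tests therefore demonstrate the *inference chain* is correct under the
stated model, not that direct Sanger consensus data are as clean as the
simulations.

## Synthetic reference panels

`synthetic_reference_its()` and `synthetic_reference_cpdna()` are
deterministic, fully synthetic stand-ins that encode the documented
summary structure of a real hexaploid study system: 29 ribotypes over 624
columns with 49 variable and 37 diagnostic sites, a fully additive
ribotype, a chimera that is diploid-like at columns 443 and 576 only, a
diploid-subgroup synapomorphy at column 529, and a 1254/1184-column
spacer panel with 7 ingroup haplotypes and 25 indels of 1–385 bp (4 of
them ingroup, 1–150 bp). They let the acceptance suite check that the
pipeline recovers a realistic result configuration end to end; because
the panels are constructed, these checks validate the detection code, not
the biological numbers.

## Numerical and edge-case choices

* Residues are stored upper-case; input is case-insensitive.
* `N` and `-` expand to the full base set but are flagged uninformative:
  they classify as inconclusive, are skipped in diagnostic-profile
  construction, deleted pairwise in distances, and missing for step
  counts.
* Ribotype ids are assigned in order of first appearance; all report
  tables have deterministic row order, so identical inputs give
  hash-identical bundles.
* Direction ties (equal parental call counts) give `none` plus a flag.
* Degenerate inputs fail loudly: ragged FASTA names the offending
  sequence, illegal residues report the column, singleton groups cannot
  request within-group diversity, duplicate haplotypes are rejected by
  the network builder, and all-gap columns after masking are dropped with
  a warning.
* `score_ribotype` with an empty profile returns `unclassified` rather
  than dividing by zero.

## Problem sizes in the test suite

The suite exercises: exhaustive oracle comparisons on alignments up to
5 × 20 (indel coding) and 5 × 30 (diagnostic sites); spanning-tree
enumeration up to 6 haplotypes; Monte-Carlo validation of the parsimony
probability at m = 40 sites with 60,000 draws; and parameter recovery
with 500 hybrids × 37 diagnostic sites × 20 seeds for each
h ∈ {0, 0.5, 0.8, 1}, requiring the estimator inside the binomial 95%
confidence band in at least 95% of runs. These sizes give stable
statistics while keeping the default test run fast.

## Limitations

* The additivity logic phases at most two underlying copy classes; a
  hexaploid carrying three distinguishable ITS variants is reported as
  whatever two-sided pattern its consensus shows.
* Maternal-lineage inference is shared-haplotype evidence, not a
  statistical test, and says nothing when hybrids and parents share no
  haplotype.
* The connection-limit probability is a plug-in approximation (divergence
  estimated from each pair itself); other statistical-parsimony
  implementations may differ by a step or two for the same alignment.
* Diversities are uncorrected p-distances; do not compare them against
  model-corrected values from other software without matching settings.
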