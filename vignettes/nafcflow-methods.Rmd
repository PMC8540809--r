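---
title: "Methods: linking culture transcriptomes to NAFC chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking culture transcriptomes to NAFC chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafcflow)
```

## The scientific problem

Oil sands process-affected water (OSPW) is acutely toxic to aquatic life,
largely because of naphthenic acid fraction compounds (NAFCs) — a diverse
family of organic acids with general formula $C_cH_hN_nO_oS_s$.
Environmental *Pseudomonas* isolates can degrade a subset of these
compounds, and the route to understanding (and eventually engineering) that
capability runs through two data streams: the transcriptomic response of
the cultures when NAFCs are the sole carbon source, and high-resolution
mass spectrometry of the water before and after treatment. `nafcflow`
implements the analysis chain that joins the two: it turns formulas into
chemistry (unsaturation, heteroatom classes), expression libraries into
per-organism transcript abundances, gene annotations into enzyme
complements, enzyme complements into candidate substrates and pathways, and
finally compares the inferred substrate spectra across cultures.

## Formula chemistry

Every downstream classification rests on three small definitions:

* **Double-bond equivalents.** $\mathrm{DBE} = c + \tfrac{1}{2}(n - h) + 1$.
  Divalent O and S contribute nothing. For odd $n + h$ the value is
  half-integral; such formulas correspond to radicals or ions and the value
  is returned unrounded so callers can flag them rather than have the
  package silently repair the input.
* **Heteroatom classes.** The $2^3$ presence/absence patterns of N, O and S
  give exactly eight classes — CH, N, NS, NO, O, NOS, S, SO — so
  `classify_nafc()` is a total function and is tested by enumeration over
  all patterns. Species labels drop zero counts and unit subscripts
  (`"N2O2"`, not `"N1O1"`); by petroleomics convention the SO class is
  spelt sulfur-first (`"SO2"`, `"S2O3"`).
* **Classic naphthenic acids.** $C_cH_hO_2$ exactly — two oxygens, no N or
  S. These are the most toxic sub-group and all removal percentages can be
  restricted to them.

Only C, H, N, O and S are accepted in formulas; any other element is an
error rather than being dropped, because a silently truncated formula would
be assigned a wrong class. Carbon content of NAFCs typically spans 7–26
atoms, but classic NAs down to C5 are observed in process water, so the
carbon-range check (`in_carbon_range()`) flags rather than filters.

## Expression summaries

Subtractive hybridisation libraries enrich up-regulated transcripts, so
the library content itself — after a coverage sanity filter — is treated as
the up-regulated gene set; no differential-expression test is involved.
The retention rule keeps a gene covered by **at least 150 bases or at
least 90% of its length** (a disjunction: short genes qualify through the
fractional clause). `compute_gene_coverage()` provides the interval-union
coverage computation (0-based half-open coordinates, BED convention) for
workflows that start from read alignments; it is backed by `IRanges` and
checked against a per-base marking oracle.

TPM is the standard length-normalised measure: $r_g = x_g/\ell_g$,
$\mathrm{TPM}_g = 10^6\, r_g / \sum_{g'} r_{g'}$, summing to $10^6$ per
normalisation group. For the co-culture library, which is aligned against a
composite two-genome reference, normalisation defaults to within
(library, strain): per-organism TPM stays comparable between a pure culture
and the same organism's share of the co-culture. Joint normalisation over
the composite gene set is available (`by_strain = FALSE`) since the choice
is genuinely open; both modes are exposed rather than hard-coded.

Between-culture comparison uses MA statistics per gene:
$M = \log_2\frac{t_{co}+\psi}{t_{pure}+\psi}$,
$A = \tfrac{1}{2}\log_2\left[(t_{co}+\psi)(t_{pure}+\psi)\right]$,
with pseudocount $\psi = 0.5$ TPM by default because subtractive libraries
routinely contain genes absent from one condition. The identity
$\log_2(t_{co}+\psi) = A + M/2$ holds exactly and is tested. Pathway
ranking counts member enzymes with $M > 0$ (or $< 0$), descending, with
lexicographic tie-break on pathway id so output is deterministic.

## Annotation consolidation and enrichment

GO-style terms from two annotation routes are merged as a per-gene union
with provenance (`merge_term_sets()` is commutative, associative and
idempotent). EC numbers from two sources are *cross-referenced*: the
default is the union with a per-record agreement flag, keeping recall while
preserving the evidence trail; strict intersection is one argument away.
Partial ECs (`1.1.-.-`) count toward the top-level enzyme-class table but
are excluded from reaction matching, where only a complete four-field EC
identifies a reaction. The enzyme-class table counts each *gene* at most
once per top-level class — the alternative (counting distinct ECs) is not
reported because multi-EC genes would otherwise inflate classes unevenly.

Over-representation uses the upper-tail hypergeometric test
$P(X \ge k)$ with parameters $(N, K, n)$ and Benjamini–Hochberg adjustment,
performed within each ontology class (BP, MF) when an `ontology` column is
present. The headline `gene_ratio` is $k/K$ — over-expressed genes with the
term relative to genome genes with the term — which differs from the more
common $k/n$; both are emitted (`gene_ratio`, `gene_ratio_de`) so either
convention can be read off directly.

## Substrates, class distributions and pathways

Reaction, compound and pathway databases are local flat files (TSV/CSV and
JSON) with the same shape as MetaCyc/PubChem-style exports, read through
dedicated loaders, so analyses are reproducible offline and real exports
can be swapped in. Only reaction *substrates* are fetched; reversibility is
out of scope. ECs with no reaction are reported in a side list, never
silently dropped.

Class distributions count *distinct compounds* per class — a compound
reachable through several enzymes is counted once. Two distributions are
compared with Pearson's chi-square on the $2 \times k$ table, without
continuity correction; zero-total classes are dropped beforehand (df is
$k-1$ over retained classes), and expected counts below 5 yield a warning,
not a failure. A descriptor-based filter hook (`filter_substrates()`:
carbon range, DBE range, required heteroatoms) is provided with all
filters off by default, because the descriptor set used in practice varies
between instruments and studies and no single default is defensible.

Pathway inference interrogates every (compound, enzyme) pair against the
pathway step sets; each input pair lands in exactly one of the *with* and
*without* outputs (a partition, property-tested). The presence matrix is
reported over four heteroatom panels — N+NO, O, NOS, S+SO — with CH and NS
routed to a residual panel rather than dropped. Presence requires at least
one supporting pair by default (`min_hits` is configurable since a stricter
threshold is equally defensible); it is monotone in the hit set.

## What the synthetic-data generator emulates

`generate_fixture()` produces a fully self-contained bundle — gene catalog,
per-library coverage and counts, two-source annotations, the three
chemistry databases, and before/after MS tables — plus a manifest of every
planted fact, so each stage's output can be checked against an independent
expectation. The defaults define the study conditions:

* **Two strains, three cultures** (two pure, one 1:1 co-culture), 200
  genes per strain of 0.3–3 kb, 25% of genes up-regulated per culture, and
  half of each pure-culture up-set shared with the co-culture.
* **Coverage** planted at ≥ 92% of gene length for up-regulated genes and
  ≤ 120 scattered bases otherwise, so the retention rule recovers the
  planted sets exactly.
* **Enzymes**: 60 complete ECs per culture, three to five substrates each,
  substrate classes drawn independently per compound. Per-culture EC sets
  are disjoint and attached to culture-exclusive genes so the two samples
  entering each chi-square comparison are independent — the test's
  assumption holds by construction in the generator's null. This sizing was
  fixed by a design-stage power analysis: with ~240 independent substrate
  draws per culture the planted pure-vs-co-culture shift is detected with
  power near 0.95 while the null rejection rate stays at the nominal 5%.
* **The planted shift** mirrors the qualitative biology being emulated:
  the co-culture's substrate spectrum concentrates further into O and NO
  (sampling probabilities 0.75 → 0.84 for O+NO) and loses the S and SO
  classes almost entirely.
* **Chemistry tables**: 131 unique classic NAs totalling 28.2 mg/L with
  carbon 5–25 and DBE 1–10 (sampling weights peaked at C16 and DBE 4),
  removal planted at 11%, 12% and 31% of the classic-NA total for the two
  pure cultures and the co-culture; species S, N2S3, NOS2 and N2OS2
  completely removed; species O7, O8, N2O2 and S2O3 produced only after
  treatment. Note that exact per-carbon population shares above ~8% cannot
  be planted for *unique* classic-NA formulas: a fixed carbon number admits
  at most ten distinct formulas within DBE 1–10, so the generator plants a
  peaked distribution and records the realised histograms in the manifest.
* **Noise**: concentrations carry multiplicative log-normal noise
  (sd 0.1 on the log scale); "planted removal" is defined on the classic-NA
  *total*, which is rescaled to the planted fraction exactly, so removal
  percentages are recovered exactly while individual compounds vary.
  Truncation to positive values is inherent to the log-normal. No noise
  model is claimed to match a real Orbitrap run; this is a documented
  stand-in.

One root seed drives the whole bundle through per-section derived seeds, so
the same seed yields byte-identical files and adding a section does not
perturb the others. `null_fixture()` switches every planted effect off
(shared class-generating process, no fold-changes, no removal, no
removed/produced species) and is the basis of the type-I calibration.

### What passing tests do and do not show

The generator plants clean, well-separated effects: disjoint enzyme
complements, exactly recovered gene sets, noise-free class assignments.
Real data violate all of these — enzymes are shared between cultures,
coverage filters are imperfect proxies for expression, EC annotation is
noisy, and reaction databases are incomplete. Fixture recovery therefore
demonstrates that the *computations* are correct and calibrated, not that
the workflow's biological inferences on real data are correct; the
statistical calibration shows the chi-square machinery behaves nominally
when its independence assumptions hold, which on clustered real data they
may not.

## Numerical choices and problem sizes

Tolerances: TPM mass is checked to $10^{-3}$ in $10^6$; MA and chi-square
identities to $10^{-9}$; exact-arithmetic recoveries to machine precision.
Test problem sizes — 1,000 random compositions for the DBE oracle, 200
random interval instances, the full $(N \le 12, K, n, k)$ hypergeometric
sweep, 500 random pair sets for the partition property, 200 tables for the
chi-square oracle, and 200 replicate fixtures each for type-I error and
power — were chosen so the whole suite exercises each property densely
while completing in a few minutes on a single core, which keeps the suite
practical to run on every change.

## Known limitations

* The workflow consumes alignment-derived tables; alignment itself,
  duplicate removal and SSH chemistry are out of scope.
* GO terms are used as flat sets (no DAG propagation), matching the merged
  flat annotations the workflow consumes.
* Pathway presence is qualitative; no gap-filling, flux or thermodynamic
  reasoning is attempted.
* Raw mass-spectral processing (peak picking, formula assignment from m/z)
  is upstream of this package; feature tables are inputs.
* The chi-square comparison treats compounds as independent draws; with
  real multi-substrate enzymes counts are clustered and p-values will be
  anticonservative. The calibration machinery in the test-suite is the
  tool for quantifying that on any alternative generator.
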