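---
title: "Discovering lincRNAs that act as miRNA targets or decoys: models and methods"
author: "lincmir developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lincRNAs that act as miRNA targets or decoys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincmir)
```

## The problem

Plant miRNAs silence transcripts through near-perfect antiparallel base
pairing, with cleavage of the target opposite miRNA position 10 (counting
from the miRNA 5' end). Long intergenic noncoding RNAs (lincRNAs) can enter
this regulatory layer in two ways:

* as **targets**: the lincRNA pairs almost perfectly and is cleaved, which
  leaves a degradome (PARE) signature — a pile-up of 5' read ends at the
  predicted cleavage position;
* as **decoys** (target mimics, eTMs, sponges): the lincRNA pairs well at
  the miRNA 5' region but carries mismatches or bulges at the central
  positions 9–12, so the silencing complex binds but cannot cut; the
  lincRNA sequesters the miRNA and de-represses its mRNA targets (the
  competing endogenous RNA, ceRNA, hypothesis).

`lincmir` implements this discovery pipeline genome-wide: complementarity
scanning with hybridization energies, a rule engine that separates targets
from decoys, degradome validation, binding-site conservation tests, network
assembly, and function transfer by co-expression (targets) or the ceRNA
rule (decoys). A synthetic-data module generates rule-conformant inputs
with known truth for every stage, and the test suite is built on those
truths.

## Duplex scanning and energies

The scanner aligns each mature miRNA antiparallel against each transcript
with a semi-global affine dynamic program (the miRNA must be fully covered,
the transcript ends are free): match +1, G:U wobble +0.5, mismatch −1, gap
open/extend −2/−1. These constants are this package's choice; the upstream
tools this stage emulates do not publish theirs. Every column of a
candidate alignment carries one `PairState` (`WC`, `GU`, `MISMATCH`,
`BULGE_MIRNA`, `BULGE_TARGET`).

Columns are stored 5'→3' along the **transcript**, so transcript positions
ascend while miRNA positions descend from L to 1. (An antiparallel duplex
cannot have both coordinates ascending; the display convention of the
standard plant target-prediction tools is followed.)

Each retained site is scored with a nearest-neighbor RNA/RNA hybridization
energy:

* stacking terms for adjacent paired columns from the Turner-lineage
  tables (Watson–Crick stacks after Xia et al. 1998, wobble-containing
  stacks after Mathews et al. 1999, in kcal/mol at 37 °C); the two
  destabilizing wobble–wobble motifs are clamped to zero so removing a
  stack can never make a duplex *more* stable — this preserves the
  mismatch-monotonicity property the tests assert;
* a duplex initiation penalty (+4.09) and terminal A:U/G:U penalties
  (+0.45 per end);
* simplified length-dependent penalties for bulges (3.8/2.8/3.2/3.6/4.0/4.4
  for 1–6 nt, log-extrapolated beyond) and internal loops
  (1.5 + ~0.3 per nt plus an asymmetry term). No stacking is applied across
  a defect.

Three statistics summarize each site: `MFEsite` (energy of the observed
alignment), `MFEperfect` (energy of the miRNA against its exact reverse
complement) and `MFEratio = MFEsite / MFEperfect` ∈ (0, 1]. Bit-exact
agreement with RNAhybrid is *not* a goal — the published per-site energies
depend on that program's internals — but the ratio arithmetic reproduces
published worked examples to machine precision, and the ordering
properties (GC-rich more stable than AU-rich, defects never stabilizing)
hold by construction.

**Retention cutoff.** Sites with `MFEratio < 0.65` are discarded by
default. The source study never states the cutoff its scan used, but the
smallest ratio in its printed target and decoy tables is 0.6506, consistent
with a 0.65 floor; the parameter is configurable (`scan_params()`).
Overlapping candidate sites are collapsed to the best ratio (ties to the
smaller start) unless `report_overlapping = TRUE`.

## The target/decoy rule engine

Diagnostics are counted over miRNA-position regions, with position 1 the
miRNA 5' end:

* **target**: at most one mismatch/indel at positions 9–12; bulged
  nucleotides plus mismatches elsewhere at most 4; no two consecutive
  mismatch columns anywhere in the alignment (the no-continuous-mismatch
  clause is enforced globally, since the published wording does not
  restrict it to a region);
* **decoy**: 2–5 mismatches/indels at positions 9–12; perfect pairing at
  positions 2–8 with no adjacent indel; at most 4 mismatches/indels in the
  remaining regions (position 1 and 13..L — each position belongs to
  exactly one clause).

Conventions this package fixes where the source is silent:

* an unpaired transcript base between miRNA positions *i* and *i+1* is
  assigned to the region containing *i* (the 5'-ward flank); an insertion
  3' of the last miRNA position is outside the duplex and undefined;
* "no adjacent indel" for the 2–8 clause means no bulged transcript base
  at junctions 1–8 and no indel at positions 2–8;
* multi-nucleotide bulges count one defect per nucleotide (the published
  "not allowed to exceed 4 nt" phrasing suggests per-nucleotide counting);
* G:U wobbles are pairs, not defects (`gu_counts_as_pair = FALSE`
  reverses this everywhere, including mismatch-run counting).

Because the central thresholds (≤1 vs ≥2) are disjoint, no alignment can be
both target and decoy; the acceptance suite proves verdict correctness by
exhaustive enumeration of all ~40.8 million placements of up to six defects
of three types on a 21-nt duplex against an independently coded clause
checker.

## Degradome validation

Reads are adapter-clipped (first exact occurrence of the adapter's first
8 nt — the published preprocessing description is ambiguous, so a simple,
configurable rule is frozen), length- and N-filtered, and deduplicated with
counts. Every exact full-length occurrence of a unique read contributes its
count at the occurrence's 5' position (multi-mapping reads count at every
occurrence; CleaveLand-lineage tools vary here and a restriction flag would
be a one-line change).

At the predicted cleavage position (transcript base opposite miRNA
position 10, with a 9–12 window fallback when position 10 is unpaired or
silent) the signal is ranked into the five CleaveLand-style categories,
with `a` the abundance there, `M` the maximum and `med` the median over
occupied positions: `a == 1` → 4; unique maximum → 0; tied maximum → 1;
above the median → 2; at or below → 3.

The p-value is a transparent positional-empirical scheme — the fraction of
transcript positions whose category would be at least as good — **not** a
reproduction of the modified CleaveLand4 model the source study used,
whose details are unpublished; printed p-values are therefore out of
reproduction scope, while categories and peak positions are fully testable
on synthetic truth.

## Conservation

A 100-nt window is centered on each binding site (floor/ceil split of the
remainder; windows are shifted, not truncated, at transcript ends). The
homology search is a seed-and-extend scan (exact 7-mers, both strands,
match +1 / mismatch −2) with Karlin–Altschul E-values
(`E = K·m·n·exp(−λS)`, λ = 1.28, K = 0.46, the published ungapped DNA
constants for +1/−2 scoring) and an E < 0.1 cutoff. The extension computes
the *optimal* ungapped segment on the seed diagonal — equivalent to X-drop
extension with an infinite drop threshold — which makes the brute-force
window oracle in the test suite an exact equivalence, not an approximation.
An external BLASTN can be substituted; E-values will then follow that
program's statistics.

Multiple alignment is an internal progressive global aligner
(match +1 / mismatch −1 / gap −2, join order by identity to the reference);
an external command (e.g. MAFFT with `--maxiterate 1000 --localpair`) can
be parsed instead. Site identity is the mean per-column fraction of
non-reference rows matching the reference base (gaps never match), and a
site is conserved when that mean exceeds 0.80 — the averaging convention is
this package's choice, with flank identity reported alongside so both the
site-only and site+flank readings are available.

## Co-expression and function transfer

Genes are filtered to the top 75% by expression variance (ties by input
order). For every lincRNA–mRNA pair the Pearson correlation and the Fisher
z-transform asymptotic p-value `2(1 − Φ(atanh(r)·√(n−3)))` are computed
(r clamped to ±(1−10⁻¹⁵)), Bonferroni-adjusted over the number of pairs
actually computed. Edges require `p_adj < 0.05` **and** a correlation in
the top or bottom 5% of the computed pair distribution — the conjunction,
as the source describes both filters. GO over-representation is the
one-sided Fisher exact (hypergeometric upper-tail) test with Bonferroni
over tested terms; annotation is taken as given (no DAG propagation).
Targets inherit the enriched terms of their co-expressed mRNAs; decoys
inherit the terms of every mRNA targeted by any miRNA the decoy
sequesters (the ceRNA rule).

## The synthetic world

The generators state the conditions the tests probe; their defaults are
frozen and are not tuned against outcomes:

* backgrounds are uniform over {A, C, G, U} with geometric-ish lengths
  around 500 nt (no GC skew or isoform structure — enough for rule and
  statistics testing, not a transcriptome simulator);
* target implants are perfect (0-defect) sites; decoy implants are either
  a contiguous 2–3 nt bulged-target insertion at a central junction (the
  classic eTM structure) or two adjacent central mismatches. Mismatch
  substitutions pick a base that pairs with the miRNA base neither
  Watson–Crick nor wobble, so an intended defect cannot silently become a
  pair. Because a reported decoy is, by definition, a site the scan
  retained, the generator verifies at construction that the implant's
  MFEratio clears the 0.65 floor with a 0.03 margin and redraws the
  miRNA/defect pattern otherwise — without this, an occasional AU-rich
  draw produces a rule-conformant site just under the floor, which is a
  property of the energy model, not of the rules;
* degradome libraries plant 10 reads exactly at each predicted cleavage
  position plus 20 uniform background reads per carrying transcript
  (a 10:1 peak:noise design);
* expression modules share a latent factor with loading √r so the expected
  within-module correlation is r = 0.9 at n = 30 samples; values are
  shifted to a non-negative FPKM-like scale (50 + 10z, clamped at 0),
  which preserves Pearson correlations, unlike exponentiation;
* ortholog windows substitute site columns at 5% and flank columns at 40%,
  emulating the conserved-site/divergent-flank structure;
* GO annotations give every module gene its module term plus background
  terms at a 2% rate.

A green test on this world establishes that the machinery recovers known
truth under stated noise; it does not establish performance on real maize
data, which additionally involves quantification noise, shared miRNA
family sites, and non-uniform base composition.

## Numerical choices and degenerate inputs

* MFEratio is an exact floating-point division; published worked examples
  reproduce to better than 1e−12 relative error.
* Scan output ordering is deterministic: ratio descending, then site start
  ascending; DP tie-breaking is fixed by the order of state comparisons.
* Empty networks, empty enrichment results, and header-only exports are
  well-defined; profile positions with zero reads yield *no* cleavage
  evidence rather than a category.
* All generators take explicit seeds and restore the caller's RNG state;
  the pipeline derives stage seeds from one run seed.

## Known limitations

* Energies are a simplified Turner-lineage model: no intramolecular
  folding/accessibility, no dangling-end terms, simplified loop penalties.
  Absolute kcal/mol values are not comparable to RNAhybrid output beyond
  ordering.
* The degradome p-value model is this package's own transparent scheme.
* The miRBase release-21 worked numbers (321 zma matures, 203 after
  merging) require the real miRBase file, which cannot be shipped; the
  acceptance test for that criterion runs only when the file is provided
  locally.
* Conservation E-values use fixed ungapped constants; gapped BLAST
  statistics are out of scope.
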