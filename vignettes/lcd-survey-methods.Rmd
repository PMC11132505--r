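---
title: "Surveying low-complexity domains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying low-complexity domains: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdscope)
```

This vignette is the package's own account of its methods: what is
computed, why the defaults are what they are, which conventions were
genuinely open choices, and what the synthetic-data validation does and
does not demonstrate about real proteomes.

## The compositional model of a low-complexity domain

A low-complexity domain (LCD) is operationalized compositionally, not
by entropy or repeat structure: a region is an LCD of class "X" when a
sliding window repeatedly finds amino acid X at high local
concentration, spread across the window rather than collapsed into one
clump. Three parameters define a class search:

* **Window size `window` (residues, default 20).** Small enough to
  resolve domains near the scale of short functional tracts
  (poly-Q stretches, H-rich patches), large enough that a 40%
  composition is an 8-of-20 event rather than noise. Windows slide with
  unit step; sequences shorter than the window yield nothing.
* **Composition thresholds `primary_threshold` (fraction, default
  0.40) and `secondary_threshold` (default 0.20).** A primary class
  ("Q") requires only the first; an ordered secondary class ("HQ")
  requires 40% H *and* 20% Q in the same window. Class order is
  positional: "HQ" and "QH" are distinct searches, and the realized
  secondary composition may exceed the primary one — only the
  thresholds are asymmetric. Threshold pairs summing over 100% are
  rejected at configuration time as unsatisfiable. With 20 amino acids
  this yields 20 primary + 380 secondary = 400 classes, the fixed key
  order of every signature in the package.
* **Dispersion threshold `dispersion_threshold` (default 0.5).**
  Composition alone cannot distinguish a genuine compositionally biased
  tract from a window that happens to straddle one dense clump. The
  linear dispersion statistic (below) must reach 0.5 for each searched
  amino acid separately.

All threshold comparisons use a `1e-9` tolerance so exact-boundary
compositions (8/20 against 0.40) pass deterministically on every
platform.

Overlapping or directly abutting passing windows are merged into one
contiguous LCD reported with 1-based inclusive coordinates and the
composition of the merged span. Merged spans are **not** re-validated
or trimmed: every constituent window passed, and the merged composition
may legitimately fall below the window threshold (a point the README's
worked example illustrates).

## The linear dispersion statistic

The dispersion of amino acid X in a window of length $W$ containing
occurrences at positions $p_1 < \dots < p_k$ is

$$\mathrm{disp} = 1 - \frac{\sigma(g)}{\sigma(g_{\max})},\qquad
g = (p_2-p_1,\; \dots,\; p_k-p_{k-1},\; W - p_k + p_1),$$

where $g$ is the *circular* gap vector (the $k-1$ internal gaps plus
the wrap-around gap, always summing to $W$) and $g_{\max}$ is the gap
vector of the fully clustered arrangement ($k-1$ unit gaps and one gap
of $W-k+1$). By convention the statistic is 1 when $k < 2$ or when the
window is a homopolymer ($k = W$).

The circular convention was a genuine design decision. The requirements
are: exactly 1 for evenly spaced occurrences, strictly decreasing as
occurrences cluster, bounded in [0, 1], and normalized by the most
clustered arrangement of the same occurrence count. Internal gaps alone
cannot satisfy them — a contiguous run has all internal gaps equal to
1 and hence standard deviation 0, the same as perfect even spacing.
Anchoring gaps to the window boundaries breaks exactness for periodic
patterns ("AGAGAG…" has unequal first and last boundary gaps). The
circular gap vector satisfies all four requirements exactly: periodic
occurrences give identical gaps regardless of phase, and a one-clump
arrangement is provably the maximum-variance gap vector for fixed $k$
and $W$ (all slack in one part). The statistic is exposed behind the
single function `linear_dispersion()`, so an alternative convention can
be swapped in without touching the scanner, and the test suite pins the
current convention against a brute-force enumerator of all
$\binom{W}{k}$ placements.

## Scrambled-proteome null model

Whether an organism has "many" Q-rich LCDs is meaningless without a
composition-matched reference. The null proteome is built by removing
each protein's initiator residue, pooling all remaining residues in
protein order, applying one seeded Fisher–Yates shuffle (R's
Mersenne-Twister generator; the seed is recorded in the result),
re-segmenting into the original protein lengths, and prepending each
initiator. This preserves the protein count, every protein length,
every first residue and the whole-proteome residue multiset — so any
excess of LCD-containing proteins in the real proteome reflects residue
*arrangement*, not composition. Conservation is asserted in the test
suite on every run.

Per class, the 2×2 table (original with/without an LCD-containing
protein vs scrambled with/without) is tested with a two-sided Fisher's
exact test. Two-sidedness was an open choice: the survey reports both
enrichment and depletion, so the symmetric test is the natural default,
and a one-sided alternative remains available through the
`alternative` argument. The p-value is computed directly from the
hypergeometric mass function (sum of all tables no more probable than
the observed one, with the conventional $1+10^{-7}$ relative
tolerance); the suite cross-checks it against both an exhaustive
`choose()`-based enumeration and `stats::fisher.test`.

Classes with zero LCD-containing proteins in *both* proteomes are not
testable; they are excluded from multiple-test correction but retained
in summaries as not significant. Correction across the represented
classes uses the step-down Holm–Šidák form
$\tilde p_{(i)} = 1 - (1-p_{(i)})^{m-i+1}$ with a running maximum —
implemented by hand because `p.adjust` offers Holm–Bonferroni, not the
Šidák variant. The effect size is $\ln \mathrm{OR} = \ln(ad/bc)$ with
the Woolf 95% CI $\pm 1.96\sqrt{1/a+1/b+1/c+1/d}$. When either
with-LCD cell is zero, 1 is added to **all four** cells and the
estimate is flagged `biased`; the without-LCD cells never trigger the
pseudocount (they are proteome-scale counts). Because the zero cell is
almost always on the scrambled side, the bias is conservative —
enrichment is understated, never invented.

## Descriptive statistics conventions

* **Per-residue occupancy** counts each residue at most once per class
  (interval union over a protein's LCDs of that class), so occupancy
  can never exceed 100% however many overlapping domains exist.
* **Domain-level mean occupancy** is the unweighted arithmetic mean
  over organisms of per-organism occupancies, not a residue-pooled
  ratio. The two differ whenever proteome sizes differ; the
  per-organism mean is the documented, test-pinned choice.
* **Rarity bins** follow the printed inequality signs exactly:
  absent ($x = 0$), very rare ($0 < x < 5$), rare ($5 \le x < 20$),
  normal ($20 \le x < 50$), common ($50 \le x < 75$), very common
  ($x \ge 75$); the bins partition [0, 100] with no gaps.
* **Eukaryote-specific classes** use strict inequalities on both sides
  (> 15% of eukaryotes, < 2% in each other domain, evaluated
  independently), so the boundary values 15.0 and 2.0 are excluded.
* **Reciprocal merging** for co-occurrence reporting maps "CS" and
  "SC" to the canonical label "CS|SC" (alphabetical concatenation) —
  deterministic and order-free; the merged label is used even when only
  one of the pair occurs.
* **Spatial distinctness** of two LCDs on one protein means at least
  `min_outside` (default 20) residues of the second LCD lie outside
  the span of the first. The alternative reading — residues of the
  protein inside the other LCD — was considered and rejected; the
  chosen reading is pinned by tests and must not drift silently.
* **Pfam clan concentration** divides the largest single-clan count by
  the number of clan-annotated proteins only, and is undefined (NA)
  below 5 annotated proteins.

## GO enrichment

The ontology is read from OBO 1.2 (`[Term]` stanzas; `is_a` edges only;
obsolete terms skipped), annotations from GAF 2.x (NOT-qualified rows
skipped; accessions restricted to the proteome). Both parsers are
intentionally minimal and hand-written — no installed package reads
these formats here — and are exercised against hand-built fixtures.

Per LCD class, the study set is the proteins with ≥ 1 LCD of the class
and the population is the whole proteome. Three conventions were open
and are pinned as follows:

* **Sidedness:** one-sided toward enrichment (hypergeometric upper
  tail), because only enrichment is reported; two-sided is available
  by flag.
* **Correction:** single-step Šidák, $1-(1-p)^m$, with $m$ the number
  of terms tested — deliberately distinct from the Holm–Šidák used for
  the scramble test, preserving the two different correction families
  used for the two analyses.
* **Depth:** the longest `is_a` path from the namespace root (the
  convention commonly called "depth", as opposed to the shortest-path
  "level", selectable via `use_level`). Reporting is filtered to depth
  ≥ 4 to suppress non-specific terms, but filtered terms still count
  toward $m$ — the filter never alters a p-value.
* **Propagation:** annotations are direct-only by default;
  `propagate = TRUE` extends them to all `is_a` ancestors.

Cross-organism sharing emits, for every (class, term) pair significant
in at least one organism of a group, the percentage of the group's
organisms in which it is significant; pairs significant nowhere are
not emitted.

## Signatures, distances and clustering

Each proteome reduces to a 400-component occupancy signature in the
fixed class order. Percentile ranks within a cohort use the
self-inclusive midrank convention
$100\,(n_{<} + \tfrac12 n_{=})/n$ — symmetric under ties, and the
per-class cohort mean is exactly 50. Manhattan distance sums absolute
differences over the 380 secondary classes by default (the
higher-resolution part of the signature; the full 400-key variant is a
flag), and viral proteomes are excluded from distance matrices by
default because their tiny proteomes produce degenerate occupancies —
both defaults are overridable. Complete-linkage clustering delegates to
`stats::hclust`; the suite validates it against a naive agglomerative
reference via cophenetic distances, and trees export to Newick through
`ape` rather than any plotting.

## What the synthetic data emulate — and what they do not

The generator produces proteomes with i.i.d. residues from a chosen
background ("uniform"; "uniprot-like" average frequencies;
"falciparum-like" with strongly elevated N and K, emulating the
composition bias of an A/T-rich genome), initiator methionines, and
planted LCDs built by Bresenham-even interleaving of the target
residues. Even interleaving guarantees the dispersion criterion with a
wide margin whatever the dispersion convention, and the default planted
compositions (0.50 primary, 0.30 secondary) sit 0.10 above the search
thresholds, so planted-truth recovery is a sharp, deterministic
expectation rather than a statistical one. Study bundles plant a
domain-of-life structure (Q- and HQ-rich eukaryotes, sparser A-rich
prokaryotes, LCD-free viruses), one class–GO-term association at
ontology depth ≥ 4, and a single-clan Pfam map.

What passing these tests shows: the scanner, merger, counting,
enrichment, GO and signature machinery compute exactly what they claim
on inputs with known truth, including calibration of the null
(scramble-vs-rescramble significance stays at or below the nominal
rate, and unplanted classes stay quiet). What it does not show:
real proteomes are not i.i.d. — repeats expand by slippage, paralogous
families share domains, and annotation coverage is biased — so
sensitivity and specificity measured here are upper bounds for real
data, and the dispersion convention remains a documented stand-in
rather than a reproduction of any particular published scanner's
internals. Accession-level reproduction of published counts for
specific reference proteomes would additionally require the original
proteome versions and is out of scope here.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to make every property sharp at
desk scale: exhaustive scanner–oracle equivalence on 1,000 random
sequences (lengths 20–500) across 40 sampled classes and three
backgrounds; 100 planted fixtures for recall with boundary agreement
within one window; 50 seeded proteomes for scramble conservation;
every 2×2 table with total ≤ 60 for exact-test agreement (to 1e-12);
50 null–null scramble pairs for calibration; 20 seeds of a
1,000-protein, 5%-planted-HQ fixture for enrichment recovery; and 200
random matrices (n ≤ 12) for clustering equivalence. Degenerate inputs
have defined behaviour throughout: empty proteomes scan to empty
tables, length-1 proteins survive scrambling unchanged, all-zero
contingency tables and zero-denominator shares return undefined
markers (never silent zeros), and single-member groups have undefined
within-group mean distances.
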