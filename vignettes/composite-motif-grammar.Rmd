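---
title: "The SMAD composite-motif grammar: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SMAD composite-motif grammar: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smadscan)
```

## The biological model

SMAD transcription factors relay BMP and TGF-β signals to the genome. Each
SMAD carries an N-terminal MH1 domain whose β-hairpin reads a short DNA
element through a conserved arginine contacting a guanine at the element's
+1 position. The recognized elements are few and short: the classical SBE
(`GTCTG`), the palindromic GC-rich SBE (`GGCGCC`, "pGC-SBE"), its
non-palindromic relative (`GGCTCC`, "npGC-SBE"), the palindromic SBE
(`GTCTAGAC`, "pSBE"), and the 5GC family (`GGCGC`/`GGCCG`). A single
element, however, does not activate transcription. The unit this package
models is the *composite motif*: two elements separated by a short spacer,
engaged simultaneously by two MH1 domains of one activated SMAD complex.

Because each MH1 domain reads its element directionally from the +1
guanine, a pair of bound domains has a relative orientation determined
entirely by which strand carries each element:

* upstream element read on the minus strand, downstream on the plus strand
  — both +1 guanines flank the spacer on opposing strands: **back-to-back**;
* the converse — the domains face each other: **face-to-face**;
* both elements on the same strand: **face-to-back**.

Palindromic elements are readable on either strand, so a site contributes
every orientation its strand availability permits; the achievable mode set
of a composite is the union over strand assignments.

The responsiveness predicate distills the reporter-assay findings into
three rules. A composite is predicted BMP-responsive iff (i) the spacer is
exactly 5 bp — one base more or less abolishes the response; (ii) the
back-to-back mode is achievable; and (iii) the element pair is drawn from
{pGC-SBE, SBE} with at least one pGC-SBE. The fully antisense
heterocomposite (`CAGAC-N5-GGCGCC`) satisfies all three but responds only
weakly in cells, and is graded as its own `BMP_responsive_weak` class —
exactly one weak class, nothing finer (spacer base composition is reported
as profile output, never as a label). A pair of 5-bp-spaced pSBE motifs is
the one TGF-β-responsive configuration. Everything else — npGC-SBE- or
5GC-containing pairs, single elements however clustered, any non-5-bp
spacing — is predicted nonresponsive. Whether npGC-SBE/SBE heterocomposites
found in bound regions could respond was never reporter-tested; labeling
them nonresponsive is a modeling choice of this package, not an
experimental claim.

## Scanning and screening

`element_occurrences()` performs exact, strand-aware matching: degenerate
elements are expanded to concrete variants before matching, overlapping
instances are all reported, and a palindromic site is emitted once with
`strands = "both"` rather than twice — this prevents double counting in
screens. `scan_composites()` pairs instances at an exact gap (default 5 bp,
configurable 0–30+ so non-functional spacings can serve as negative
controls) and annotates each hit with spacer sequence, achievable modes and
label. Heterocomposite pairs are unordered by default (`A-N5-B` and
`B-N5-A` both count), with an `ordered` override.

`screen_regions()` applies the scan over a peak set (BED intervals plus a
genome or per-region FASTA): a region is positive for a composite class iff
it carries at least one hit of that class, and classes are counted
non-exclusively, mirroring per-class bar counts of bound-region screens.
Coordinates are 0-based half-open throughout; unresolvable regions become
error records and are excluded from totals rather than aborting the screen.
Lowercase (soft-masked) bases are uppercased and matched by default, with
an option to mask them instead; `N` never matches. Peak-annotation tools
differ (and are often undocumented) in how they deduplicate overlapping
matches and strand duplicates, so our policy — dedup by element pair and
the two start coordinates, palindromic sites counted once — is stated
explicitly and may yield counts that differ from other tools on the same
input.

## Linker profiling

`extract_linkers()` collects the 5-bp spacers of a hit set after an
orientation normalization: each locus is flipped, when necessary, so the
composite reads GC-element → spacer → partner on the plus strand (fully
antisense hits are likewise flipped). Some convention is required — a
mixed-strand hit set would otherwise average a spacer with its reverse
complement and scramble positional composition; this one anchors position
+1 of the spacer next to the GC element. `linker_profile()` gives exact
counts (pseudocount 0 by default; 0.5 optional for logo rendering), and
`position_information()` reports per-position information content
(`log2(4) + Σ f·log2 f` bits against a uniform background, the relative
entropy for a general one) plus a one-sided binomial test for guanine
enrichment (α = 0.01 per position) — the feature of interest being elevated
Gua at spacer positions +2/+3. Pooling linkers across composite classes is
the default; per-class profiles are obtained by filtering the hit table.

## Genomic annotation

`annotation_model()` builds promoter/UTR/exon/intron interval sets from a
class BED, a TSS list and chromosome sizes, with a −1000..+100 bp promoter
window (a common peak-annotation default; configurable). Regions are
classified by the feature containing their midpoint, ties broken by
precedence promoter > UTR > exon > intron, remainder intergenic; any-overlap
classification is available via `by = "any"`. `normalized_distribution()`
divides each class's share of positive regions by its share of the genome,
so proportional placement scores 1.0 — comparisons against a specific
genome build's annotation database are out of scope and no hg38 data are
bundled.

## Hill fitting

Fraction-bound titrations are fitted to `Y = Bmax·X^h/(Kd^h + X^h)` with
box constraints (Bmax ∈ (0, 1], Kd > 0, h > 0) enforced by bounded
Levenberg–Marquardt least squares, not by reparameterization, so standard
errors are reported on the natural scale. Initialization: Bmax₀ = max(Y)
clipped to (0, 1], Kd₀ = the concentration whose response is nearest
Bmax₀/2, and a deterministic multi-start over h₀ ∈ {0.5, 1, 2} with the
lowest-RSS fit retained — steep curves fitted from a single shallow start
can otherwise stall with Bmax pinned at its upper bound. Replicates are
stacked and fitted jointly by default. Degenerate inputs are refused
(all-zero responses, fewer than 4 distinct concentrations) or flagged
(non-convergence, h at its bound, Kd extrapolated beyond 10× the largest
tested concentration) — never silently "fitted". The cooperativity bands
(h < 1.3 weak positive, h ≥ 1.5 moderate positive) are interpretive labels
for reporting, not fitted quantities. Published Kd/h values for specific
SMAD–element pairs are not reproduction targets here because the underlying
gel quantifications are not available as numbers; synthetic curves with
known truth are the test bed instead.

## Reporter library

`build_insert()` assembles reporter inserts deterministically: KpnI context,
the motif cassette, a 10-bp junction made of overlapping XhoI/BglII sites
(`CTCGAGATCT`), then the minimal adenoviral major late promoter — so the
MLP-proximal motif always sits exactly 10 bp upstream of the MLP, the
geometry in which the 5-bp rule was established. The promoter-distance
effect (responses shrink when the composite moves further upstream) has no
published threshold, so distance is carried as metadata and never enters
the label. Unnamed spacers follow a GC-poor rule — bases from {A, T} plus a
single C for spacers ≥ 4 bp — which cannot create any SMAD element;
the native ID1/ID2/ID3 linkers (`TGGCT`, `AGAGA`, `AGGCT`) and the control
linker (`AACTT`) are available by name. The exact spacer sequences of the
original non-5-bp constructs were not published; synthetic GC-poor spacers
stand in, which cannot change labels under the grammar.

`enumerate_library()` regenerates the design space from its published
description — a 7×7 spacing grid, homotypic orientation sets, copy-number
1–6, ID-linker and heterocomposite-orientation variants, and all 18
single-nucleotide pGC-SBE permutations — 89 constructs by default, asserted
as ≥ 65 (never an exact equality, since the original oligo list is not
regenerated verbatim). The canonical pGC-SBE is the 6-mer `GGCGCC`
throughout; a 7-mer spelling that appears in one methods listing is
accepted as a user-defined element but not used. `check_library()` compares
the grammar's labels against `expected_library_outcomes()`, a rule table
written directly from the qualitative assay outcomes per series — an
independent route, so full agreement is a real cross-check rather than a
tautology.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analysis assumes,
with defaults chosen once as field-realistic study conditions:

* `generate_background()`: i.i.d. bases at GC 0.41 (human-like) in 300-bp
  regions (typical ChIP-seq peak scale), each region rejection-sampled
  (bounded at 10⁴ attempts) to contain *no* composite of any canonical
  class — so planting truth tables are exact and screens on planted sets
  admit no background false positives.
* `plant_composites()`: one composite per selected region (screens count
  regions, not occurrences), uniform placement, optional minus-strand
  writing; at the default low rates the positive fraction stays below 1%
  per class, the rarity regime reported for real SMAD-bound regions.
* `sample_linkers()`: uniform bases with P(G) boosted at chosen spacer
  positions (default +2/+3, 0.6).
* `simulate_binding_curve()`: Hill responses with Gaussian noise, clipped
  to [0, 1].

Every generator is a pure function of its parameters and seed. What the
synthetic data does **not** emulate: local GC heterogeneity, repeats and
soft-masking, peak-length distributions, co-factor motifs, read-level noise
or peak-caller artifacts. Passing tests on planted sets therefore
demonstrate correctness of the scanning and counting machinery under the
stated model, not performance on real ChIP-seq data, where composite counts
additionally depend on peak calling and the annotation pipeline.

## Problem sizes and numerical checks

The shipped tests exercise: scanner-vs-brute-force equivalence on 200
random 1-kb sequences across all 15 canonical element pairs and spacers
2–20; exact recovery of 15 composites planted at 3% into 500 rejection-
sampled 300-bp regions; reverse-complement invariance of positivity and
back-to-back achievability; Hill recovery on a 12-point noiseless grid to
1e−5 relative error and a 200-seed noisy ensemble with median Kd error
below 5%; the hand-counted ID-linker matrix; and the annotation toys with
closed-form enrichments. These sizes were chosen as the smallest at which
each property is statistically unambiguous.

## Known limitations

* The grammar is exact-match by design; no PWM scoring, so near-miss
  elements score zero rather than low.
* Responsiveness is a discrete label; magnitudes (fold induction, dose
  response) are outside the model.
* The annotation module is a midpoint classifier over user-supplied
  intervals, not a reimplementation of any annotation database.
* Screens of real peak sets require user-supplied BED + FASTA; the package
  deliberately downloads nothing.
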