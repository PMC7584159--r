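---
title: "Reconstructing inversion breakpoint architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing inversion breakpoint architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invarch)
```

## The problem

A paracentric inversion turns the chromosome arrangement `+A +B +C +D`
into `+A -C -B +D`: the segment between the proximal (`+A|+B`) and distal
(`+C|+D`) breakpoints is excised and rejoined in reverse orientation.  The
junctions of the derived chromosome carry the molecular fingerprints of
how the rearrangement formed:

* **NAHR** (non-allelic homologous recombination between inverted
  repeats) leaves the mediating repeats at both ends, in **both** the
  inverted and uninverted arrangements.
* **Clean-cut NHEJ** ("cut and paste") leaves blunt junctions with no
  duplicated or missing sequence.
* **Staggered-break NHEJ** (isochromatid or two-chromatid variants) fills
  in the single-stranded overhangs of offset breaks, creating inverted
  duplications of the junction-adjacent sequence in the inverted
  arrangement **only**.  The two staggered variants produce the same
  duplication pattern and cannot be distinguished from sequence, so the
  classifier never reports them as separate labels.
* The **chromosome model** (in-*trans* repair) joins broken ends from the
  two *homologous* chromosomes.  When the two standing haplotypes differ -
  here, by the orientation of a spacer between two long inverted repeats -
  the derived junction is a mosaic whose halves match different parental
  lines, with a central deletion where the two breaks were offset.
* **BIR/MMBIR-compatible** events (replication-based repair) add filler
  DNA at a junction, typically carrying a short microhomology copied from
  a template near the resumed flank.  Because filler is compatible with
  several repair pathways, this evidence is reported as a *flag* on top of
  the structural label, never as a label of its own.

The package provides both directions of this logic: a **simulator** that
plants an inversion under each mechanism and emits the four-assembly
input set (inverted line, two uninverted lines, outgroup) with
machine-readable truth, and an **inference chain** that recovers the
architecture from assemblies alone:

1. `find_anchors()` / `chain_blocks()` / `call_inversion_candidates()` -
   conserved-synteny comparison by exact k-mer anchors unique in the
   target, greedy colinear chaining, and inversion candidates called at
   orientation flips (the loci of interrupted synteny);
2. `demarcate_segments()` - base-pair localization of the four junctions
   by comparative alignment of each inverted junction region against both
   uninverted flanks;
3. `second_pass_homology()`, `call_duplications()`,
   `call_microinversion()`, `phase_spacer_mosaic()`,
   `find_filler_microhomology()` - reconstruction of the junction
   architecture (assembled by `reconstruct_architecture()`);
4. `classify_mechanism()` - the decision table above, applied per
   breakpoint and combined, with composite labels for mixed mechanisms
   (a staggered proximal break plus an in-*trans* distal junction is the
   configuration of the *D. subobscura* O7 inversion this package is
   modelled on).

Companion scanners cover the sequence-context analyses used around
breakpoints: non-B DNA-forming motifs (`find_inverted_repeats()`,
`find_mirror_repeats()`, `find_tandem_repeats()`, `find_zdna()`,
`find_g4()`, `find_aphased()`, `cruciform_dG()`), PWM binding-site
prediction with exact p-values (`scan_pwm()`), and small
molecular-evolution statistics (`tajima_rrt()`,
`effective_number_of_codons()`, `concerted_pattern()`,
`identity_excluding_indels()`).

## The simulator defines the study conditions

`sim_config()` fixes the conditions every test and recovery rate in this
package refers to.  Component lengths default to the dissected O7
junction: a 2,445-bp proximal insertion opening with a 153-bp direct
repeat of the upstream flank (R1-2), inverted duplications d1 (59 bp) and
d2 (534/540 bp) separated by a 1,374-bp intervening sequence - which
makes the nested microinversion span 59 + 534 + 1374 + 59 = 2,026 bp - a
distal spacer (350 bp) flanked by long inverted repeats (1,117/1,112 bp)
with a 100-bp central deletion (the published spacer lengths, 250 nt
inverted versus 407/317/343 nt uninverted, constrain the deletion to
about this size but do not print it), and a 21-nt filler whose final 8 bp
match the +D start with one mismatch.  The printed element lengths leave
135 bp of the insertion unaccounted for, so inter-element spacers are a
parameter (default `c(135, 0, 0, 0)`, which reproduces both printed
totals); likewise the split of d2B across the insertion boundary is a
parameter (default 131/409) because the printed numbers do not uniquely
partition it.  Background GC content defaults to 0.438, the composition
of the region the study dissected.

Divergence is modelled as independent per-site substitutions (no indels),
0.005 per site for each conspecific line and 0.05 for the outgroup -
typical values for *Drosophila* lines and a congeneric outgroup.  All
randomness derives from one integer seed; the ancestor is drawn under
`seed` and the mechanism step under `seed + 1`, in a documented order, so
datasets are bit-reproducible.

Two generator design rules make the ground truth *identifiable* rather
than merely planted:

* **Maximality of planted copies.** If a base just outside a planted
  duplication copy would extend the homology by chance (probability 1/4
  per base), it is redrawn.  Without this, the "true" extent of a planted
  copy is ill-defined at the level of one or two bases.  The same rule is
  applied to the bases adjoining the chromosome-model junction and the
  filler ends.
* **Observable truth extents.** Divergence applied after formation can
  mutate the terminal bases of a copy; the homology every downstream
  analysis can observe then genuinely ends earlier.  Truth duplication
  extents are therefore restated as the maximal ungapped homologous
  extents in the emitted assemblies (computed with the same documented
  extension rule the scanners use); the planted component lengths remain
  in the configuration.  Planted breakpoints, the microinversion span and
  the central-deletion interval are kept as planted.

What the simulator does *not* emulate: indels and transposable-element
turnover around breakpoints (real breakpoint regions are indel- and
repeat-rich beyond the planted elements), assembly errors, and
read-level artifacts.  Passing recovery tests on these data therefore
demonstrate the correctness of the inference logic under its stated
assumptions, not robustness to assembly noise.

## Numerical and algorithmic choices

**Anchors and chaining.** Anchors are exact k-mer matches (default
k = 15, encoded exactly in 31-bit integers) unique in the target;
uniqueness suppresses repeat noise, so repeat-rich breakpoint regions
appear as anchor deserts bounded by unique flanks, which is precisely how
candidates are delimited.  Chaining is greedy: anchors collapse along
exact diagonals, and runs merge left to right when query and target gaps
are both at most `max_gap` (default 2,000 bp) in the orientation-
consistent direction, with leftmost tie-breaks.  A flanking block may
overlap the flipped block through a shared repeat (the NAHR geometry);
the overlap is then reported as the breakpoint ambiguity region.

**Junction localization.** For each inverted junction region, per-position
match profiles against the two uninverted flanks are built from ungapped
homology hits accepted greedily under a target-disjointness rule (each
flank region may explain only one query region - the positional-homology
convention).  Gapped local alignment is used only as a fallback when
ungapped coverage is absent, because optimizing gaps over non-homologous
sequence inflates its apparent identity.  The junction is then the
change point of a competitive two-state model (ties broken leftmost, so a
chance match to the upstream flank just past the true junction cannot
displace it when the downstream flank also matches there); a three-state
model with a middle segment homologous to neither flank is preferred only
when it improves the log-likelihood by `delta` (default 6), and its
middle becomes a cataloged unassigned interval - a candidate insertion or
filler.  Junction zones wider than 10 bp are reported as intervals, not
points.  The published analysis located junctions by eye from alignments;
the explicit likelihood rule makes the call reproducible, which is why it
replaces a fixed windowed-identity threshold.

**Duplication calls.** Windows around the two inverted-assembly junctions
are scanned against each other and themselves for ungapped matches
(seeded at k = 12, extended across an isolated substitution only when
backed by a clean run, so chance extension is vanishingly rare), with
min_len = 20 and min_identity = 0.85 - comfortably below the shortest
published junction duplication (59 bp at 98.3% identity).  Identities
always exclude gap columns.  `present_in` counts occurrences of the copy
in the uninverted assemblies: two or more mean the duplication predates
the inversion (`both_states`, the NAHR signature).

**Microinversion.** The span runs from the first base of the upstream d1
copy to the last base of the downstream one, inclusive of the fill-in
copies - the convention that reproduces the printed 2,026 bp.  The
certifying partner copy must be at least 100 bp so that low-complexity
repeat pairs cannot fake the layout; conflicting layouts are returned
with a warning flag rather than auto-selected.

**Mosaic and central deletion.** The reconstructed spacer (the junction-
adjacent material of both junctions, spliced in the `+C|+D` frame) is
phased against both uninverted lines with the same competitive
change-point machinery; halves assign to the line with higher identity
(excluding indels) and a mosaic is called at an identity gap of at least
20 points - the published halves show ~97% against one line versus no
detectable homology against the other, an extreme this threshold easily
captures.  Half identities are computed over a 150-bp window adjacent to
the switch (the spacer-half scale) so that flanking sequence shared by
both lines does not dilute the contrast.  The central-deletion length is
the distance between the flank coordinates at the switch, read off the
modal colinear offset of the adjacent homology.  With a single uninverted
haplotype the test is skipped and flagged, never guessed.

**Filler and microhomology.** The filler is the unassigned middle at the
distal junction (from the mosaic phase when one was called, otherwise
from demarcation).  The microhomology is the longest gapless match
between a filler substring and a window anchored at the +D start, with at
most one mismatch and a 4-bp floor (the literature uses "microhomology"
for ~1-25 bp of chance similarity); the filler/flank split is scanned
over a few bases because a boundary base can be claimed by either side.
Note one inherent ambiguity the package resolves the same way the
original analysis did: since the microhomology *is* a near-copy of the +D
start, a gapped aligner will happily absorb it into the flank - the
ungapped, colinearity-respecting profiles are what keep the filler
intact.

**Non-B DNA scanners.** Inverted repeats follow the standard palindrome-
scan settings (arms 6-20 nt, spacer <= 10 nt, <= 1 mismatch); all maximal
repeats are reported, including nested and overlapping ones, because
published counts (15 IRs within a 150-nt stretch) are only reachable if
they are retained.  A repeat is non-maximal only if its arms extend
outward (same spacer) or inward (spacer shrinks by two) without violating
the bounds.  Cruciform propensity is a nearest-neighbor stem stability
minus a linear loop penalty, with the parameter table shipped as plain
text and overridable; the external tool's exact thermodynamic table is
unpublished, so only rank order is meaningful, and the published values
2.64/2.05 are treated as tool-specific.  Mirror repeats use a wider
spacer bound (50 nt) because the published triplex-forming instance has a
30-nt spacer.  Tandem repeats are found period-by-period from
self-matches at lag p, with fractional copy number span/p and majority
consensus; overlapping calls resolve to the largest span, then the
smallest period.

**PWM scanning.** Log-odds scores with pseudocounts against a 0-order
background (estimated from the input unless supplied), both strands, and
*exact* p-values from the score distribution computed by convolution over
motif positions with 0.01-bit discretization - deterministic, unlike
shuffling.  The raw p <= 1e-3 cutoff follows the published analysis; no
multiple-testing correction is applied, and hit counts are reported so
users can apply their own.  Transcription start sites are inputs (GFF3 or
a data frame), not predictions.

**Molecular evolution.** The relative-rate test uses only columns where
all three sequences are unambiguous, and reports
`chi2 = (m1 - m2)^2 / (m1 + m2)` on 1 df.  Because the published analysis
states only that "either" remaining sequence served as outgroup, the
function takes the outgroup explicitly and can simply be called per
choice.  For the effective number of codons the published source cites an
"improved" index without printing its formula; this package documents
exactly what it computes - per-family codon homozygosity combined as
`Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` - with two F estimators: Wright's
classic small-sample form and a pseudocount-regularized form
(`sum(((n_i + 1)/(n + k))^2)`, the default) that is defined for every
observed family.  Unobserved families are imputed from their
degeneracy-class mean, and a class with no observed family at all falls
back to uniform usage.

## A worked run

```{r demo, eval = FALSE}
cfg <- o7_sim_config(genome_length = 40000L, seed = 7L)
ds <- simulate_dataset(cfg)
inf <- infer_inversion(ds$seqs)
inf$call
#> <mechanism_call> NHEJ_STAGGERED+CHROMOSOME_MODEL [BIR/MMBIR-compatible]
#>   proximal: NHEJ_STAGGERED | distal: CHROMOSOME_MODEL
#>   evidence: inverted_dups_inverted_only, mosaic_spacer, central_deletion,
#>             multibreak
inf$architecture$microinversion$span
#> [1] 2026
nchar(inf$architecture$filler)
#> [1] 21
inf$architecture$microhomology[c("length", "mismatches")]
#> $length
#> [1] 8
#> $mismatches
#> [1] 1
evaluate_inference(inf, ds$truth)
```

## Problem sizes

Desk-scale simulations use 30-kb chromosomes with an 8-kb inversion (the
O7-parameter demonstrations use 40 kb to accommodate the 2,445-bp
insertion and the spacer/inverted-repeat block); these sizes preserve
every structural relationship of the junctions while keeping a full
simulate-infer-evaluate cycle around one second.  The recovery-rate
properties are asserted over 100 seeds per mechanism; reduced-replicate
versions of the same properties run in the per-module tests.

## What is not reproducible at desk scale

The study's assembly-scale quantities are documented non-targets: the
PacBio assembly statistics, the 9,936,431-bp inversion length and its
gene counts, the printed junction identity percentages (98.3%, 95.6%,
96.8%, 97.6%, 95.4%), the codon-usage values Nc = 51.2/50.7, and the
cruciform free-energy values 2.64/2.05.  They require the PRJEB38585
assemblies and annotations and, for the free energies, the external
tool's unpublished parameter table; the package computes the
corresponding *statistics* but does not claim those *values*.  Marker-
based cytological filtering of candidates is likewise not modelled; the
optional `expected_span` filter is its desk-scale stand-in.

## Known limitations

* The inference chain assumes assemblies of the same chromosome at
  near-collinear scale; whole-genome many-to-many synteny, translocations
  and duplication typing are out of scope.
* Indel-free divergence is the default; with dense indels the ungapped
  profile machinery falls back to gapped alignment and junction precision
  degrades gracefully from +/-1 bp to the alignment's ambiguity.
* The distal-junction coordinate frames of the uninverted lines are
  assumed comparable (no large line-specific indels near the spacer) when
  the central-deletion length is computed across lines.
* With the R1-2 direct repeat of the upstream flank, the insertion start
  is intrinsically ambiguous by the repeat's length; the package follows
  the positional-homology convention (the flank's own copy keeps its
  place), and tests allow exactly this ambiguity.
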