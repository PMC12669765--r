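---
title: "Designing co-transcriptional RNA origami with origamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing co-transcriptional RNA origami with origamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origamir)
```

## The design problem

An RNA origami is one long transcript that folds, during transcription,
into a raster of parallel A-form helices. The design space is discrete and
combinatorial: helices are extended by stems, capped by tetraloops, tied to
their neighbours by dovetail double crossovers, and bridged coaxially by
180° kissing loops whose loop–loop pairs are pseudoknots. `origamir`
treats all of these as *motifs* — small sets of strands on a character
grid, plus a local pair map — and an origami as a 2D grid of motifs. This
vignette explains the models and conventions behind each stage and the
choices made where the design space was genuinely open.

## Blueprint model and assembly

Every motif strand is a glyph walk: IUPAC nucleotide codes occupy cells
and keep the walking direction; box-drawing path glyphs
(`─ │ ╭ ╮ ╰ ╯`) route turns. Each grid row of
an origami is one helix track occupying two glyph lines — top strand read
west→east, complement east→west by default; motifs on the flipped rows of
a serpentine raster are oriented with `transform_motif()` (`rotate_180` is
the composition of the two mirror flips).

Assembly is deterministic. Motifs are laid out with per-row column
cursors (a motif spanning two helix rows advances both); cell occupancy
must be unique. Strand fragments are then stitched: a 3' exit slides east
or west across empty cells until it meets an occupied cell — a strand
start with matching travel direction connects (the gap is filled with
path glyphs, which is how the assembler "dynamically aligns" rows of
unequal width), anything else raises a junction-mismatch error naming
both motifs and the offending cell. Exits that run off the blueprint are
molecule termini. Closed backbone cycles are legal — a fully capped
serpentine *is* a cycle — and are nicked at the first fragment in reading
order, which reproduces the conventional 5' start at the top-left stem.
Strands are numbered by the reading-order position of their 5' ends;
motif-local pairs are re-indexed into the global map.

Two consequences of this convention are worth knowing. First, two facing
cap motifs with nothing between them legally close into a small nicked
loop rather than raising an error. Second, the layered dot-bracket writer
assigns pseudoknot pairs greedily (first seen, lowest non-crossing layer,
alphabet `() [] {} <> Aa Bb …`); if a partial design interleaves
nominally-nested pairs in its linear order, the surplus pairs are
promoted to pseudoknot layers instead of failing.

## The dovetail convention

A dovetail is modelled minimally: one crossover base pair on each side of
an inter-crossover seam stem of |offset| bp paired between the two
pass-through strands; flanking duplexes come from the neighbouring stem
motifs. This gives |offset| + 4 pairs and 2·|offset| + 8 nucleotides,
independent of sign. The layout is identical for both signs; the sign
lives in the motif metadata and controls only the 3D dihedral (below).
The seam nucleotides are flagged so the 3D builder can bend them onto the
midline between the two helix rows, keeping every pair within pairing
distance.

## 3D model

Geometry is rigid-body and ideal: A-form helices with 0.281 nm rise and
32.7° twist per base pair and a 1.15 nm backbone radius (`helix_params()`;
all overridable). These are standard A-form values; base-pair planes are
modelled perpendicular to the helix axis (the inclination parameter is
exposed but defaults to 0), which makes paired base vectors exactly
anti-aligned and keeps the closed-form tests sharp. Helix rows are
chained through one frame per row: junction *r*→*r+1* rotates the
stacking direction about the shared helix axis by the dihedral
τ = wrap(180° + d·32.7°) where *d* is the junction's dovetail offset.
Thus τ(0) = 180° (a back-folded back-to-back crossover), alternating
d = ±5 gives τ = ∓16.5° — a nearly flat, corrugated sheet — and short
|d| = 2 dovetails fold at ±114.6°, which is how the filament demo stacks
its second layer. The inter-helix spacing is a packaged constant of
3.3 nm chosen as a plausible crossover-geometry value consistent with a
six-helix layer spanning roughly 20 nm; it approximates the geometry that
would be measured from crossover-rich crystal structures and is labelled
as an approximation.

Conformations are exported in the oxDNA new-topology dialect (5'→3'
strand records) with positions in simulation units (0.8518 nm per unit);
`%.8f` formatting bounds the write→read round-trip error well below
10⁻⁵ nm. Steric clashes are counted (`clash_count()`) but never resolved:
rigid concatenation over-packs locally and the flexibility of real RNA is
expected to relax such contacts.

`helix_tracks()` recovers helices from geometry alone: layer-0 pairs are
grouped into runs of continuously advancing midpoints, runs shorter than
3 bp are dropped, collinear runs (axes within 10°, perpendicular offset
under 1.5 nm) are merged, and tracks shorter than `min_run_bp = 6` are
discarded — the default deliberately excludes the short dovetail seam
stems so that a track means a real helix.

## Sequence design

`design_sequence()` replaces an external inverse-folding engine with a
self-contained greedy searcher that keeps the same target-file contract
(3 lines: name, IUPAC constraints with `&` strand breaks, layered
dot-bracket). Free positions are seeded uniformly at random within their
constraint class; paired positions are seeded jointly so complementarity
(Watson–Crick, plus G·U only at wobble-flagged pairs) holds by
construction and every later mutation updates both partners. The score is
`defect + λ·repeats`: the defect is the base-pair distance between the
oracle-predicted MFE structure and the pseudoknot-masked target (kissing
loops are enforced by hard complementarity only, and masked to dots for
the oracle — loop–loop energetics are not modelled); `repeats` counts
k-mer occurrences in excess of one, the sequence-symmetry-minimisation
penalty, with k = 8 and λ = 0.1 as defaults. Proposals that strictly
lower the score are accepted, so the defect is non-increasing; the search
stops at score 0 or after `max_iterations` proposals. Everything is a
deterministic function of `(target, seed, oracle)`; the RNG state of the
session is saved and restored.

The folding oracle is pluggable; the packaged one shells out to
ViennaRNA's `RNAfold` (and `RNAeval` for the target's ensemble
frequency, exp((G_ensemble − E_target)/kT) at 37 °C). Without an oracle
the defect is reported as `NA` and only the repeat penalty is minimised —
that is the default, because partition-function calls on designs of
thousands of nucleotides dominate runtime.

The co-transcriptional folding-barrier score is a deliberate heuristic:
for each pseudoknot run, every decoy occurrence of the run's reverse
complement transcribed between the run and its true partner adds
1/(1 + distance). It is zero for pseudoknot-free designs, strictly
increased by adding a decoy copy of a kissing-loop sequence, and intended
for ranking design variants, not for predicting yields.

## Thermodynamics and wet-lab preparation

Melting temperatures use the unified DNA nearest-neighbor table
(Allawi & SantaLucia 1998): ΔH/ΔS accumulation over dinucleotide stacks,
terminal A·T/G·C initiation terms, a symmetry correction for
self-complementary oligos, the entropic salt correction
0.368·(N−1)·ln[monovalent] with the von Ahsen divalent equivalence
(+120·√Mg, concentrations in mM), and Tm = 1000·ΔH/(ΔS + R·ln(CT/4)) −
273.15 (CT/2 for palindromes). Defaults: 50 mM monovalent, no Mg,
500 nM total oligo. The tests verify agreement with an independently
coded implementation of the same published model to within 0.01 °C.

Primer design anchors the forward primer at the coding 5' end (which
includes the promoter) and the reverse primer at the 3' end, scanning
lengths 15–40 nt for the Tm nearest the target (default 69 °C, tolerance
1.5 °C; ties go to the shorter primer). The T7 template builder applies
the +1 overlap rule: the promoter's 3'-terminal G is the first transcribed
nucleotide, shared with the transcript when the RNA starts with G and
otherwise followed by the full RNA plus a low-efficiency warning.

## Demo designs and what they do (and do not) show

The three packaged demos are re-parameterisations of published-scale
architectures; the supplementary scripts that defined the originals are
not available, so the parameter choices here are the package's own,
constrained by the printed design characteristics:

- `demo_rect_10h_3x()`: 10 helices, alternating ±5 dovetails in every
  segment, 3 kissing-loop columns with one stem-bridged row each (the
  crossover/segment graph is then a spanning tree, so the backbone is a
  single cycle, nicked once), a Broccoli cap on helix 4, 7-bp stem slots
  and 13 extra east base pairs. The last two values are the free length
  knob set so the design totals exactly 2501 nucleotides in one strand.
- `demo_filament_tile()`: 8 helices — six base-layer helices on ±5
  junctions plus two second-layer helices folded on top by ∓2 junctions —
  with 35-bp stem slots so the tile is longer than it is wide, and
  palindromic terminal kissing loops on the first helix for head-to-tail
  polymerisation.
- `demo_droplet_y()`: built through the Structure Converter: three 10-bp
  arms each ending in a palindromic kissing loop (partners are on other
  molecules, hence unpaired in-design), five-uracil linkers, and a
  Broccoli hairpin.

`make_fixture()` generates seed-deterministic random small origami
(2–4 helices, 0–2 kissing-loop columns, optionally an aptamer) together
with closed-form expected totals derived from the motif-inventory
arithmetic; the tests assert assembly reproduces them on 50 seeds. These
fixtures exercise the combinatorial layer — they say nothing about
thermodynamic foldability of real molecules, which is exactly why the
folding oracle and the wet-lab stages are tested separately against
external references (RNAfold, an independent nearest-neighbor
implementation, exhaustive dimer/subsequence scans).

Problem sizes in the default test run are deliberately modest (designs up
to 2501 nt, 100 random design targets of 30–200 nt, 50 fixtures); all are
the package's own choices for a fast, fully deterministic suite.

## Known limitations

- Non-adjacent helix connections are not expressible in the row grammar.
- Branched kissing loops are simplified to the single-hairpin terminal
  variant; dimeric kissing loops share the intra-strand blueprint and are
  distinguished by annotation.
- The kissing-loop binding energy field is annotation only; no loop–loop
  thermodynamics are applied anywhere.
- Aptamer 3D poses are placeholder helical geometry, not
  experimentally-derived models.
- Multi-strand sequence optimisation is not joint: strands share one
  target string and are designed together only through the global
  constraint/pair map.
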