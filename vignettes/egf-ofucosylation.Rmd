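---
title: "Methods: EGF-like domain O-fucosylation analysis with egfofuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EGF-like domain O-fucosylation analysis with egfofuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfofuc)
```

## The biological problem

Protein O-fucosyltransferase 1 (POFUT1) attaches a single fucose to the
serine or threonine of the consensus motif C2-X-X-X-X-(S/T)-C3 inside
EGF-like domains (EGF-LDs) of the hEGF subtype. Whether a given consensus
site is *actually* modified depends on more than the motif: the domain must
also dock productively into the POFUT1 binding groove. The WIF1 family of
Wnt inhibitors is a striking case — five EGF-LDs, two evolutionarily
conserved consensus sites (in domains III and V of gnathostomes), yet only
domain III carries O-fucose in the mouse protein. `egfofuc` packages the
dry-lab side of that analysis: motif scanning and sequence-level substrate
rules, cross-species conservation, parsimony reconstruction of site gains
and losses, and the targeted mass-spectrometry arithmetic (digestion,
masses, MRM transitions, occupancy) needed to quantify site occupancy.

## Coordinate and domain conventions

All coordinates are 1-based inclusive and counted on the full precursor from
the initiator methionine, so positions like T255 are directly comparable to
published residue numbers. An EGF-LD is anchored on its six cysteines
C1..C6 (disulfides C1–C3, C2–C4, C5–C6); a "loop" always means the residues
strictly between two cysteines, and C4+1 is the residue immediately after
C4. Domain spans are reported C1 to C6: the literature does not agree on how
many flanking residues "belong" to a domain, and the cysteine span is the
part every convention shares.

Domain *detection* is deliberately plain: a run of six cysteines whose five
inter-cysteine spacings fall inside configurable ranges (default
`C-x(2,14)-C-x(3,12)-C-x(3,12)-C-x(1,3)-C-x(5,12)-C`), scanned greedily left
to right without overlap. Curated domain annotations, when supplied, always
override detection and are only validated against the six-cysteine
invariant. The hEGF subtype — the class POFUT1 modifies — is called from the
C5–C6 loop length being 8 or 9.

## The consensus scanner and the POFUT1 rule set

A site is reported iff the C2–C3 segment has exactly five interior residues
and the residue immediately before C3 is S or T. An `X` (unknown residue) is
tolerated at the four wildcard positions but never accepted as the acceptor
or as a cysteine anchor: an unknown residue is not evidence of a site.

The compatibility report distils the structural reasoning about POFUT1
binding into four sequence-level flags:

| flag | rule | default |
|---|---|---|
| `bulky_c2plus3` | residue at C2+3 in a configurable set | `{H, Y, D}` |
| `basic_c5plus1` | residue at C5+1 is basic | `{R, K, H}` |
| `proline_c1c2` | proline anywhere in the C1–C2 loop | — |
| `gln_c4plus1` | glutamine at C4+1 | — |

The verdict is total and deterministic: no consensus → `incompatible`;
consensus with a bulky C2+3 or basic C5+1 → `incompatible` (steric clash or
charge repulsion); consensus with only the proline and/or glutamine flags →
`weakened` (reduced binding affinity); otherwise `favorable`. The bulky set
defaults to the three residues with direct evidence (His, Tyr, Asp); Trp and
Phe plausibly behave the same but are not included by default precisely
because that is an extrapolation — add them via `bulky_set` if desired. No
structural modelling is performed: these are sequence rules, and a
`favorable` verdict is a prediction, not a measurement.

## Conservation: alignment, site matrices, logos, similarity

Homologous EGF-LDs are aligned on their cysteine framework rather than by a
general-purpose aligner: the six cysteines become anchor columns and each
loop is padded to the maximum length in the set, left-aligned with trailing
gaps against the next anchor (the pre-C1 region is right-aligned). This is
deterministic, permutation-stable and exactly reversible by degapping —
properties a heuristic aligner cannot promise — and for domains this rigidly
cysteine-scaffolded it is also biologically sensible. An externally produced
alignment can be supplied instead wherever an alignment is consumed.

The species-by-slot site matrix distinguishes four states: `present`,
`absent`, `domain_missing` (the species genuinely lacks that domain) and
`unknown` (a partial sequence truncates the domain). The last two are
treated identically downstream (no information) but are biologically
different facts and are kept apart in outputs.

Logo columns report the residue frequency distribution over non-gap entries
and a conservation class with the uppercase/lowercase/dot convention:
`upper` when the dominant frequency is at least 0.80, `lower` in
[0.50, 0.80), `dot` below 0.50; both thresholds are inclusive on their lower
edge. Ties for the dominant residue break alphabetically. Subfamily
comparison flags a column as a *relevant deviation* when the dominant
residues differ **and** the dominant residue of subfamily A drops in
frequency by at least 0.5 (configurable) in subfamily B — our
operationalisation of the qualitative "relevant deviations" convention of
logo-rendering tools, chosen so a flag requires both a switch and a large
frequency change.

Percent identity/similarity of two aligned sequences excludes every column
where either sequence is gapped; similarity additionally counts matches
within the groups `{GAVLI} {FYW} {CM} {ST} {KRH} {DENQ} {P}` (the SMS2
ident_sim defaults). Published WIF1 similarity percentages computed on
curated alignment blocks are not reproduced here, since the exact column
sets behind them are not recoverable from the publication.

## Site evolution by Fitch parsimony

Gains and losses of the consensus per domain slot are reconstructed
independently per slot with unit-cost (Fitch) parsimony on a rooted species
tree; multifurcations are allowed and `?` leaves (partial sequences, missing
domains) carry the full state set so they never force a change by
themselves.

Internally the pass is an exact dynamic programme (unit-cost Sankoff):
`cost[v, s]` is the minimum number of changes in the subtree of `v` given
state `s` at `v`. This has two advantages over the classical set-based
down-pass: the minimum is exact for multifurcations without special-casing,
and *any* top-down argmin trace attains the global minimum, so both
ambiguity-resolution flavours are provably optimal:

* `deltran` (default): on ties a child keeps its parent's state, placing
  changes as late as possible; an ambiguous root resolves to absent. This is
  the conservative reading — a site is not pushed deeper into the tree than
  the data demand.
* `acctran`: on ties a child switches, placing changes early; an ambiguous
  root resolves to present.

The change count itself is invariant to the choice (and to re-rooting);
only event placement differs, and the resolution used is recorded in every
result. Events are reported per branch, labelled by the child clade's sorted
tip set. Slots are analysed independently: the "replacement" of one slot's
site by another's is a narrated coincidence of a loss and a gain on the same
stem branch, not a joint model.

Newick parsing/serialisation delegates to `ape`, and midpoint rooting to
`phangorn::midpoint` (tested against a brute-force all-pairs longest-path
oracle); tree *inference* is out of scope — the species tree is an input,
and a curated bilaterian topology with the per-species site states ships
under `inst/extdata/`.

## In silico glycoproteomics

**Digestion.** Trypsin cleaves after K/R except before proline. Thermolysin
cleaves before the hydrophobic residues I/L/V/A/M/F; for its exception we
adopt the convention that cleavage is suppressed when the residue *after*
the hydrophobic one is proline (P2' rule). This choice matters: the
documented EGF-LD V co-digestion peptide `VCEPGCGAHGTCHEPNK` begins with a
valine immediately preceded by proline, so a "no cleavage after proline"
convention could never produce it, while the P2' rule reproduces both
published co-digestion peptides exactly. The exception predicate is a plain
function and can be replaced. Co-digestion uses the union of the proteases'
cut sites and counts missed cleavages against that union; level-0 peptides
provably tile the substrate.

**Masses.** All masses are monoisotopic and derived at load time from
elemental compositions (CODATA-era atomic masses), so residue,
carbamidomethyl (+57.02146), and glycan deltas (dHex 146.05791, HexNAc
203.07937, Hex 162.05282, NeuAc 291.09542) are mutually consistent; unit
tests pin them against an independently coded elemental oracle to 1e-6 Da.
Cysteine carbamidomethylation is the default fixed modification, matching
reduced/alkylated digests.

**Transitions and occupancy.** The glycoform ladder on a site-bearing
peptide is unmodified, O-Fuc, GlcNAc-Fuc, +Hex, +NeuAc. Fragments are
computed *without* the glycan (labile-loss convention), so modified and
unmodified forms of a peptide share one fragment list — the property that
makes shared-fragment quantitation valid; a glycan-retaining mode exists for
other chemistries. Fragment ranking, absent measured intensities, is
deterministic y-series-first by decreasing index, and at most `top_n`
(default 6) transitions are kept per precursor. Occupancy is
`100 * A_mod / (A_mod + A_unmod)` on the most abundant fragment of the
*unmodified* form (ties to the lowest fragment m/z); choosing the unmodified
form makes the selection independent of the quantity being estimated. The
denominator excludes the extended glycoforms by default — the percentage
then answers "what fraction of the core-fucosylation-competent pool carries
at least the core fucose" with `include_extended = TRUE` available since the
convention is not universal. Mass matching uses a strict 10 ppm criterion;
instrument resolution is deliberately not modelled.

## The synthetic-data generator

The generator emulates the *structure* of the comparative data: per-slot
EGF-LDs evolving along a species tree, with per-branch site gain/loss
probabilities (default gain 0.03, loss 0.05 — rare events, so most slots are
phylogenetically informative rather than saturated) and loop substitutions
(default 0.02 per residue per branch) that never touch the cysteines; the
acceptor toggles atomically with the site state, so a site is present iff
the sequence says so. Random topologies come from seeded coalescent joining
with exponential(1) branch lengths — structure only, no biological
calibration is claimed. Loop lengths are drawn from canonical ranges with
the C2–C3 loop pinned to five residues, so the consensus is geometrically
possible in every domain. Flanks and linkers are cysteine-free, which makes
detection unambiguous by construction.

MRM peak tables are simulated by splitting a fixed precursor signal between
the unmodified (`1 - occupancy`) and O-Fuc (`occupancy`) forms, weighting
transitions 1/rank within each precursor, and multiplying every area by
independent unit-mean log-normal noise at the requested CV (default 0.10,
the scale of well-behaved targeted-MS area CVs); the default true occupancy
is 0.6724, the observed modification level of the mouse EGF-LD III peptide.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: amino-acid substitution processes (no JTT/LG-style
model, so simulated loops are compositionally unrealistic), correlated
gain/loss between slots, alignment ambiguity (domains are always exactly
alignable on their cysteines), chromatography and spectra (areas are drawn,
not integrated from peaks), interference between co-eluting species, and
N-glycan heterogeneity (a real N-glycosylated peptide can simply escape
detection). Every stochastic entry point requires an explicit seed and is
byte-reproducible.

## Numerical choices and degenerate inputs

Logo thresholds are compared with `>=` on exact doubles (frequencies are
ratios of small integers, so 0.80 and 0.50 are representable exactly in the
test cases that matter). All-gap alignment columns yield `NA` classes rather
than inventing a dominant residue. Identity/similarity of two sequences with
no co-ungapped columns is `NA`, not 0. A zero/zero occupancy ratio raises a
missing-signal error instead of returning `NaN`. Windows with a cysteine
count other than six, annotation spans violating the invariant, duplicated
slot labels, leaf/character mismatches and malformed Newick all raise typed
conditions (`egfofuc_*_error`) naming the offending record.

## Problem sizes used by the tests

The suite verifies the Fitch pass against exhaustive enumeration on 1000
seeded random trees of up to 7 leaves (the largest size where enumeration of
all internal labelings is instant), masses against the elemental oracle on
1000 random peptides, occupancy recovery at truths 10/50/67.24/90% with CV
0.10 and 100 replicates, and gain-branch recovery on 100 20-leaf coalescent
trees. These sizes make the whole suite run in well under a minute per
module while leaving each property no room to pass by accident.

## Known limitations

* The compatibility verdict is a sequence heuristic; it encodes the residues
  with direct experimental implication and will mislabel domains whose
  incompatibility has other structural causes.
* Per-slot independence in the parsimony stage cannot express correlated
  replacement; the narrative coupling of a loss and a gain is left to the
  report.
* The cysteine-anchored aligner assumes positional homology of loop residues
  by offset from the preceding cysteine, which degrades for loops of very
  different lengths.
* Occupancy from peak areas inherits all the usual targeted-MS caveats
  (ionisation efficiency differences between glycoforms are assumed away by
  the shared-fragment design, but matrix effects are not modelled).
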