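---
title: "Thermodynamically screened tiling microarray design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically screened tiling microarray design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotile)
```

## The problem

A whole-genome tiling microarray places a probe roughly every *w* base pairs
along a genome so that any transcript — annotated gene or novel RNA —
hybridizes to at least one probe. The difficulty is the trade-off between
coverage and specificity: a probe must detect its 100-bp target fragment
without capturing signal from partially matching sequence elsewhere in the
genome. Sequence-level statistics (identity, longest common stretch) do not
order hybridization stability: probes with identical identity (24 of 50 bp)
and identical longest match stretch (14 bp) to a nontarget can differ by
40 °C in nontarget melting temperature (see the case-encoded examples in
`inst/extdata/crosshyb_examples.tsv`). `thermotile` therefore decides
specificity thermodynamically: every potential probe/nontarget duplex is
built explicitly and scored with nearest-neighbor models, and a probe is
kept only when its target melting temperature exceeds that of its closest
nontarget by a configurable margin.

## The design procedure

1. **Fragmentation.** Each genome record is cut into non-overlapping
   100-bp target fragments (the terminal fragment may be shorter and is
   kept — coverage accounting is fragment-based, so dropping trailing
   sequence would silently bias it). Separately, 50-bp windows centered on
   every internal fragment junction are extracted and added to the design
   as *avoidance fragments*: they are screened as nontargets, which is what
   prevents any probe from straddling a junction. Avoidance is thus
   enforced thermodynamically, by the same machinery as all other
   specificity decisions, not by geometric exclusion.
2. **Candidate enumeration.** Every substring of a target fragment with
   length 36–46 bp is a candidate; candidates containing `N` are rejected.
3. **Match screening.** An exact-match index (k = 8) over both strands of
   every genome record and every avoidance fragment yields all maximal
   exact matches between a candidate and nontarget sequence. A candidate
   with any nontarget match of ≥ 18 bp is ruled out immediately. Matches of
   8–17 bp are extended into explicit duplex layouts (below) and scored.
4. **ΔTm acceptance.** A candidate is accepted only if it has no screenable
   nontarget at all, or if `Tm(target) − max Tm(nontarget) ≥ 5 °C`. The
   *closest* nontarget is the one with the highest melting temperature, not
   the highest identity — identity does not order stability.
5. **Selection.** Per fragment, up to two mutually non-overlapping accepted
   candidates are chosen, ranked by (a) larger ΔTm separation (candidates
   with no screenable nontarget outrank all others), (b) target Tm closest
   to the genome-wide median target Tm of accepted candidates — the array
   is hybridized at a single temperature, so Tm uniformity is a design
   goal — and (c) smaller start coordinate. The rule is fully
   deterministic; two runs on the same input produce byte-identical probe
   tables.
6. **Second pass.** Fragments left without probes are re-targeted with the
   boundary windows narrowed to 40 bp; fragments already covered join the
   avoidance set. The narrower windows admit borderline probes near
   junctions that the 50-bp windows blocked. Both probe lists are merged
   with their pass labels.
7. **Synthesis-cycle filter.** Probe cost under cyclic in-situ synthesis
   (fixed dispense schedule A, C, G, T repeating, synthesized 3′→5′) is
   computed for every probe, and probes exceeding 148 cycles are removed
   (counted and reported). The 148-cycle budget is the manufacturing
   platform's constraint; the dispense-schedule convention is a documented
   reconstruction and is configurable.

## The thermodynamic engine

Duplexes are represented as explicit column-by-column layouts (probe strand
5′→3′ against the counter strand 3′→5′) with column kinds `pair`,
`mismatch`, `bulge_probe`/`bulge_counter`, and
`dangle_probe`/`dangle_counter`. Enthalpy and entropy are additive over the
layout:

* **Watson–Crick stacks** between adjacent pair columns use the unified
  oligonucleotide parameter set (SantaLucia 1998; SantaLucia & Hicks 2004),
  with duplex initiation expressed as a per-duplex term plus a penalty per
  terminal A·T pair — algebraically identical to the published per-end
  formulation.
* **Single internal mismatches** use the measured trimer-context tables of
  Allawi & SantaLucia (G·T, G·A, C·T, A·C) and Peyret et al. (A·A, C·C,
  G·G, T·T). Both orientations of every stack are resolved by a symmetric
  key lookup.
* **Mismatch runs of length ≥ 2** fall outside the single-mismatch tables
  and are treated as an internal loop: a fixed entropy penalty per column
  (default −3 cal mol⁻¹ K⁻¹) and no stacking credit. The default is
  deliberately mild: underestimating nontarget stability is the dangerous
  direction for a specificity screen, so the fallback errs toward
  *stabler* nontargets.
* **Bulge loops** take a length-dependent free-energy penalty (ΔH = 0,
  ΔS = −ΔG₃₇·1000/310.15), linearly interpolated between tabulated loop
  lengths; a single-base bulge retains the Watson–Crick stack of its
  flanking pairs (the closing-stack rule). Bulges enter layouts only by
  *seed bridging*: two exact matches on the same subject whose offsets
  differ by 1–3 bp are joined by a bulge run and extended as one duplex.
* **Dangling ends** (Bommarito et al. 2000) contribute one term per
  unpaired terminal base adjacent to a terminal pair. A dangle is never
  placed next to a bulge or a mismatch — the published terms assume a
  closing pair, so the engine simply omits the (small, stabilizing) term
  in those configurations.
* **Melting temperature** is the two-state expression
  `Tm = 1000·ΔH / (ΔS_salt + R·ln(C_T/x)) − 273.15` with
  R = 1.987 cal mol⁻¹ K⁻¹, the entropic salt correction
  `ΔS_salt = ΔS + 0.368·N·ln[Na⁺]` with N = (pair columns − 1), and 273.15
  used exactly. Non-exothermic inputs yield `NA`, which callers read as
  "no stable duplex".

**Hybridization conditions.** Defaults are 50 mM Na⁺, C_T = 1 µM, symmetry
factor 4. These are explicit, swappable configuration — not part of the
method's substance — because every screening decision is a Tm *difference*,
which first-order cancels the dependence on the absolute condition choice.
Absolute Tm values printed by this package are therefore comparable within
a run but should not be read as predictions for a particular buffer.

## Seed extension policy

A seed is extended outward symmetrically, in rounds: in every round each
open side proposes its next ungapped column; matching bases are always
added, and mismatches are admitted only if the layout-wide identity — pair
columns over pair-plus-mismatch columns, the definition that keeps the
printed identity column interpretable — stays at or above the 66 % floor.
Both proposals in a round are judged against the same identity snapshot,
and when only one of two simultaneous mismatches would fit under the floor,
both sides stop. This round-based rule makes the layout exactly invariant
under flipping the duplex end-for-end, so the *structure* of screening is
strand-symmetric: seeds and the 18-bp rule-out for a candidate mirror those
of its reverse complement exactly. The melting temperatures themselves
agree only approximately between a candidate and its reverse complement:
complementing a duplex exchanges each mismatch for its complement (G·T
becomes C·A), and those carry genuinely different measured parameters. The
identity floor is evaluated globally over the layout (not in a sliding
window) and extension is ungapped; both choices are configurable policy in
the sense that they are localized in one function, and the global/ungapped
variant is the minimal mechanism consistent with a single similarity
threshold.

Self-matches are excluded by coordinate overlap with the candidate's own
locus on the same strand — not by sequence equality — so a second verbatim
copy of the candidate elsewhere in the genome is screened as the nontarget
it really is. This is precisely what drives probe rejection in repeat
regions.

## The synthetic-data generator

Because no external genome is downloaded, all validation runs on generated
sequence with planted, labeled structure:

* `random_genome()` — i.i.d. sequence at a chosen GC fraction; every draw
  runs under an explicit seed and restores the caller's RNG state.
* `random_unique_genome()` — a genome in which every 8-mer and its reverse
  complement occur exactly once; no candidate can have any off-locus match,
  so full coverage is guaranteed and any uncovered fragment would be an
  implementation bug.
* `plant_feature()` — copies an interval verbatim (`exact_repeat`) or with
  i.i.d. per-base mutations (`near_duplicate`), recording ground-truth
  intervals and realized identity.
* `make_screening_truth()` — candidates whose correct verdict is known by
  construction: inside a planted exact repeat of ≥ 18 bp the verdict must
  be the long-match rule-out; in regions free of planted structure the
  verdict must be acceptance.

What the generator does *not* emulate: real genomic repeat families, GC
skew and codon structure, gene-scale homology, or ambiguous bases at
assembly gaps. Passing the suite therefore demonstrates the screening
rules, the thermodynamic bookkeeping, and the two-pass logic — not
performance claims on any particular organism. Problem sizes in the suite
and acceptance run (genomes of 0.6–5 kb, 100-bp fragments, 36–46-bp
probes) were chosen so the full two-pass design is exercised end-to-end
many times with margins large enough that verdicts are stable across
seeds.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open on the top strand everywhere; genomes
  are linear (no boundary window wraps an end; a circular mode is
  deliberately not implemented).
* Tm values serialize at two decimals in the probe-table dialect; full
  precision is kept in memory.
* The rule-out threshold is inclusive (a ≥ 18 bp match rules out):
  "maximum match length 18" is read as *17 is the largest tolerated exact
  match*, the stricter of the two readings, and the parameter is
  configurable.
* A fragment shorter than the minimum probe length yields no candidates
  and is recorded as uncovered, not an error; an empty genome record is an
  error.
* Ties in probe selection resolve by smaller start coordinate, making the
  design a pure function of its inputs. The `seed` parameter exists for
  alternative randomized tie-breaking policies and is unused by default.

## Known limitations

* Internal loops larger than the tabulated mismatch/bulge coverage,
  probe hairpin/self-structure, Mg²⁺ corrections, and surface/position
  effects are out of scope of the energy model.
* The audit locates coordinate-free probes by exact top-strand search; a
  probe absent from the genome is audited against all of its partial
  matches with an undefined target Tm rather than being guessed.
* Screening is exhaustive within the seed-and-extend horizon: a nontarget
  duplex with no exact match of at least 8 bp is invisible to the screen.
  This mirrors the screening thresholds of the published method — the
  minimum-match parameter bounds what "every potential cross-hybridization"
  means operationally.
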