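---
title: "Screening cross-subunit ATP sites and the phosphoketolase regulatory motif: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cross-subunit ATP sites and the phosphoketolase regulatory motif: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosite)
```

## The biological problem

Cyanobacterial phosphoketolase (XPK) is switched off by ATP through an
unusual allosteric site: the enzyme assembles into face-to-face dimers
(stacked into a dodecamer), and two ATP molecules bind head-to-head at the
dimer interface, roughly 30 Å from each catalytic (thiamine-pyrophosphate)
site. Each adenine ring is *sandwiched* between a histidine from one
subunit and a tyrosine from the other, both engaging it by π–π stacking,
while an arginine from the reciprocal subunit forms a salt bridge with the
γ-phosphate. No aspartate/glutamate or divalent metal coordinates the
phosphates — the site is held together by aromatic stacking and
arginine/histidine charges. The residues involved fall on a short
C-terminal stretch with eight conserved anchors, giving a sequence motif
that can be surveyed across protein families.

This package implements the two computational procedures attached to that
discovery — a geometric screen for the binding mode in nucleotide-bound
structures, and a positional scan for the regulatory motif in sequences —
plus the supporting analyses (Cα superposition, conservation logos,
neighbor-joining trees) and synthetic-data generators that make every stage
testable without any external downloads.

## The geometric screen

### Criteria and anchors

A candidate site must satisfy, for one ligand copy:

1. **Aromatic pair contact.** At least two residues from {Tyr, Trp, Phe,
   His} whose side-chain γ-carbon `CG` lies within `dAromatic` (default
   **5 Å, inclusive**) of the adenine `C5` atom. `C5` sits at the fusion of
   the purine's two rings, so it is a stable proxy for "near the adenine";
   `CG` is the first side-chain carbon shared by all four aromatic types.
2. **Arginine–γ-phosphate contact.** An arginine whose `CZ` (the
   guanidinium carbon) lies within `dArg` (default **5 Å**) of the
   γ-phosphate phosphorus `PG`. ADP and AMP have no `PG`, so in the
   extended, criterion-1-only search they can never satisfy this.

Supported ligand codes are ATP and its five non-hydrolyzable analogs (ANP,
ACP, APC, ZAN, AGS), plus ADP/AMP in criterion-1-only mode.

### Stacking assessment

The distance criteria alone admit edge-on aromatics, so candidate contacts
are refined by explicit stacking geometry. We fit least-squares planes
through the ligand's nine purine atoms and through the side-chain ring
(6-ring for Tyr/Phe, 5-ring for His, the full 9-atom indole for Trp) and
call a contact *stacked* when the ring-centroid separation is at most
`stackingCentroidMax` (default **5 Å**) and the interplanar angle, folded
into [0°, 90°], is at most `stackingAngleMax` (default **30°**). These are
standard literature thresholds for face-to-face π–π geometry; the angle
fold means anti-parallel planes count as parallel, as they should.

### Pair selection and the tier ladder

When more than two aromatics qualify, the reported pair is the one with
the smallest summed C5–CG distance — equivalently, the two closest
contacts. This choice makes tier assignment provably monotone in the
cutoffs: tightening `dAromatic` can only delete the farther contacts, so
it can never swap a nearer, differently-chained pair into the report.
Sites are ranked on a cumulative ladder — `T1_pair_contact` (≥ 2 aromatic
contacts), `T2_cross_subunit` (the pair spans two chains),
`T3_dual_stacking` (both members stacked), `T4_full` (plus an arginine
contact; requires a γ-phosphate). `T4_full` is the full signature of the
cross-subunit sandwich.

Two deliberate interpretations where the procedure needed pinning down:
the arginine is not required to come from any particular chain (the screen
records the contact's chain so callers can impose one), and each ligand
copy is screened independently, with a per-entry summary taking the
maximum tier over copies (`tierCounts(..., by = "entry")` vs `"site"`).

## Structure handling

Files are parsed through `bio3d` (both PDB and mmCIF) into a single flat
atom table. Conventions, chosen once:

* only the **first coordinate model** of multi-model files is used (the
  deposition convention for cryo-EM/crystal structures);
* **hydrogens are dropped**; every criterion uses heavy atoms only;
* **altlocs collapse** to the highest-occupancy conformer, ties broken
  alphabetically (so `A` wins);
* residue numbering is **author numbering** (this is what makes "P702"
  meaningful);
* the deposited asymmetric unit is taken as-is — no symmetry-mate or
  assembly expansion. A screen over deposited coordinates can therefore
  miss a cross-subunit site whose partner chain is crystallographically
  implied but not deposited; this is a known limitation, not a bug.

## Superposition and site distances

Ligand-bound and free forms of the same construct are compared by pairing
Cα atoms on identical (chain, residue number, insertion code, residue
type) and solving the least-squares rotation with the SVD form of the
Kabsch algorithm, with the reflection excluded by sign-correcting the
smallest singular vector. A single pass is used — no outlier-rejection
iterations — because the quantity of interest is the plain Cα RMSD.
Degenerate (collinear) point sets are rejected. The independent check in
the test suite minimizes RMSD numerically over rotation space and agrees
with the closed form to 10⁻⁶ Å.

"Distance to the catalytic site" is operationalized as the heavy-atom
centroid distance from the nucleotide to the nearest thiamine-pyrophosphate
(TPP) residue, since TPP marks the active site.

## The motif scanner

The motif is `P W x(2) H x(3) Y R x(7) H x R x(31) R`: eight anchors at
offsets 0, 1, 4, 8, 9, 17, 19, 51 from the leading proline, a 52-residue
span. With `fungalVariant = TRUE` the offset-9 arginine (the residue that
reaches across to the reciprocal ATP's γ-phosphate) may also be lysine, as
in fungal homologs. `X` never matches an anchor.

Scanning operates on **unaligned sequences with exact spacing**. The
original survey checked residue identity inside a multiple alignment,
which tolerates indels between anchors; exact-spacing scanning is the
stricter reading, and it is what makes prevalence on synthetic families an
exact, deterministic quantity rather than a statistical one. For real
families with small indels an optional `spacerSlack` parameter lets each
of the seven inter-anchor spacers stretch by up to that many residues
(default 0); the leftmost placement is reported. Anything the slack scanner
accepts at slack *s* it also accepts at slack *s* + 1, so the default is
the most conservative.

Percent identity — the stand-in for a similarity-search retrieval step,
chosen so the pipeline needs no network and is deterministic — is computed
by Needleman–Wunsch global alignment with unit match score, zero mismatch
and affine gaps (open 10, extend 0.5), counting identical columns over all
aligned columns including internal gaps. Surveys filter at
`minIdentity = 60`% by default, the threshold used to delimit the family.

## Logo data and trees

`anchorWindows()` tallies a position-frequency matrix over each anchor ±
`flank` residues (default 3; the flank width is a display choice, so it is
a parameter). Overlapping windows merge; positions outside a sequence
count as gaps. Information content per column is log₂20 − Shannon entropy
of the residue frequencies, with a **uniform background** and **no
small-sample correction** (intended use is hundreds-plus of sequences),
and gaps excluded from the frequencies rather than treated as a 21st
symbol. The bounds are [0, log₂20 ≈ 4.3219] bits.

Trees use the uncorrected **p-distance** (mismatches over gap-free
columns) — the simplest defensible model for protein families at ≥ 60 %
identity, where multiple substitutions per site are rare — followed by
Saitou–Nei **neighbor joining**. Ties in the Q-criterion break at the
lowest index pair, so output is deterministic; negative branch-length
estimates are clamped to zero with the deficit moved to the sibling branch
so the joined pair's path length is preserved. On additive matrices the
tree reproduces the input distances exactly (tested to 10⁻⁹). Newick
serialization is written directly from the join list and parsed back with
`ape`, so the round-trip is itself a test. Alignment construction is out
of scope: callers supply aligned input, and the synthetic generator emits
gap-free families that are trivially aligned.

## The synthetic-data generators

### Binding sites

`makeBindingSiteStructure()` realizes a `siteGeometry()` design: an
idealized planar purine (regular hexagon + fused pentagon, 1.39 Å bonds)
with correctly named atoms and a phosphate tail, two aromatic rings placed
one on each face, an arginine positioned off the γ-phosphate, and inert
poly-glycine scaffolds establishing each chain. Ring placement solves for
the lateral offset and ring phase that realize the requested ring-centroid
distance, interplanar angle *and* C5–CG distance simultaneously; the phase
equation is closed-form (the squared distance is sinusoidal in the phase),
so planted values are realized to ±0.01 Å and infeasible requests fail
loudly. A seeded random rigid transform is applied last so fixtures are
never axis-aligned. Decoy modes violate exactly one condition each —
aromatics beyond the cutoff, a single aromatic, a same-chain pair,
destroyed stacking, or a missing arginine — and the expected tier is
derived from the final design fields and recorded as the ground-truth
label.

Defaults mirror the characterized site: His706 on chain A and Tyr710 on
chain B at 4.0/4.5 Å C5–CG with near-parallel stacking, Arg711 (chain B)
at 3.8 Å PG–CZ, and an ANP (AMPPNP) ligand.

What the generator does **not** emulate: real rotamer chemistry, backbone
continuity, crystallographic noise, partial occupancy, or crowded pockets
with many competing aromatics. Passing the end-to-end label-recovery suite
therefore demonstrates that the screen implements its stated geometry
exactly — not that the cutoffs are optimal for any particular survey of
real depositions, which additionally depends on database composition.
Generator plant types are Tyr/Phe/His; Trp stacking assessment is
implemented and tested against an analytically constructed indole, but
Trp is not a plant type.

### Sequence families

`makeSequenceFamily()` derives each member from a random reference with
the motif planted at position 702 (by default) in an 800-residue
background: a per-member identity target is drawn from the band (default
70–95 %), converted to an exact mutation count over non-anchor positions;
motif-negative members additionally have one anchor destroyed (to a
residue outside every anchor's allowed set, so neither the canonical nor
the fungal spec matches). Prevalence, fungal fraction and identity are
thus exact by construction, and the family is byte-identical under a fixed
seed. Defaults (200 sequences, 75 % prevalence, 60 % identity floor) give
a family in which the survey's filter and scanner both do non-trivial
work. Real families differ in having indels, compositional bias and
phylogenetic correlation — none of which the generator models, which is
why tree *topology* on synthetic families is only checked for additivity
and determinism, not biological structure.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: a 100-fixture structure library
(balanced across the six design modes), 200-sequence families, 4–8-taxon
additive matrices, and 40–50-point superposition sets — sizes at which
every oracle (brute-force O(n²) distance scans, window-by-window motif
checks, numerical rotation search, path-length additivity) is itself fast
and exact. Key tolerances: planted geometry ±0.01 Å; rigid-transform
invariance 10⁻⁶; Kabsch vs numerical optimizer 10⁻⁶ Å; NJ additivity
10⁻⁹; identity and prevalence exact. Angle computations guard the acos
domain; all tie-breaks (contact ordering, Q-criterion, altlocs) are
lexicographic so every output is deterministic.

## Known limitations

* No assembly expansion: cross-subunit geometry is judged on deposited
  chains only.
* Exact-spacing motif scanning undercounts motif occurrences interrupted
  by indels unless `spacerSlack` is raised.
* Global-alignment identity is not BLAST local identity; thresholds
  calibrated against BLAST retrievals transfer only approximately.
* The NJ implementation targets the few-hundred-taxon scale of motif
  surveys, not genome-scale trees.
* Published database hit counts from historical snapshots are inherently
  irreproducible and are not targets of this package.
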