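---
title: "Localizing disordered C-terminal tails from frozen-core trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing disordered C-terminal tails from frozen-core trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtail)
```

## The problem

Group I chaperonins such as *E. coli* GroEL are double-ring 7-mer machines
whose last ~23 residues — a hydrophilic motif followed by low-complexity
Gly-Gly-Met repeats after Pro-525 — are invisible in every crystal structure:
the termini are intrinsically disordered and exist as a conformational
ensemble. Where that ensemble sits inside the ring matters, because the
tails have been implicated in substrate binding and encapsulation. A
practical way to localize a disordered segment is statistical rather than
structural: simulate the tails moving over a fixed scaffold, count
residue–residue contacts over many trajectory segments, and ask which
scaffold residues the terminus touches most.

`ringtail` implements that analysis chain as reusable, tested components:

1. **Tail building** — seeded, clash-avoiding chain growth appends the
   crystallographically missing residues as Cα-level beads
   (`build_tail()`).
2. **Frozen-core Langevin simulation** — only the tails (plus an optional
   hinge residue) move; the N-terminal core is an exact freeze group
   (`define_freeze()`, `run_langevin()`).
3. **Contact maps** — per-segment residue–residue contact matrices over
   frames (`compute_contact_map()`), summed across segments and divided by
   the matrix maximum (`aggregate_and_normalize()`).
4. **Ring-symmetry averaging** — the global map is tiled into
   monomer×monomer blocks and all blocks over a monomer subset are summed
   into one monomer-frame matrix (`tile_blocks()`, `sum_blocks()`).
5. **Terminal analysis** — tail-row submatrices, single-residue profiles
   with intra-tail zeroing, ranked partners
   (`terminal_profile()`, `rank_partners()`).
6. **Projection** — per-residue scores painted into the B-factor column of
   a PDB file for rendering (`project_scores()`), plus Kabsch superposition
   with iterative outlier rejection for conformer comparison
   (`align_with_rejection()`).

Because the full-scale all-atom protocol (190 ns of implicit-solvent MD per
conformer for a 14-mer of 547-residue subunits) is far beyond desk scale,
the package ships a coarse-grained synthetic-trajectory generator with
*designed* contact preferences. It is a first-class, tested module: its
whole point is that the analysis chain can be validated against a known
ground truth.

## The contact statistic

For residues $i$ and $j$ with atom sets $A_i$, $A_j$, the per-frame
dissimilarity is the minimum cross-pair distance
$d_{ij} = \min_{a \in A_i, b \in A_j} \lVert x_a - x_b \rVert$
(the "smallest distance" semantics of classic MD contact-matrix tools). Two
matrix modes are provided:

* **frequency** (default): $M_{ij}$ is the fraction of frames with
  $d_{ij} < d_c$; diagonal fixed at 1. Contact-map figures in this field
  are usually read as "how often do these residues touch", so this is the
  figures-facing default.
* **mean smallest distance**: $M_{ij}$ is the time average of
  $\min(d_{ij}, d_c)$; diagonal 0. This is the native output of
  `g_mdmat`-style tools. Both conventions circulate in the literature and
  are rarely distinguishable from a rendered heat map, so both are
  provided.

Per-segment maps of one conformation are summed and the sum divided by its
maximum entry, so the strongest contact is exactly 1. The diagonal is
excluded from the maximum search in frequency mode — it is trivially 1 in
every frame and would otherwise swamp the normalization; this is recorded
as this package's convention. Aggregation sorts segments by id before
summing, making the
result independent of input order at the bit level.

**Symmetrization.** With $n$ monomers of $L$ residues under dense global
indexing $g = mL + r$, the global map tiles losslessly into $n^2$ blocks
$B^{(a,b)}_{rs} = M_{aL+r,\,bL+s}$. The symmetrized map is
$S = \sum_{a,b \in \text{subset}} B^{(a,b)}$, summed over *ordered* pairs
including $a = b$. The subset mechanism is how hetero components (a GroES
cap, say) are excluded: restrict the sum to the ring of interest.
Whether to re-normalize after summation is a presentation choice, so
`sum_blocks(normalize =)` exposes both and records which was taken.
Intra-only and inter-only decompositions are also available.

**Terminal profiles.** The profile of the last residue (M548 in GroEL
numbering) is its row of $S$ with a configurable set of author-number
ranges set to exactly zero — by default the whole tail, since
sequence-local contacts are trivially the strongest signal and would mask
the scaffold contacts of interest. Ranking of partners is deterministic:
descending score, ties broken by ascending author residue number.

## Author numbering

All user-facing I/O uses author residue numbers verbatim. GroEL monomers
hold 547 residues yet end at residue 548 because Met1 is absent from the
models; renumbering would disconnect the residue labels used throughout
the GroEL literature (R268, M267, V263, L259, Pro-525, M548) from the
output. Internally a dense
0-based index map (`residue_index_map()`) provides the $g = mL + r$
coordinate system; the two are bijectively linked and round-trip tested.

The freeze group follows the same convention: `define_freeze(sys, 23,
include_hinge = TRUE)` on a 547-residue monomer freezes the N-terminal 523
residues. That split leaves 24 residues mobile — one more than the
23-residue tail — because whether the residue preceding the tail (Pro-525)
should hinge is a genuine modelling choice; `include_hinge` exposes both
readings rather than baking one in.

## The synthetic generator

`make_ring_scaffold()` builds an exactly $C_n$-symmetric ring of bead
monomers: each core is a vertical column whose chain runs top to bottom, so
the C-terminal anchor sits at the column base — as GroEL's C-terminus does
in the equatorial domain — and a mobile tail grows from it by the same
clash-avoiding procedure used for real structures. Two core beads per
monomer are designated sites: an *apical* bead near the top of the column
(standing in for the substrate-binding face of helix I) and an
*equatorial* bead near the base (standing in for the stem loop). Gaussian
attraction wells of depth $\varepsilon$ on one site set or the other give
two generation modes with known ground truth:

* **open mode** — tails attracted to the apical sites, emulating the
  apical localization of the termini seen in ATP-bound and apo rings;
* **closed mode** — tails attracted to the equatorial sites, emulating the
  retreat of the termini toward the stem loop when the ring is capped.

The dynamics are BAOAB-split Langevin in reduced units ($k_BT = 1$, bead
mass 1, diameter $\sigma = 1$): harmonic bonds along the tails and at the
anchor, WCA purely repulsive excluded volume between every mobile–any
non-bonded pair, and the attraction wells
$U(r) = -\varepsilon e^{-r^2/2r_w^2}$. Nominal physical temperatures
(370 K) and durations (10 ns) are protocol *labels* carried as metadata — a
coarse-grained bead model cannot honor them physically, and pretending
otherwise would be dishonest; `sim_params(temperature_label = 370)` records
them without letting them touch the dynamics.

### Default study conditions

| parameter | default | why |
|---|---|---|
| ring size $n$ | 3 | smallest ring with distinct inter-monomer blocks |
| core length $L_\text{core}$ | 4 beads, spacing 1 σ | both sites within reach of the tail |
| tail length | 5 beads | shortest tail that must *traverse* the core to reach the far site |
| apical site | core residue 1 (column top) | farthest scaffold point from the anchor |
| equatorial site | core residue 3 (one above the anchor) | nearest distinct scaffold point |
| well depth $\varepsilon$ | 3 kT | strong enough to bind, weak enough to exchange |
| well range $r_w$ | 1.5 σ | capture radius reaches the tail's thermal cloud |
| $k_\text{bond}$ | 100 kT/σ² | stiff bonds; sets the timestep bound |
| $dt$ | 0.001 | the enforced stability bound $0.01\sqrt{m/k_b}$ |
| friction γ | 1/τ | diffusive but not overdamped |
| steps per segment | 2×10⁵ | tail diffusion time ≪ segment length |
| frames | every 100 steps | decorrelated contact samples |
| contact cutoff $d_c$ | 1.3 σ | first coordination shell of a WCA bead |

The geometry was designed (and is verified by the test suite) so that the
two modes are discriminable: the open-mode terminal profile peaks at the
apical site and the closed-mode profile at the equatorial site in at least
9 of 10 seeds, both by argmax and by mean-score ranking. For Å-unit
systems the contact default is instead $d_c = 4.5$ Å, the conventional
heavy-atom contact distance.

What the generator deliberately does **not** emulate: all-atom packing and
side-chain chemistry, implicit-solvent electrostatics, sequence-specific
tail–scaffold affinities, and the 7-fold/14-mer scale of the real system.
Passing the recovery suite therefore shows that the *analysis chain*
faithfully extracts a designed localization signal from trajectories — not
that the coarse-grained physics reproduces chaperonin behaviour.

## Protocol bookkeeping

`schedule_segments(n_equil, equil_ns, n_prod, prod_ns)` reproduces the
equilibrate–subsample–produce protocol: the canonical shape
`schedule_segments(5, 10, 19, 10)` gives 19 production segments and 190 ns
of nominal production per conformer. The rule for drawing starting
conformers from the equilibration runs is underdetermined by the protocol
shape alone; this package draws them at evenly spaced frames of the pooled
equilibration trajectory and records that rule in the manifest.
Segment seeds derive from the base seed by fixed offsets, so a pipeline
run is bit-reproducible including its written files.

## Superposition

`kabsch()` is the closed-form least-squares rigid superposition with the
reflection case corrected (det = +1), validated against a numerical
minimizer over rotation vectors. `align_with_rejection()` pairs atoms by
monomer-relative residue number and atom name (author-number offsets
reconciled) and alternates fitting with pruning of pairs whose deviation
exceeds `sigma_factor` times the RMS pair deviation, defaulting to 5
cycles at 2.0 — conventional for PyMOL-style alignment. The spread
measure is the RMS about
zero rather than a centered standard deviation: deviation norms are
one-sided, and a centered sd collapses the retained set on clean inputs.
Both the retained-pair RMSD and the all-atom RMSD of every pair under the
final transform are reported, because quoted all-atom RMSD values are
often ambiguous between the two.

## Numerical choices and degenerate inputs

* Timestep stability bound $dt \le 0.01\sqrt{m/k_b}$ enforced at
  `sim_params()` construction; non-finite coordinates abort with the step
  number.
* Frozen beads are never integrated — their displacement is exactly zero,
  not small.
* Randomness inside the C++ integrator uses R's RNG stream, so
  `set.seed()` gives bit determinism across the whole pipeline.
* Tail growth excludes only the bonded predecessor from the clash set
  (consecutive beads sit at `bond_length` < `clash_radius`); placement
  failure reports the residue reached.
* B-factor projection is linear min–max to the format's 0–99.99 range; a
  degenerate (all-equal) score range maps to 0.00, and unscored residues
  get 0.00.
* Normalization of an all-zero aggregated map is an error, not NaN.
* `rank_partners()` with more requested than available nonzero entries
  returns all nonzero entries and flags the result.

## Problem sizes

The shipped tests and the acceptance script run entirely at the
demonstration scale chosen for the synthetic ring: contact-map oracle
checks at ≤ 50 residues × 20 frames, simulator physics at 10⁵–2×10⁶ steps
on 1–51 beads, and the two-mode recovery study at 10 seeds per mode ×
2×10⁵ steps. These sizes were chosen so the full validation study is a
few minutes of a single CPU; the pipeline itself scales to larger rings
and longer runs through the same configuration surface.

## Known limitations

* The coarse-grained generator is a test bed, not a physical model of
  chaperonin energetics; its temperatures and durations are labels.
* XTC trajectories are not read natively (multi-model PDB and DCD are);
  mmCIF is not written.
* Monomer ids map to single-character PDB chain ids on output.
* No statistical significance is attached to contact enrichment — the
  profile is a descriptive statistic.
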