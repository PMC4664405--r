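---
title: "From lysine cross-links to structural restraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lysine cross-links to structural restraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmapr)
```

xlmapr implements the computational chain behind a BS3 cross-linking study
of the sGC–PDI interaction: identifying cross-linked peptide pairs in MS/MS
data, converting identified lysine–lysine cross-links into distance
restraints on coordinate models, screening docking poses against those
restraints with an internal control, deciding whether one ligand molecule
can bridge two receptor sites, and quantifying co-IP densitometry. This
vignette records the models, the tunable parameters, and the design
decisions taken where the procedure was genuinely open.

## Mass model for cross-linked peptides

A peptide's neutral mass is the sum of its residue masses (monoisotopic or
average scale) plus water plus positional modification deltas. Two fixed
deltas matter here:

* **Carbamidomethyl (CAM), +57.02146 Da per Cys.** The samples are alkylated
  with iodoacetamide before digestion, so CAM is treated as a fixed
  modification on every cysteine.
* **BS3 bridge, +138.06808 Da per cross-link (C8H10O2).** The mass added by
  one intact suberate bridge between two primary amines, i.e. the reagent
  minus its two sulfo-NHS leaving groups. Hydrolysed dead-end ("mono-link")
  species are not modelled.

A cross-linked pair's mass is `m(A) + m(B) + 138.06808`, and the precursor
m/z at charge z is `(M + z·1.00728)/z`. For the worked-example pair (the
21-mer with two CAM cysteines bridged at its internal lysine, plus
TETTGEKGK bridged at position 7) this gives 3562.7072 Da and, at charge 4,
m/z 891.68 — matching the printed spectrum annotation. The source figure
labels that precursor "6+", which is arithmetically inconsistent with the
printed m/z for these sequences (6+ gives 594.79); the package therefore
never hard-codes the charge, and the acceptance test records the
inconsistency while checking the m/z itself at charge 4.

Fragment ions follow the b/y convention. Any b- or y-ion whose residue span
contains the linked position carries an *appendage*: the bridge delta plus
the full modified mass of the intact partner peptide. This is what makes
cross-linked spectra diagnostic: for a link at position p of an n-mer, the
smallest appendage-carrying y-ion is y(n−p+1), so observing the appendage
first at y9 on the 21-mer (link at 13) and at y3 on TETTGEKGK (link at 7)
localises both link sites. a/x/c/z series, neutral losses and isotope
envelopes are out of scope.

## Digestion and decoys

Trypsin cleaves C-terminal to K/R except before proline (the standard rule;
the source only names the enzyme). Defaults mirror the search settings used
in the study: up to 4 missed cleavages, peptide length 6–50. Decoy databases
are reversed (deterministic) or randomized (seeded) permutations of the
target sequences, preserving length and composition.

Link-site eligibility encodes the chemistry: BS3 reacts with lysine
side-chain amines and free protein N-terminal α-amines. A lysine at a
peptide's C-terminal boundary is *not* an eligible site unless it is the
protein C-terminus — a BS3-blocked lysine is not cleaved by trypsin, so a
genuine internal link implies a missed cleavage (the worked-example
TETTGEKGK carries its link on an internal K). The N-terminal rule supports
links observed at the very start of a chain (e.g. a K5 link).

## Search scoring

The original search engine's exact scoring formulas live in its own
publications and are not reproduced; the three scores are re-specified as
transparent statistical analogues with the same *meaning*:

* `score` — the number of theoretical b/y ions (both chains, product-ion
  charges 1..min(z−1, 2); implemented as 1..max(1, min(z−1, 2)) so singly
  charged precursors still yield singly charged fragments) matched by an
  observed peak within the fragment tolerance.
* `pp` — could this many matched ions be random? The −log₁₀ upper-tail
  probability of ≥ `score` successes in Binomial(N_theoretical, p_rand),
  with p_rand = min(1, n_peaks · 2 · tol / span(m/z)): the chance that one
  theoretical m/z lands within tolerance of some peak if peaks were uniform
  over the observed span. Computed on the log scale, so it stays finite.
* `pp2` — could the matched *abundance* be random? The −log₁₀ permutation
  probability (default 1000 draws, mandatory seed) that a random peak subset
  of the same size reaches the matched total intensity.

Defaults: precursor tolerance 10 ppm, fragment tolerance 0.02 Da —
instrument-class defaults for an Orbitrap; the source prints neither, so
both are configurable. Charge handling follows the stated rule: declared
charges are used as-is, spectra declared 1+ are searched at 1+, and
undetermined spectra are searched at 2+ and 3+ (the configured charge list
minus 1). The per-spectrum winner is the highest `score`, tie-broken by
higher `pp` and then lexicographic pair identity, so output is
deterministic. The report thresholds (defaults score ≥ 5, pp ≥ 2) are
exposed configuration, *not* the original engine's unpublished cutoffs;
analyses that need a principled cutoff should derive one from the
target-decoy FDR table (`decoy_fdr`), as the acceptance test does.

## Restraint geometry

Cross-linked residues are represented by an anchor atom: lysine NZ when
present, else CB, else CA (the source does not name the atom; NZ is the
default and fallbacks are reported per evaluation). The acceptance cap is
15 Å between anchors — lysine side-chain reach plus the 11.3 Å BS3 spacer —
applied as ≤ (a distance exactly at the cap satisfies). The spacer length is
carried as metadata; an optional stricter control rule (≤ spacer + 1 Å
slack) is available for receptor-internal control cross-links, motivated by
a control observed at 11.2 Å, essentially the spacer length. The default
control rule is the same 15 Å cap.

PDB handling is deliberately minimal (ATOM/HETATM records, altloc resolved
to highest occupancy, first instance of each chain kept for multi-copy
crystals); no installed R package provides PDB parsing in this environment,
so the fixed-column reader/writer is implemented here. mmCIF, solvent
chemistry and energetics are out of scope.

**Bridging feasibility.** Each satisfied cross-link confines its ligand
anchor to a ball of radius `cap` around the receptor anchor. Treating the
two ligand anchors as colocated gives the simple bound: one ligand can
engage both receptor sites only if the receptor anchors are within
2·cap = 30 Å ("paper" mode). "Triangle" mode uses the ligand's own anchor
separation: a rigid placement exists iff |d_receptor − d_ligand| ≤ 2·cap,
which is exact for unconstrained rigid placement (verified in the tests
against a brute-force placement grid). The colocated bound is never more
permissive than the triangle bound while the ligand anchors are within
2·cap of each other. With receptor anchors 61.3 Å apart, both bounds fail
decisively — the mutual-exclusivity verdict.

## Coarse-grained tail sampling

The unresolved C-terminal tails carrying the cross-linked lysines were
extended in the original study by all-atom MD (Amber, 4 × 100 ns, NPT
Langevin). That protocol is deliberately replaced: the quantity extracted is
purely geometric — the closest achievable distance between two tail
residues — which a Cα-level self-avoiding chain sampler bounds and
approximates at desk scale. Beads are grown from the anchor Cα at a fixed
3.8 Å virtual bond with uniform random directions, rejecting placements
within a 4.0 Å clash radius of resolved Cα atoms or earlier beads (the
bonded predecessor excluded); conformers exhausting the retry budget are
discarded and counted. The estimator reports the minimum over all sampled
conformer pairs — an upper bound on, and with growing n an estimate of, the
geometric minimum. On the toy geometry with anchors 20 Å apart and one
residue per tail the closed form is 20 − 2·3.8 = 12.4 Å and the sampler
converges within 0.5 Å by n = 5000. The MD-derived distances themselves
(61.3 Å, 11.2 Å) are *not* claimed reproducible here; they enter as inputs
to the feasibility logic. A configurable +6.4 Å side-chain extension can be
added when comparing Cα-based tail positions against NZ-based caps (off by
default). Whether the original minimum was taken across averaged structures
or frames is unstated in the source; this estimator reports the ensemble
minimum and labels it as such.

## Pose screening

Docking poses (ligand already in the receptor frame, as rigid-body docking
emits them) are evaluated independently: a pose is accepted iff every
evidence restraint is satisfied and every control restraint passes.
Unevaluable poses (unresolvable anchors) are counted, never silently
dropped. Whether a given screening scenario uses one receptor–ligand
restraint or several is left to the caller — the two-model presentation of
the source (an α-site pose set and a β-site pose set, each with its own
single evidence restraint plus the internal control) maps to two calls with
different restraint subsets. Verdicts are invariant to pose order and to
rigid transforms applied jointly to receptor and ligand, which the tests
assert.

## Densitometry statistics

Bound/input ratios are computed per replicate; group summaries report the
mean and SEM = SD/√n (the standard convention for "±" at n = 3; the source
does not state its convention, which is flagged here). "Student's t-Test"
is interpreted as the two-sample pooled-variance two-sided form
(independent condition groups, n = 3–5), with Welch's form behind a flag
and explicit degenerate handling (zero pooled variance: p = 1 with equal
means, p = 0 with a warning otherwise). No multiple-testing correction is
applied, matching the mirrored analysis; this is noted rather than silently
"fixed". Band extraction from gel images is out of scope — the module
starts from numeric intensities.

## The synthetic world

Every input is generated with known ground truth, so each stage is testable
offline:

* **Structures** — lysine anchors placed by classical MDS to reproduce a
  target distance matrix within 0.01 Å; triangle-violating or
  non-embeddable requests are rejected. Fixtures carry NZ and CA atoms only.
* **Poses** — exactly ⌊f·n⌋ poses satisfy every evidence restraint by
  construction (ligand anchor placed inside the cap ball; violators placed
  in a band beyond it). The default world mirrors the source's ensemble:
  100 poses, 7 satisfying.
* **Spectra** — a stated fraction of each pair's theoretical ions at exact
  m/z plus uniform noise peaks over the 300–1650 m/z acquisition window,
  intensities log-normal (signal above noise on average). The source gives
  no noise model, so this one is fixed and documented; no isotope patterns
  or chromatography.
* **Densitometry** — replicate ratios Normal(mean, SD) truncated at zero,
  inputs log-normal, bound = ratio·input. The default condition table uses
  the reported group means (1.08/0.74/0.76) with per-replicate SDs
  back-computed from the reported SEMs at n = 3.

All generators are pure functions of (configuration, seed).

What a green test establishes — and what it does not: planted-truth
recovery shows the pipeline's bookkeeping and decision rules are correct on
data matching its assumptions (exact fragment m/z, uniform noise, rigid
poses, normal ratios). It does not establish performance on real spectra
(calibration drift, isotope clusters, co-isolation) or real pose ensembles.

One statistical note: the generator-coverage property ("planted mean within
2 SEM of the estimate in ≥ 93% of runs") is checked at n = 20 replicates,
where the 2-SEM interval has near-nominal coverage. At the experimental
n = 3 the heavy t₂ tails make a 2-SEM interval cover only ~82% — a property
of the interval, not a defect of the generator — so asserting ≥ 93% there
would be wrong.

## Numerical choices and limitations

* Proton mass 1.00728 Da; m/z printed to 2 decimals where the source prints
  2 decimals. Monoisotopic masses to 5 decimals.
* Candidate enumeration uses a sorted-mass window search; results equal
  brute-force pair enumeration (tested).
* The pp2 permutation count (1000) and every stochastic component require
  an explicit seed; identical seeds give byte-identical outputs.
* The construct-mass utility (average masses over residue ranges of the
  sGC α sequence) is implemented and unit-tested on synthetic sequences,
  but checking the printed kDa values requires the full-length UniProt
  sequence, which is not bundled and cannot be fetched offline; the
  corresponding acceptance test fails by design in offline environments
  unless a copy is provided under `inst/extdata/Q02108.fasta`.
* The catalytic-domain construct range follows the cloning methods
  (466–690); the source's results text says 460–690 in one place — the
  discrepancy is documented in `sgc_alpha_constructs()`.
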