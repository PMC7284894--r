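---
title: "From marker genes to genus-specific LAMP assays: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker genes to genus-specific LAMP assays: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampgen)
```

## The problem

Hydrogenotrophic methanogens (*Methanoculleus*, *Methanothermobacter*,
*Methanococcus*, *Methanobrevibacter*) drive CO~2~-reductive
methanogenesis in anaerobic digesters, sediments and the gut. Monitoring
them by sequencing is slow and costly; loop-mediated isothermal
amplification (LAMP) offers a one-temperature, under-an-hour, low-cost
alternative — if genus-specific primer sets can be designed. `lampgen`
implements the in-silico arm of that workflow:

1. **Marker screening** — find KEGG orthologue (KO) groups whose every
   occurrence in an ORF catalogue is archaeal, then score candidate genes
   by cross-group alignment identity. The archaeal elongation factor 2
   gene (aEF-2, *fusA*, K03234) is the canonical outcome of this screen:
   single-copy, universally archaeal, and conserved enough within orders
   to align well while diverging between genera.
2. **Consensus extraction** — detect conserved tracts in a multi-genus
   nucleotide alignment (per-column identity strictly greater than 0.8)
   and emit IUPAC degenerate consensus sequences.
3. **LAMP design** — enumerate and assemble six-primer sets (F3/B3
   outer, F2/B2 + F1c/B1c inner, optional FL/BL loop primers) under
   explicit length, Tm, GC, end-stability, dimer and spacing windows,
   composing FIP = F1c + `TTTT` + F2 and BIP = B1c + `TTTT` + B2.
4. **Specificity** — exhaustive mismatch-tolerant scanning of primer sets
   against labelled sequence databases, with a geometric positivity rule.
5. **Phylogenetic placement** — Jukes–Cantor distances,
   neighbour-joining, bootstrap, Newick output.

A synthetic-data module generates every input with planted, known
structure, standing in for unpublished metagenome assemblies and culture
genomes.

## Statistical and thermodynamic model

### Column identity and consensus

For an alignment column the identity fraction is the modal base count
divided by the number of non-gap rows. Conserved regions are maximal runs
of columns with identity **strictly greater** than the threshold
(default 0.8) — a column at exactly 0.8 splits a run — and with per-column
gap fraction at most `max_gap_frac` (default 0.1; the gap rule is our
decision, made explicit and overridable, since per-position identity
thresholds are conventionally silent about gaps). The degenerate
consensus emits, per column, the IUPAC code covering exactly the bases at
frequency ≥ `min_base_frac` among non-gap rows. The default of 0.2
reproduces the 2–3-fold degeneracy typical of consensus primers built
from a handful of genomes; `N` appears only when all four bases qualify.

### Nearest-neighbour thermodynamics

Melting temperatures use the unified DNA nearest-neighbour parameter set
(ten stack enthalpies/entropies plus terminal initiation terms) with the
monovalent-salt entropy correction
$\Delta S_{salt} = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$ and

$$T_m = \frac{\Delta H \times 1000}{\Delta S_{salt} + R\,\ln(C_T/4)} - 273.15.$$

Default conditions are 50 mM monovalent salt and 0.1 µM primer, chosen to
approximate the (unpublished) conditions of common LAMP design software;
on the four published aEF-2 assay sets shipped in
`inst/extdata/aef2_lamp_primers.tsv` the recomputed Tm tracks the printed
values within ±3 °C for 23 of 24 oligos, which is the package's own
calibration check, not an exact target — printed Tm values from design
software never state their full model. Degenerate primers are scored as
the mean over all concrete expansions, exact up to a configurable
degeneracy cap (256 for Tm; the per-primer design cap is 64, comfortably
above the ≤16-fold degeneracy of published sets).

End stability is the sum of stack ∆G° (37 °C) over a terminal window of
6 bases; more negative is more stable. The two thresholds are applied by
role: the extension-competent 3′ ends of F3/B3, F2/B2 and loop primers
must reach −4 kcal/mol, and the 5′ ends of F1c/B1c (which prime loop-back
synthesis after strand displacement) must reach −3 kcal/mol.

### The dimer check

The dimer score scans every ungapped antiparallel offset of two primers
and scores complementary runs (≥ 2 Watson–Crick pairs) by stack ∆G plus
both duplex-initiation terms. Two modes exist because the conventional
−2.5 kcal/mol floor is only meaningful for **3′-anchored** duplexes — the
species a polymerase can extend into a primer-dimer artifact. Interior
complementary runs below −2.5 kcal/mol occur in essentially every usable
primer pair (including all four published aEF-2 sets), so the design
screen uses the 3′-anchored mode; the `"any"` mode reports total
cross-complementarity as a diagnostic. Degenerate positions pair if any
expansion pairs and runs are scored by their most stable consistent
realization, making the score a conservative (worst-case) bound.

### Spacing geometry

Footprints on the sense consensus run F3 < F2 < (FL) < F1 < B1 < (BL) <
B2 < B3. F3, F2, B1c and BL read the sense strand as-is; F1c, B2, B3 and
FL are reverse complements of their footprints, 5′→3′ as synthesized.
Published constraint windows state distances but not measurement anchors,
so the anchors are pinned here and boundary-tested:

* **F2–B2 span** (120–180 nt): F2 5′ end to B2 5′ end, i.e.
  `B2.end − F2.start` in sense coordinates.
* **Loop distance** (40–60 nt): F2 5′ end to F1 5′ end (mirrored on the
  B side, `B2.end − B1.end`). This is the only anchor under which the
  120 nt span minimum is attainable (40 + 20 + 0 + 20 + 40 = 120 with
  minimal inner lengths and a zero F1–B1 gap); measuring the bare
  footprint gap instead would make the span window unsatisfiable.
* **F2–F3 gap** (0–20 nt) and **F1–B1 gap** (0–100 nt): plain footprint
  gaps.

All bounds are inclusive.

### Assembly, scoring, and determinism

Per-role candidates are enumerated exhaustively, then combined under the
spacing windows with early pruning; geometry-passing combinations are
ranked before the (more expensive, cached) pairwise dimer screen is
applied in rank order. The score is a lexicographic penalty: (1) the
number of spacing distances outside the middle half of their windows,
(2) total |Tm − role-window midpoint| over the six primers, (3) total
degeneracy. The ranking is deliberately free of randomness, and ties
break by discovery order over a candidate list sorted by coordinates, so
permuting candidate input order cannot change the top set. Loop primers
are searched after assembly in the two loop gaps (length 15–22 nt, Tm
window 59–61 °C, our defaults: published loop primers were partly
designed by eye and no algorithmic rule exists to inherit); a set without
a feasible loop primer is returned unchanged and flagged, since loop
primers accelerate but never gate amplification.

### Auditing published sets

`audit_set()` recomputes length, GC, Tm, end stability and degeneracy for
every oligo and reports per-constraint violations **without failing**:
published LAMP sets routinely contain hand-edited primers outside the
software windows (the published aEF-2 outer primers run 43.5–52.3 °C
against a 59–61 °C design window, and the *Methanobrevibacter* assay is
operated at a reduced 58 °C precisely because of its low-Tm outer
primers). Composites are split at the first `TTTT` linker occurrence
whose parts fit the role length windows (preferring a 1c part nearest the
window midpoint); a composite built by this package is audited from its
known components, since a part ending in `T` makes the string split
genuinely ambiguous. Recomputed Tm is reported for both the whole
composite and its parts.

### Specificity rules

Binding-site scanning is exhaustive over both strands; a subject base
matches when the primer's IUPAC code covers it (equivalently, when some
concrete expansion matches). Defaults allow 2 total mismatches but none
in the 3′-terminal 5 nt — 3′ fidelity is what polymerase extension
actually gates — and the published evaluation never quantified its
"could potentially anneal" criterion, so the policy is an explicit,
overridable parameter rather than a guess. A subject is called positive
when all six required footprints occur in canonical order and
orientation with the F2–B2 span within the design window stretched by
1.5× at the top; loop primers are excluded from the rule. Screening is
local and database-driven; no remote BLAST service is involved, so
results are reproducible against a fixed FASTA.

### Phylogenetics

Complete deletion removes every column containing `-` or `N` (`N` is
treated as missing data, matching common phylogenetics-suite semantics).
Jukes–Cantor distance is $d = -\tfrac34\ln(1-\tfrac43 p)$, undefined at
p ≥ 0.75. Neighbour-joining follows Saitou–Nei with the Studier–Keppler
criterion; ties in Q break deterministically by the smallest label pair.
Negative branch-length estimates are clamped to zero with the deficit
transferred to the sibling edge (path lengths through the join are
preserved); the reference implementations this mirrors do not state
their policy, so ours is pinned and tested. Bootstrap resamples columns
with replacement, rebuilds JC+NJ per replicate, and annotates the
point-estimate tree with bipartition percentages (majority mapping onto
one tree, not a consensus tree). On additive matrices the algorithm
recovers the generating tree exactly — the property the test suite
checks on 50 random 6–12-taxon trees in place of published tree
statistics, which depended on sequence sets (including unpublished
assembly ORFs) that cannot be regenerated from public data.

## The synthetic-data module

Simulators are pure functions of their parameters and a seed.

* `simulate_marker_alignment()` draws a star-of-stars: root → genus
  ancestors → leaves, with per-branch substitution rates solved in closed
  form so expected pairwise identity within and between genera matches
  the request under a uniform substitution model (P(match) = 1/4 + 3/4·λ
  along a path). Planted windows are fully conserved (every record
  carries the root base). Defaults (4 genera × 4 sequences, 1500 nt,
  within-identity 0.9, between 0.7, three 250 nt windows) emulate a
  marker-gene alignment of a handful of genomes per genus. What it does
  **not** emulate: indels (no gaps are simulated; gap handling is
  exercised by hand-built fixtures), rate heterogeneity across sites, and
  codon structure — so passing tests show the statistics are computed
  correctly, not that real alignments are this clean.
* `simulate_orf_catalog()` plants `round(frac × n_kos)` archaea-unique
  KOs and guarantees every other KO occurs in ≥ 2 domains, which makes
  planted-KO recovery exact by construction for any seed.
* `simulate_lamp_template()` rejection-samples six footprints that
  individually satisfy the per-primer windows, spaces them by sampled
  in-window distances, verifies the planted six survive the dimer
  screen, and embeds them in random background — a consensus on which at
  least one compliant primer set provably exists.
* `simulate_target_db()` writes the set's own binding sites (degeneracy
  resolved at random) at the set's own spacing into random background for
  on-target records; divergent decoys mutate each site base at the stated
  rate, and half the decoys are pure background, emulating distant
  EF-2-like genes with at most partial single-primer matches.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the design loop on 10–20
seeded templates, conserved-window recovery on 10–20 alignments of
1000 nt, specificity on 5 databases of 6 records, neighbour-joining
oracles on 50 matrices of 6–12 taxa, and bootstraps of 50–200 replicates
on 6–16 sequence alignments — sizes chosen so the whole validation suite
exercises every code path in minutes on one core while keeping every
statistical check comfortably away from its decision boundary. Floating
point: NJ additivity is asserted to 1e−10, thermodynamic oracle
agreement to 1e−6 °C; identity targets carry a ±0.05 Monte-Carlo
tolerance at 1500 sites.

## Known limitations

* Tm/∆G conditions approximate unpublished design-software settings;
  recomputed values are tolerance-tracked, never exact.
* Specificity is sequence-geometric; no annealing kinetics or
  amplification efficiency is modelled, and a "positive" call is a
  statement about binding-site layout only.
* The identity simulator's uniform-substitution model cannot request
  identities below 0.25 and does not model transition/transversion bias.
* Consensus profiling requires concrete A/C/G/T alignments (plus gaps);
  inputs already containing ambiguity codes must be resolved upstream.
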