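---
title: "Auditing side-chain packing with discretized rotamer analysis"
author: "rotaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing side-chain packing with discretized rotamer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaudit)
```

## The problem

Side-chain packing programs (FASPR, RASP, SCWRL4 and relatives) strip the
side chains from a protein backbone and rebuild them from a rotamer
library. Auditing their output calls for a residue-by-residue comparison
between the deposited crystal conformation and the repacked one, a robust
discretization of conformational space so that "same or different" is
well defined, and covariates — solvent accessibility above all — that
explain where predictions fail. `rotaudit` implements that audit as a
reusable pipeline, and pairs it with a synthetic structure generator and a
mock predictor so that every stage can be validated against exact ground
truth rather than against another program's output.

## The discretized rotamer model

A side chain with $k$ Chi torsions is summarized by the vector
$(\chi_1, \dots, \chi_k)$, each angle in $(-180^\circ, +180^\circ]$ with
trans reported as $+180^\circ$. A canonical rotamer class is a mode
vector, one mode per torsion; a conformation belongs to a class when every
torsion lies within $\pm 30^\circ$ of the class mode (circular distance,
so the trans bin wraps across $\pm 180^\circ$). Conformations inside no
class are "off". The generic modes are

* p (plus): $+65^\circ$, bin $[+35^\circ, +95^\circ]$;
* t (trans): $180^\circ$, bin $|\chi| \ge 150^\circ$;
* m (minus): $-65^\circ$, bin $[-95^\circ, -35^\circ]$.

The $\pm 65^\circ$ centers follow from the printed minus interval
$[-95^\circ, -35^\circ]$; the plus bin mirrors it. Both are configurable
through `bin_model.json`. Amino acids whose terminal torsion does not
cluster near the generic modes carry named modes instead (ASN "m-20",
GLU "mt-10", ARG "mtt180", ...); named bins use the same $\pm 30^\circ$
halfwidth, so one off rule covers everything. The class universe —
`rotamer_inventory.tsv`, 155 rows over the 18 side-chain types — is the
closed list used throughout; Chi combinations outside it classify as off.
When several bins overlap (ASP "p-10" and "p30" meet between their
modes) the class with the smallest maximum per-torsion deviation wins,
ties fall back to the deviation sum and then to inventory order.

Proline is special: its ring constrains $\chi_1$, and the two pucker
states are classified from $\chi_1$ alone — within $30^\circ$ of
$+30^\circ$ is "Cg endo", within $30^\circ$ of $-30^\circ$ is "Cg exo",
otherwise off. The sign convention (endo positive) is a documented
package convention; no authoritative sign is attached to the labels by
the upstream analysis, and the boundary $\chi_1 = 0$ goes to exo.
Arginine is classified on $\chi_1$–$\chi_4$ only; the guanidinium
$\chi_5$ is excluded from the definitions table.

### Symmetric branches and nomenclature

The carboxylates of ASP and GLU and the aromatic rings of PHE and TYR are
two-fold symmetric: their terminal torsion is only defined modulo
$180^\circ$, and IUPAC-IUB rules pick the representative in
$(-90^\circ, +90^\circ]$. `correct_symmetric_chi()` folds the terminal
torsion (ASP $\chi_2$, GLU $\chi_3$, PHE/TYR $\chi_2$) into that range by
a $180^\circ$ rotation when it lies in $[-180^\circ, -90^\circ]$ or
$(+90^\circ, +180^\circ]$ — the boundary is closed at $-90^\circ$ and
open at $+90^\circ$, and the operation is idempotent. A published variant
of the rule indexes the ASP/GLU torsions one lower; because the named
classes (ASP "t70", GLU "mt-10") only make sense for the terminal
torsion, the terminal reading is the default and
`verbatim_indices = TRUE` reproduces the variant.

Classification treats those symmetric terminal torsions with
$180^\circ$ periodicity. This is forced by the class tables themselves:
the PHE "m-85" bin, $[-115^\circ, -55^\circ]$, crosses $-90^\circ$, so a
conformation at $\chi_2 = -100^\circ$ — stored as its IUPAC image
$+80^\circ$ after correction — must still land in "m-85". Per-Chi
*deviations* between paired structures, by contrast, use the plain
circular difference $180 - |\,|x - y| - 180\,|$ on corrected angles,
which is the printed definition of the angular-error statistic.

On the record level, a PHE/TYR $\chi_2$ outside $(-90^\circ, +90^\circ]$
means the CD1/CD2 and CE1/CE2 atom names were written swapped.
`fix_ring_names()` audits every PHE/TYR, swaps the names (never the
coordinates) when the raw $\chi_2$ violates the rule, and
`nomenclature_census()` reports the violation percentage per amino acid
before/after fixing.

## Quality filters

Structure level: single chain, crystallographic resolution strictly below
2.0 Å (absent resolution fails unless the check is disabled — synthetic
structures carry a nominal 1.5 Å so they pass by default). Residue level:
every atom participating in any of the residue's torsion computations
(backbone N, CA, C plus all side-chain Chi atoms) must be present with
B-factor $\le 40$ Å$^2$ and occupancy 1. Flags are prioritized
missing-atoms, then B-factor, then occupancy, and each residue receives
exactly one flag. Alternate locations other than blank/'A' are dropped at
parse time; with the occupancy-1 filter they could never survive anyway.

## Solvent accessibility

Per-residue accessibility (ACC) is computed by Shrake–Rupley sampling:
each heavy atom's sphere at $r_{vdW} + 1.4$ Å is covered with 960
deterministic Fibonacci-spiral points and points inside any neighbour's
probe-expanded sphere are occluded; residue ACC sums its atoms. The
per-element radii (`radii.tsv`, Chothia-style: C 1.87, N 1.65, O 1.40,
S 1.85 Å) and the probe are tunable. At 960 points an isolated atom's
area is within 2% of $4\pi r^2$ and doubling the points moves no residue
of a 21-residue test chain by 1%. A classic DSSP output can be ingested
instead for parity runs; note that DSSP's ACC differs from Shrake–Rupley
by a few Å$^2$ per residue, while the downstream category thresholds —
zero (ACC $= 0$), low $(0, 50]$, medium $(50, 100]$, high $> 100$
Å$^2$ — are kept as printed. Fixed 20 Å$^2$ bins labelled by their
left-closed lower limit cover 0–320 Å$^2$ with an overflow bin above.
Dividing ACC by 9.65 Å$^2$ converts it to contacting water molecules.

Secondary structure is ingested from DSSP's 8 categories when a DSSP file
is available; otherwise a coarse $\phi/\psi$ fallback assigns H (within
$30^\circ$ of $-57/-47$), E (within $30^\circ$ of $-120/+120$) or C and
is flagged approximate. The fallback exists so strata are populated on
synthetic data; it is not a DSSP replacement.

## Error statistics

`pair_structures()` matches residues by chain and author numbering,
refuses amino-acid mismatches, and compares only residues retained and
classified on both sides. A rotamer (class) error is any label
difference; for long side chains one deviant torsion suffices, which is
why the per-Chi view dichotomizes each angular deviation at $30^\circ$
separately. Decompositions follow two complementary ratios: the error
*rate* of an amino acid (its errors over its records) and its
*contribution* (its errors over all errors, summing to 100%). Rates are
reported per amino acid, per ACC bin and category, per secondary
structure, per protein-size bin (100 residues wide) and per side-chain
group — group I (CYS, SER, THR, VAL; $\chi_1$ only) through group IV
(LYS, ARG; $\chi_1$–$\chi_4$). Per-class confidence is the diagonal of
the class confusion matrix: of the residues originally in class X, the
percentage predicted X, per program with a macro-average across programs
(the aggregation is a package choice; per-program columns are retained).
Transition tables rank "original to predicted" label pairs among errors,
ties broken lexicographically so reports are deterministic.

The accessibility–rotamer relationship is tested per amino acid with a
one-way ANOVA of ACC across classes (off included) via `aov()`, followed
by Tukey HSD. The raw Tukey p-value is then Bonferroni-scaled by the
total number of class pairs across all amino acids,
$\sum_{aa} \binom{k_{aa}}{2} = 963$ for the shipped inventory (off
included), capped at 1; the family-adjusted significance level is
$0.05 / 963 \approx 0.000052$. Both the family size and the scaling are
derived from the inventory at run time, not hard-coded. Classes with a
single record are dropped from the post hoc with a note.

## The synthetic generator and mock predictor

`build_peptide()` constructs single-chain all-atom peptides by sequential
internal-coordinate placement (N–CA 1.458, CA–C 1.525, C–N 1.329 Å,
$\omega = 180^\circ$, CB at the L-configuration improper of
$-122.9^\circ$) with helix/strand/coil backbone presets, then attaches
side chains from idealized templates (`sidechain_templates.tsv`) at
prescribed Chi angles. Default sampling reproduces the reference-census
conditions: amino-acid composition proportional to the census totals and
class weights proportional to the observed class counts (off included),
with angles uniform within $\pm 15^\circ$ of the class mode. Off
conformations place exactly one torsion uniformly more than $31^\circ$
from every mode at that index — minimal, unambiguous off ground truth
(the $1^\circ$ margin keeps build/measure round-trip noise from touching
the bin boundary). Proline is built open-chain with $\chi_2 = -\chi_1$ as
a ring-like correlation; its ring is not closed, which is why PRO is
exempted from the $10^{-4}$-degree round-trip guarantee (its $\chi_1$ is
still exact by construction). Construction is deterministic given the
mandatory seed, B-factors are drawn inside the filter cutoff, and
metadata corruption (occupancy 0.5, B-factor 60, or swapped
symmetric-branch names at configured rates) always hits atoms inside the
residue's torsion set so filter and census tests have exact expectations.

`mock_predict()` stands in for an external packing program: per residue,
with probability $\varepsilon = \mathrm{logit}^{-1}(\mathrm{logit}
(\varepsilon_0) + s \cdot \mathrm{ACC})$, the side chain is rebuilt at a
different inventory class (uniform over the alternatives, off included),
backbone untouched, every action written to the truth ledger. With
$s > 0$ error rates rise monotonically across accessibility strata, which
is what the audit must detect.

What the generator does *not* emulate: steric exclusion (clashes are
permitted), real rotamer–backbone coupling, crystallographic noise, and
compact tertiary packing — a single synthetic chain is mostly solvent
exposed, so its zero-ACC stratum is sparse. Passing tests therefore
demonstrate that the pipeline measures what was injected, not that any
packing program behaves a particular way on real crystals.

## Numerical choices and degenerate inputs

* Angles live in $(-180^\circ, +180^\circ]$; $-180^\circ$ is normalized
  to $+180^\circ$ so trans has one representative.
* A deviation of exactly $30.0^\circ$ counts as correct (the bin reach is
  read inclusive).
* Collinear torsion frames raise errors rather than returning arbitrary
  values; residues with missing Chi atoms carry a defined-mask and are
  excluded from classification (refused, not off).
* Empty strata are absent rows, never 0% — a bin with no cases carries no
  rate. ACC bins above 220 Å$^2$ are flagged as potentially low-count.
* ANOVA requires at least two classes with two records each; the Tukey
  step drops singletons and errors out below two usable classes.
* Problem sizes in the shipped tests and acceptance script (chains of
  150–2000 residues, 120–960 sphere points, 4-structure pipeline runs)
  were chosen as the smallest sets whose binomial error bars make the
  recovery checks decisive.

## Known limitations

DSSP ACC and Shrake–Rupley ACC differ systematically, so absolute
category boundaries are comparable only within one method. The
phi/psi secondary-structure fallback knows only H/E/C. The proline
endo/exo sign is a convention, and the open-ring proline build caps its
$\chi$ fidelity at about $1^\circ$. Real PDB pathologies (altloc
ensembles beyond 'A', chain breaks, non-standard residues) are out of
scope: non-standard residues and waters are dropped at parse time.
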