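---
title: "Filtering docked poses by substructure geometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering docked poses by substructure geometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posegrep)
```

## The problem and the model

A docking run leaves each candidate compound with several predicted
poses and a score per pose. Ranking by score alone discards structural
knowledge that is often available: known ligands of a target frequently
share a specific contact — a hydrogen-bond acceptor near a particular
backbone atom, an aromatic ring stacked against a particular side chain,
a sugar-like ring in a particular subsite. posegrep encodes each such
expectation as a filter with four parts: a SMARTS substructure, a 3D
query point, a distance cutoff (Å), and an optional exclude flag.

For a pose and a filter, the engine finds every embedding of the SMARTS
pattern in the pose's molecular graph, takes the minimum Euclidean
distance from any matched atom to the query point, and compares it to
the cutoff (inclusively: *within* means `d <= cutoff`; the conventional
reading of "within cutoff distance", documented here because the
boundary case is otherwise ambiguous). The verdict follows a six-row
truth table: with the exclude flag unset, a pose passes iff the
substructure is present *and* within the cutoff; with exclude set, the
verdict is the complement when the substructure is present, and an
automatic pass when it is absent. Filters combine by conjunction, and a
compound passes when at least one of its poses passes all filters —
every docked pose is considered, not only the top-scoring one.

Query points come in two forms. A `coordinate` filter carries a literal
`[x, y, z]` in the docking frame (receptor and poses are assumed
pre-aligned by the docking run; no transformation is ever applied). A
`receptorAtom` filter names a receptor atom by (chain, resid, atomname);
the lookup must resolve to exactly one atom, and anything else aborts
the run before any pose is read — a mis-anchored filter that silently
passed everything would be worse than a crash. Insertion codes and
altLoc indicators do not participate in matching, and HETATM records
(e.g. co-crystallised cofactors) are legal anchors.

## Bond assignment: three modes

PDB and PDBQT pose files carry no bond orders, so SMARTS matching needs
a bond-assignment step. SDF files carry a bond block and always use it,
whatever the mode.

**NONE mode** treats every atom as sp³ and joins atoms *i*, *j* by a
single bond when

$$d_{ij} \le r_i + r_j + t,$$

with $r$ standard single-bond covalent radii and $t = 0.45$ Å of
additive tolerance, chosen to absorb the geometric distortion typical of
docked conformers without fusing non-bonded contacts (the shortest
non-bonded heavy-atom contact in a reasonable pose is ≳ 2.3 Å, while a
stretched C–C bond stays under 1.97 Å = 0.76 + 0.76 + 0.45). A floor of
0.4 Å rejects coincident-atom artifacts. Both the radius table and the
tolerance are configurable (`covalent_radius_table()`). The consequence
users must know: NONE-mode graphs contain only single bonds, so a SMARTS
with aromatic atoms or higher-order bonds can never match PDB/PDBQT
poses; `validate_smarts_for_mode()` warns about exactly this.

**SMILES mode** reads a per-compound template (`<posefile>.smi`, same
directory). The template's heavy-atom graph is embedded into the pose's
geometric connectivity by an element-labelled backtracking search, and
template bond orders (and aromatic flags) are copied onto the mapped
atoms. Hydrogens are deliberately excluded from the mapping because
PDBQT strips non-polar hydrogens; pose hydrogens that survive parsing
keep their geometric single bonds. Stereochemistry and formal charge are
ignored — docked PDBQT files carry neither reliably. When several
mappings exist (symmetric molecules), the first is used: automorphic
mappings carry identical bond orders, so the filter outcome is
mapping-invariant (asserted in the tests). Any failure — missing or
unparseable template, heavy-atom element mismatch, no mapping — falls
back to NONE-mode bonds for that file with a warning, so a single bad
template never kills a screen.

**OPENBABEL mode** shells out to an external PDB→SDF converter (the
`--babel_exec` contract). The file is converted with all hydrogens added
(`-h`); if the converter's heavy-atom set does not match the input, the
conversion is retried at pH 7.4 (`-p 7.4`); if both attempts fail the
file is recorded as skipped and the screen moves on. The converter is
never linked in-process: the core stays dependency-free and the contract
is testable with a stub executable. Perceiving hybridisation from 3D
coordinates is inherently ambiguous, so this mode is a convenience, not
a recommendation.

The SMARTS dialect implemented covers what distance filters use in
practice: organic-subset atoms (aliphatic upper-case, aromatic
lower-case), `*`, bracket atoms with atomic-number primitives, element
symbols, `a`/`A`, negation `!` and the `,`/`&`/`;` connectives at their
usual precedences, explicit bonds `-`, `=`, `#`, `:`, `~` plus the
default single-or-aromatic bond, branches, and ring closures. Recursive
SMARTS, charge/degree/ring-count primitives and dot-disconnected
patterns are rejected at filter-load time — failing loudly at
configuration beats failing silently per pose. An atom is aromatic iff
it participates in at least one aromatic bond; kekulised SDF input (a
benzene written as alternating single/double bonds) is therefore not
matched by `cc`, which is documented rather than "fixed": aromaticity
perception from kekulé structures is a normalisation problem this
package deliberately does not own.

## Screen mechanics

Pose files are discovered by extension, case-insensitively; `.smi`
companions are never poses; mixed-format directories are legal. Each
compound file is a work unit: with `jobs > 1` files are distributed over
forked workers and results merged in file order, so the output is
byte-identical for any worker count (on Windows, where forking is
unavailable, execution degrades to serial). Output is one passing file
name per line, sorted lexicographically regardless of directory
enumeration order, so diffs between runs are meaningful. Per-compound
failures (unparseable file, failed external conversion) become skip
records with warnings; the run completes and exits successfully. Only
configuration errors — unreadable receptor, malformed filters file,
unresolvable receptorAtom — are fatal. Within a file, template-based
bond assignment is computed once and reused across poses: MODEL blocks
of one docked file are conformers of one molecule.

## Scoring a screen

`ranked_library()` orders compounds by docking score (more negative is
better), breaking ties lexicographically by compound id — the tie rule
is arbitrary but fixed, chosen for reproducibility. The metrics are
`enrichment_factor()` ($EF_n = P_n/(nP_T/T)$), `top_n_hits()`, and
`percentile_ranks()` (rank $r$ of $T$ maps to $100\,r/T$, i.e. "top
40%" means percentile ≤ 40; ties inherit the sorted order). To score a
filtered screen, `apply_filter_to_ranking()` moves every compound that
failed the filters to the bottom, survivors first, both groups keeping
their relative order — a stable partition, which conserves the compound
multiset, is idempotent, and can only remove compounds from any
top-*n* window, never reorder survivors. $EF_T = 1$ identically, and
$EF_n \le T/P_T$ with equality when the top *n* are all positives.

## The fixture generator

`make_pose_fixtures()` exists so that every claim above is testable
without any external library or docking run. It emulates the *geometry*
of a docked screen, not its chemistry or energetics:

- Molecules come from five templates (ethanol, ethanolamine, propane,
  benzene, tetrahydropyran) built at near-ideal bond lengths
  (C–C 1.54 Å, C–O 1.43 Å, C–N 1.47 Å, aromatic C–C 1.39 Å, tetrahedral
  chain angles), so geometric bond inference is unambiguous on them.
- Each compound file gets 1–18 poses (default 3; docking pipelines that
  produce up to nine poses for up to two variants per molecule motivate
  the ceiling of 18). A designed fraction of compounds (default 40%)
  passes: for each passing compound a seeded subset of pose indices is
  made to pass, with a coin-flip bias toward shapes where pose 1 fails
  and only a lower-ranked pose passes. Failing compounds fail either by
  lacking the substructure or by geometry.
- Placement is exact: a designated substructure atom is put at a sampled
  distance from the query point, inside `[0.3, cutoff − 0.3]` for a
  designed pass and beyond `cutoff + 0.5 + diameter` for a designed
  fail; per-atom Gaussian jitter (sd 0.05 Å) is then applied and the
  placement re-verified, with the requirement that no verdict sits
  closer than 0.2 Å to a boundary — no test may hinge on floating-point
  edge behaviour. Coordinates are rounded to the 3-decimal PDB width
  before writing.
- The ground-truth table is computed by direct arithmetic on the placed
  coordinates and hand-annotated feature atom sets, sharing no code with
  the engine's matcher — so engine-vs-truth comparisons are a real
  dual-route check.

What the fixtures do *not* emulate — conformational strain, realistic
valences, scoring-function behaviour, receptor flexibility, crowded
binding sites — bounds what passing tests mean: they establish that the
filtering logic, formats, modes and metrics are correct, not that any
particular filter enriches any particular real screen.

Test and acceptance runs use 100-compound × 3-pose screens (seconds in
plain R) and ranked libraries of 120–1561 compounds; these sizes were
chosen as the smallest at which multi-format mixing, per-pose diversity
and Monte-Carlo EF averages are all informative.

## Known limitations

- Geometric perception near the tolerance boundary can fuse atoms in
  severely distorted poses; the radius table and tolerance are exposed
  for exactly that case.
- The SMARTS subset excludes recursive/environment primitives; filters
  needing them should be pre-compiled into explicit patterns.
- Aromaticity is taken from bond orders, never perceived from geometry
  or kekulé alternation.
- The engine never sees docking scores; the output lists passing file
  names lexicographically, and score-aware analysis belongs to the
  metrics module.
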